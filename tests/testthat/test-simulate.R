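test_that("plate simulation is deterministic and respects null spectra", {
  proto <- default_protocol()
  d <- droplet_spec(20, 100)
  m0 <- spectrum_model(list(), background = NULL)
  p0 <- simulate_plate(m0, d, proto, 32, seed = 1)
  expect_equal(p0$frozen_counts, rep(0, length(proto)))
  m <- spectrum_model(spectrum_component("proteinaceous", "particulate",
                                         -8, 1e-3, 0.5))
  a <- simulate_plate(m, d, proto, 32, seed = 99)
  b <- simulate_plate(m, d, proto, 32, seed = 99)
  expect_identical(a$frozen_counts, b$frozen_counts)
  expect_false(identical(
    a$frozen_counts,
    simulate_plate(m, d, proto, 32, seed = 100)$frozen_counts))
  # near-certain saturation when the first-setpoint hazard is large
  big <- spectrum_model(spectrum_component("proteinaceous",
                                           "particulate", -2,
                                           20 / 2000, 0),
                        background = NULL)
  sat <- simulate_plate(big, d, proto, 32, seed = 7)
  expect_equal(sat$frozen_counts[1], 32)
})

test_that("frozen counts are marginally binomial at each setpoint", {
  proto <- freeze_protocol(-10)
  d <- droplet_spec(20, 100)
  lam <- 0.36
  m <- spectrum_model(spectrum_component("proteinaceous", "particulate",
                                         -10, lam / 2000, 0),
                      background = NULL)
  p_freeze <- 1 - exp(-lam)
  n <- 16; plates <- 400
  pass <- 0
  for (b in 1:100) {
    counts <- vapply(1:plates, function(i)
      simulate_plate(m, d, proto, n,
                     seed = inpspectra:::derive_seed(b, "gof", i))$frozen_counts[1],
      numeric(1))
    obs <- tabulate(counts + 1L, nbins = n + 1L)
    expc <- plates * dbinom(0:n, n, p_freeze)
    # pool sparse tail bins so expected counts stay >= 5
    keep <- expc >= 5
    o <- c(sum(obs[!keep]), obs[keep])
    e <- c(sum(expc[!keep]), expc[keep])
    stat <- sum((o - e)^2 / e)
    pass <- pass + (pchisq(stat, df = length(e) - 1,
                           lower.tail = FALSE) >= 0.01)
  }
  expect_gte(pass, 95)
})

test_that("treatment transforms act on the right components and are idempotent", {
  prot <- spectrum_component("proteinaceous", "particulate", -6, 1e-3)
  sol <- spectrum_component("non_proteinaceous", "soluble", -10, 5e-4)
  epi <- spectrum_component("proteinaceous", "particulate", -4, 2e-3,
                            epibiont = TRUE)
  m <- spectrum_model(list(prot, sol, epi))
  d <- droplet_spec(20, 100)
  Tgrid <- seq(-2, -28, by = -2)

  h <- apply_treatment(m, "heated")
  expect_equal(length(h$components), 1L)
  expect_equal(h$components[[1]]$protein_class, "non_proteinaceous")
  expect_equal(apply_treatment(h, "heated"), h)       # idempotent
  pure_np <- spectrum_model(sol)
  expect_equal(apply_treatment(pure_np, "heated")$components,
               pure_np$components)
  pure_p <- spectrum_model(prot)
  expect_equal(predict(apply_treatment(pure_p, "heated"), Tgrid),
               rep(0, length(Tgrid)))

  f <- apply_treatment(m, "filtrate", droplet = d)
  expect_true(f$per_droplet)
  expect_equal(length(f$components), 1L)
  expect_equal(f$components[[1]]$amplitude_A, 5e-4 * 2000)
  expect_equal(apply_treatment(f, "filtrate", droplet = d), f)
  # particulate-only model: only background remains after filtration
  fp <- apply_treatment(pure_p, "filtrate", droplet = d)
  expect_equal(predict(fp, Tgrid), rep(0, length(Tgrid)))

  ax <- apply_treatment(m, "axenic")
  amps <- vapply(ax$components, function(cm) cm$amplitude_A, 0)
  expect_equal(amps, c(1e-3, 5e-4, 0))
  ax2 <- apply_treatment(m, "axenic", axenic_attenuation = 0.5)
  expect_equal(ax2$components[[3]]$amplitude_A, 1e-3)

  hf <- apply_treatment(m, "heated_filtrate", droplet = d)
  expect_true(hf$per_droplet)
  expect_equal(vapply(hf$components, function(cm) cm$protein_class, ""),
               "non_proteinaceous")
})

test_that("cumulative spectra are non-decreasing with cooling", {
  set.seed(3)
  for (i in 1:20) {
    cm <- spectrum_component(sample(c("proteinaceous",
                                      "non_proteinaceous"), 1),
                             sample(c("particulate", "soluble"), 1),
                             onset_T = runif(1, -20, -3),
                             amplitude_A = 10^runif(1, -4, -2),
                             slope_gamma = runif(1, 0, 1))
    K <- inpspectra:::component_K(cm, seq(-2, -28, by = -0.5))
    expect_true(all(diff(K) >= 0))
    expect_true(all(K[seq(-2, -28, by = -0.5) > cm$onset_T] == 0))
  }
})

test_that("strain panels are reproducible and match the configured design", {
  cfg <- panel_config()
  p1 <- generate_strain_panel(cfg, seed = 10)
  p2 <- generate_strain_panel(cfg, seed = 10)
  expect_identical(p1$strains, p2$strains)
  expect_identical(
    p1$screens[["A-01"]][[1]]$sample$frozen_counts,
    p2$screens[["A-01"]][[1]]$sample$frozen_counts)

  s <- p1$strains
  expect_equal(nrow(s), 113)
  expect_equal(sum(s$ina_true & s$source == "airborne"), 14)
  expect_equal(sum(s$ina_true & s$source == "aquatic"), 16)
  expect_equal(sum(s$freeze_survival == "survived" &
                     s$source == "aquatic"), 10)
  expect_equal(sum(s$freeze_survival != "untested" &
                     s$source == "airborne"), 38)
  expect_equal(sum(s$desiccation == "killed"), 11)
  expect_equal(sum(s$taxon %in% c("Trebouxiophyceae", "Chlorophyceae") &
                     s$source == "airborne"), 46)
  expect_equal(length(p1$profiles), 30)
  # airborne INA strains are configured warmer than aquatic ones
  onset_of <- function(src) {
    ids <- s$strain_id[s$ina_true & s$source == src]
    vapply(ids, function(id) p1$truth[[id]]$components[[1]]$onset_T, 0)
  }
  expect_gt(mean(onset_of("airborne")), mean(onset_of("aquatic")))
})

test_that("panel config validation rejects inconsistent designs", {
  expect_error(panel_config(ina_airborne = 100), "exceed")
  expect_error(panel_config(airborne_classes = c(warm = 1, mid = 1,
                                                 cool = 1, cold = 1)),
               "allocate")
  expect_error(panel_config(generalist_fraction = 1.5), "\\[0, 1\\]")
  expect_error(panel_config(nature_probs = c(1, 1, 0, 0)),
               "probability")
})

test_that("a zero-prevalence panel confirms essentially no strains", {
  cfg <- panel_config(ina_airborne = 0, ina_aquatic = 0,
                      airborne_classes = c(warm = 0, mid = 0, cool = 0,
                                           cold = 0),
                      aquatic_classes = c(warm = 0, mid = 0, cool = 0,
                                          cold = 0),
                      n_airborne = 20, n_aquatic = 10,
                      airborne_taxa = c(Trebouxiophyceae = 10,
                                        Chlorophyceae = 2,
                                        Stramenopiles = 3, unknown = 5),
                      freeze_tested_airborne = 10,
                      freeze_survivors_aquatic = 3,
                      desiccation_tested_aquatic = 4)
  false_pos <- 0; total <- 0
  for (run in 1:50) {
    panel <- generate_strain_panel(cfg, seed = 500 + run)
    for (id in panel$strains$strain_id) {
      scr <- vapply(panel$screens[[id]], function(x)
        screen_ina_assay(x$sample), TRUE)
      false_pos <- false_pos + confirm_ina(scr)
      total <- total + 1
    }
  }
  expect_lt(false_pos / total, 0.05)
})
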