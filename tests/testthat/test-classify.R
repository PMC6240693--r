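test_that("INA screen uses an inclusive 50% rule at -24 degC", {
  expect_true(screen_ina(8, 16))
  expect_false(screen_ina(7, 16))
  expect_true(screen_ina(16, 16))
  expect_error(screen_ina(17, 16))
  # monotone: adding frozen wells never flips positive -> negative
  for (n in c(16, 32)) {
    flags <- vapply(0:n, screen_ina, TRUE, n_wells = n)
    expect_true(all(diff(flags) >= 0))
  }
  p <- default_protocol()
  a <- plate_assay("s", "untreated", "r", droplet_spec(20, 100), p,
                   cumsum(c(rep(0, 10), 2, 2, 2, 2)), 16)
  expect_false(screen_ina_assay(a))      # 6/16 at -24
  p2 <- freeze_protocol(c(-10, -12))
  a2 <- plate_assay("s", "untreated", "r", droplet_spec(20, 100), p2,
                    c(8, 16), 16)
  expect_error(screen_ina_assay(a2), "-24")
})

test_that("confirmation requires all of at least two screens positive", {
  expect_true(confirm_ina(c(TRUE, TRUE)))
  expect_false(confirm_ina(c(TRUE, FALSE)))
  expect_false(confirm_ina(c(FALSE, FALSE)))
  expect_true(confirm_ina(c(TRUE, TRUE, TRUE)))
  expect_error(confirm_ina(TRUE), "2")
})

test_that("onset is the warmest setpoint active in all replicates", {
  p <- freeze_protocol(c(-4, -5, -6, -7))
  mk <- function(first_ok) {
    a <- plate_assay("s", "untreated", "r", droplet_spec(20, 100), p,
                     rep(16, 4), 16)
    s <- fit_inp_spectrum(a)
    s$flag <- ifelse(p$setpoints <= first_ok, "ok", "below_detection")
    s$estimate <- ifelse(p$setpoints <= first_ok, 1e-3, 0)
    s
  }
  expect_equal(onset_temperature(list(mk(-5), mk(-5), mk(-6))), -6)
  expect_equal(onset_temperature(list(mk(-4), mk(-4), mk(-4))), -4)
  expect_equal(onset_temperature(list(mk(-5), mk(-5), mk(-6)),
                                 rule = "any"), -5)
  dead <- mk(-99)
  expect_true(is.na(onset_temperature(list(dead, dead, dead))))
  # never warmer than any single replicate's first activity
  set.seed(9)
  for (i in 1:20) {
    firsts <- sample(p$setpoints, 3, replace = TRUE)
    reps <- lapply(firsts, mk)
    on <- onset_temperature(reps)
    expect_lte(on, min(firsts))
  }
})

test_that("temperature classes partition the assay range without gaps", {
  expect_equal(temperature_class(-5), "warm")
  expect_equal(temperature_class(-11), "mid")
  expect_equal(temperature_class(-20), "cold")
  expect_equal(temperature_class(-6), "warm")      # boundary to warmer class
  expect_equal(temperature_class(-12), "mid")
  expect_equal(temperature_class(-18), "cool")
  expect_equal(temperature_class(-24), "cold")
  expect_equal(temperature_class(-25), "none")     # below assay range
  expect_equal(temperature_class(NA), "none")
  grid <- seq(-2, -24, by = -0.5)
  classes <- vapply(grid, temperature_class, "")
  expect_false(any(classes == "none"))
  # contiguity: class changes exactly at the documented edges
  edges <- grid[which(classes[-1] != classes[-length(classes)])]
  expect_equal(edges, c(-6, -12, -18))
})

test_that("ina_decision combines screens, filter and onset coherently", {
  batch <- make_test_batch(onset = -8, seed = 21)
  reps <- fit_arm(batch, "untreated")
  dec <- ina_decision(c(TRUE, TRUE), reps)
  expect_true(dec$confirmed)
  expect_true(dec$screened_positive)
  expect_equal(dec$temperature_class, "mid")
  expect_lte(dec$onset_temperature, -8)
  dec2 <- ina_decision(c(TRUE, FALSE), reps)
  expect_false(dec2$confirmed)
  expect_true(dec2$screened_positive)
  expect_equal(dec2$temperature_class, "none")
  expect_true(is.na(dec2$onset_temperature))
})

test_that("nature inference recovers the generating compound classes", {
  combos <- list(
    list("proteinaceous", "particulate", "proteinaceous",
         "cell_associated"),
    list("proteinaceous", "soluble", "proteinaceous", "soluble"),
    list("non_proteinaceous", "soluble", "non_proteinaceous",
         "soluble"),
    list("non_proteinaceous", "particulate", "non_proteinaceous",
         "cell_associated"))
  for (cb in combos) {
    batch <- make_test_batch(protein = cb[[1]], localization = cb[[2]],
                             seed = 31)
    v <- infer_nature(fit_arm(batch, "untreated"),
                      fit_arm(batch, "heated"),
                      fit_arm(batch, "filtrate"))
    expect_equal(v$protein_axis, cb[[3]],
                 info = paste(cb[[1]], cb[[2]]))
    expect_equal(v$localization_axis, cb[[4]],
                 info = paste(cb[[1]], cb[[2]]))
  }
})

test_that("missing treatment arms give indeterminate axes", {
  batch <- make_test_batch(seed = 41)
  unt <- fit_arm(batch, "untreated")
  v1 <- infer_nature(unt, heated = NULL,
                     filtrate = fit_arm(batch, "filtrate"))
  expect_equal(v1$protein_axis, "indeterminate")
  expect_match(v1$evidence$notes, "heated", all = FALSE)
  v2 <- infer_nature(unt, heated = fit_arm(batch, "heated"),
                     filtrate = NULL)
  expect_equal(v2$localization_axis, "indeterminate")
})
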