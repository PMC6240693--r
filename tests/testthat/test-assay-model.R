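test_that("protocol and plate invariants are enforced", {
  expect_error(freeze_protocol(c(-2, -2.5)), "gaps")
  expect_error(freeze_protocol(c(-2, -5)), "gaps")
  expect_error(freeze_protocol(c(-2, 2)), "below 0")
  expect_error(freeze_protocol(c(-4, -2)), "decreasing")
  p <- freeze_protocol(c(-10, -12, -14))
  d <- droplet_spec(20, 100)
  expect_error(plate_assay("s", "untreated", "r", d, p, c(2, 1, 3), 16),
               "cumulative")
  expect_error(plate_assay("s", "untreated", "r", d, p, c(2, 5, 17), 16),
               "n_wells")
  expect_error(plate_assay("s", "untreated", "r", d, p, c(2, 5), 16),
               "setpoints")
  expect_error(droplet_spec(-1, 10), "positive")
})

test_that("frozen fraction is counts over wells and keeps monotonicity", {
  p <- freeze_protocol(seq(-2, -28, by = -2))
  d <- droplet_spec(20, 100)
  zero <- plate_assay("s", "untreated", "r", d, p, rep(0, 14), 16)
  expect_equal(compute_frozen_fraction(zero)$frozen_fraction, rep(0, 14))
  counts <- c(0, 0, 0, 0, 1, 2, 4, 6, 8, 10, 12, 8 + 8, 16, 16)
  a <- plate_assay("s", "untreated", "r", d, p, counts, 16)
  ff <- compute_frozen_fraction(a)
  expect_equal(ff$frozen_fraction[p$setpoints == -24], 16 / 16)
  expect_equal(ff$frozen_fraction[p$setpoints == -18], 8 / 16)
  expect_true(all(diff(ff$frozen_fraction) >= 0))
  expect_true(all(ff$frozen_fraction >= 0 & ff$frozen_fraction <= 1))
})

test_that("background correction subtracts and excludes negatives", {
  p <- freeze_protocol(c(-10, -12, -14))
  d <- droplet_spec(20, 100)
  s <- compute_frozen_fraction(
    plate_assay("s", "untreated", "r", d, p, c(2, 8, 16), 16))
  ctl0 <- compute_frozen_fraction(
    plate_assay("s", "control", "r", droplet_spec(20, 0), p,
                c(0, 0, 0), 16), role = "control")
  ident <- correct_background(s, ctl0)
  expect_equal(ident$ff_corrected, s$frozen_fraction)
  ctl <- compute_frozen_fraction(
    plate_assay("s", "control", "r", droplet_spec(20, 0), p,
                c(4, 6, 8), 16), role = "control")
  corr <- correct_background(s, ctl)
  expect_true(corr$excluded[1])       # 2/16 - 4/16 < 0
  expect_true(is.na(corr$ff_corrected[1]))
  expect_equal(corr$ff_corrected[2], 8 / 16 - 6 / 16)
  p2 <- freeze_protocol(c(-8, -10, -12))
  s2 <- compute_frozen_fraction(
    plate_assay("s", "untreated", "r", d, p2, c(2, 8, 16), 16))
  expect_error(correct_background(s2, ctl), "protocol")
})

test_that("the Vali transform matches closed forms and scalings", {
  expect_equal(inp_per_cell(1 - exp(-1), droplet_spec(20, 100)),
               1 / 2000, tolerance = 1e-12)
  expect_equal(inp_per_cell(0.5, cV = 1), log(2), tolerance = 1e-12)
  expect_equal(inp_per_cell(0, cV = 123), 0)
  expect_error(inp_per_cell(1, cV = 1), "saturation")
  expect_error(inp_per_cell(0.5, droplet_spec(20, 0)), "per-droplet")
  # strictly increasing in ff, inverse in c and V
  set.seed(11)
  for (i in 1:50) {
    f <- sort(runif(2, 0, 0.99))
    cc <- runif(1, 1, 500); v <- runif(1, 5, 50); s <- runif(1, 1.1, 4)
    expect_gt(inp_per_cell(f[2], cV = cc * v),
              inp_per_cell(f[1], cV = cc * v))
    expect_equal(inp_per_cell(f[1], cV = s * cc * v),
                 inp_per_cell(f[1], cV = cc * v) / s, tolerance = 1e-12)
  }
})

test_that("detection limits match hand computation and shrink with n", {
  dl <- detection_limits(32, cV = 2000)
  expect_equal(unname(dl["lower"]), -log(31 / 32) / 2000,
               tolerance = 1e-12)
  expect_equal(unname(dl["lower"]), 1.588e-5, tolerance = 1e-3)
  dl16 <- detection_limits(16, cV = 1)
  expect_equal(unname(dl16["lower"]), -log(15 / 16), tolerance = 1e-12)
  expect_equal(unname(dl16["lower"]), 0.0645, tolerance = 1e-3)
  expect_lt(dl["lower"], detection_limits(16, cV = 2000)["lower"])
  expect_true(all(detection_limits(8, cV = 5)["lower"] <
                    detection_limits(8, cV = 5)["upper"]))
})

test_that("Clopper-Pearson interval matches a binomial-tail bisection oracle", {
  for (k in c(0, 1, 5, 8, 15, 16)) {
    got <- binomial_ci(k, 16, 0.95)
    want <- cp_oracle(k, 16, 0.95)
    expect_equal(unname(got), unname(want), tolerance = 1e-6,
                 info = paste("k =", k))
  }
  expect_equal(unname(binomial_ci(0, 16)["low"]), 0)
  expect_equal(unname(binomial_ci(16, 16)["high"]), 1)
  got <- binomial_ci(8, 16, 0.95)
  expect_equal(unname(got), unname(cp_oracle(8, 16)), tolerance = 1e-6)
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(202)
  n <- 16; reps <- 2000
  hits <- 0
  p_true <- runif(reps, 0.05, 0.95)
  for (i in seq_len(reps)) {
    k <- rbinom(1, n, p_true[i])
    ci <- binomial_ci(k, n, 0.95)
    hits <- hits + (ci["low"] <= p_true[i] && p_true[i] <= ci["high"])
  }
  mc_err <- sqrt(0.95 * 0.05 / reps)
  expect_gte(hits / reps, 0.95 - 3 * mc_err)
})

test_that("spectrum fit flags saturation, below-detection and removals", {
  p <- freeze_protocol(c(-10, -12, -14, -16))
  d <- droplet_spec(20, 100)
  a <- plate_assay("s", "untreated", "r", d, p, c(0, 4, 16, 16), 16)
  ctl <- plate_assay("s", "control", "r", droplet_spec(20, 0), p,
                     c(1, 0 + 1, 1, 1), 16)
  s <- fit_inp_spectrum(a, control = ctl)
  expect_equal(s$flag[1], "negative_removed")   # 0 < 1/16
  expect_true(is.na(s$estimate[1]))
  expect_equal(s$flag[2], "ok")
  # fully frozen plates are censored even with a partly frozen control
  expect_equal(s$flag[3], "saturated")
  expect_equal(s$estimate[3], -log(1 - (15.5 / 16 - 1 / 16)) / 2000,
               tolerance = 1e-12)
  expect_true(is.infinite(s$ci_high[3]))
  expect_equal(s$flag[4], "saturated")
  sat <- fit_inp_spectrum(
    plate_assay("s", "untreated", "r", d, p, c(0, 4, 16, 16), 16))
  expect_equal(sat$flag[3], "saturated")
  expect_equal(sat$estimate[3], -log(1 - 15.5 / 16) / 2000,
               tolerance = 1e-12)
  expect_true(is.infinite(sat$ci_high[3]))
  ok <- s$flag == "ok"
  expect_true(all(s$ci_low[ok] <= s$estimate[ok] + 1e-15))
  expect_true(all(s$estimate[ok] <= s$ci_high[ok] + 1e-15))
  expect_true(all(s$estimate[ok] >= 0))
})

test_that("identical sample and control curves give an all-zero spectrum", {
  p <- freeze_protocol(seq(-2, -28, by = -2))
  counts <- c(0, 0, 1, 1, 2, 4, 4, 6, 8, 10, 12, 13, 14, 16)
  a <- plate_assay("s", "untreated", "r", droplet_spec(20, 100), p,
                   counts, 16)
  ctl <- plate_assay("s", "control", "r", droplet_spec(20, 0), p,
                     counts, 16)
  s <- fit_inp_spectrum(a, control = ctl)
  expect_true(all(s$estimate[!is.na(s$estimate)] == 0))
})

test_that("merge_dilutions averages usable dilutions and is order-invariant", {
  p <- freeze_protocol(c(-10, -12))
  mk <- function(est, flag, dil) {
    a <- plate_assay("s", "untreated", "r",
                     droplet_spec(20, 100 / dil, dil), p, c(0, 0), 32)
    s <- fit_inp_spectrum(a)
    s$estimate <- est; s$flag <- flag
    s$ci_low <- est * 0.5; s$ci_high <- est * 2
    s
  }
  s1 <- mk(c(2e-3, 1e-3), c("ok", "ok"), 1)
  s2 <- mk(c(4e-3, 5e-3), c("ok", "saturated"), 10)
  m <- merge_dilutions(list(s1, s2))
  expect_equal(m$estimate[1], 3e-3)            # mean of usable
  expect_equal(m$estimate[2], 1e-3)            # saturated excluded
  expect_equal(m$flag, c("ok", "ok"))
  m_rev <- merge_dilutions(list(s2, s1))
  expect_equal(m$estimate, m_rev$estimate)
  expect_equal(m$flag, m_rev$flag)
  single <- merge_dilutions(list(s1))
  expect_equal(single$estimate, s1$estimate)
  # no dilution usable: most informative flag propagates
  s3 <- mk(c(1e-2, NA), c("saturated", "negative_removed"), 1)
  s4 <- mk(c(0, NA), c("below_detection", "negative_removed"), 10)
  m2 <- merge_dilutions(list(s3, s4))
  expect_equal(m2$flag, c("saturated", "negative_removed"))
  expect_error(merge_dilutions(list()), "no spectra")
})

test_that("three-replicate filter drops strains below detection", {
  batch <- make_test_batch(seed = 5)
  reps <- fit_arm(batch, "untreated")
  expect_true(replicate_filter(reps)$keep)
  # replace one replicate with a control-only (inactive) plate
  dead_model <- spectrum_model(list(), background = NULL)
  dead <- fit_inp_spectrum(simulate_plate(
    dead_model, droplet_spec(20, 100), default_protocol(), 32,
    seed = 3, replicate_id = "r3"))
  res <- replicate_filter(list(reps[[1]], reps[[2]], dead))
  expect_false(res$keep)
  expect_match(res$reason, "below detection")
  expect_error(replicate_filter(reps[1:2]), "3")
})

test_that("estimator recovers a constant simulated hazard (small n)", {
  # single setpoint, lambda = cV * K = 0.2, 200 plates of 32 wells
  proto <- freeze_protocol(-10)
  d <- droplet_spec(20, 100)
  K <- 0.2 / 2000
  m <- spectrum_model(spectrum_component("proteinaceous", "particulate",
                                         -10, K, 0),
                      background = NULL)
  est <- vapply(1:200, function(i) {
    a <- simulate_plate(m, d, proto, 32, seed = 7000 + i)
    fit_inp_spectrum(a)$estimate[1]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - K), 3 * se + 1e-12)
})
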