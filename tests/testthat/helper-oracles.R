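# Independent oracle implementations used to check the package's
# estimators and tests. These deliberately avoid the code paths (and
# where possible the base functions) used by the implementation.

# Clopper-Pearson bounds by direct bisection of the binomial tail
cp_oracle <- function(k, n, level = 0.95, tol = 1e-12) {
  a <- (1 - level) / 2
  bisect <- function(f) {
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  low <- if (k == 0) 0 else
    bisect(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) < a)
  high <- if (k == n) 1 else
    bisect(function(p) stats::pbinom(k, n, p) >= a)
  c(low = low, high = high)
}

# mid-ranks computed by explicit counting, not base rank()
midranks_oracle <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Kruskal-Wallis H by the direct rank-sum formula with tie correction
kw_oracle <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- midranks_oracle(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 0
  for (g in seq_along(groups))
    H <- H + sum(r[idx == g])^2 / sum(idx == g)
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  ties <- 0
  for (v in unique(x)) {
    t <- sum(x == v)
    ties <- ties + t^3 - t
  }
  C <- 1 - ties / (N^3 - N)
  if (C <= 0) 0 else H / C
}

# Dunn z statistics by the direct formula on rank means
dunn_oracle <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- midranks_oracle(x)
  idx <- rep(seq_along(groups), lengths(groups))
  ties <- 0
  for (v in unique(x)) {
    t <- sum(x == v)
    ties <- ties + t^3 - t
  }
  s2 <- N * (N + 1) / 12 - ties / (12 * (N - 1))
  out <- NULL
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    ni <- sum(idx == i); nj <- sum(idx == j)
    se <- sqrt(s2 * (1 / ni + 1 / nj))
    z <- if (se == 0) 0 else
      (mean(r[idx == i]) - mean(r[idx == j])) / se
    out <- rbind(out, data.frame(i = i, j = j, z = z))
  }
  out
}

# Yates-corrected 2x2 chi-squared by the closed form
yates_oracle <- function(k1, n1, k2, n2) {
  a <- k1; b <- n1 - k1; c_ <- k2; d <- n2 - k2
  n <- n1 + n2
  dev <- max(0, abs(a * d - b * c_) - n / 2)
  n * dev^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# a strain model + plates used by several tests
make_test_batch <- function(protein = "proteinaceous",
                            localization = "particulate",
                            onset = -8, A = 1e-3, gamma = 0.5,
                            seed = 1, n_replicates = 3, n_wells = 32) {
  model <- spectrum_model(
    spectrum_component(protein, localization, onset_T = onset,
                       amplitude_A = A, slope_gamma = gamma))
  simulate_treatment_batch(model, droplet_spec(20, 100),
                           default_protocol(), n_wells = n_wells,
                           n_replicates = n_replicates, seed = seed)
}

fit_arm <- function(batch, arm, level = 0.95) {
  lapply(seq_along(batch[[arm]]), function(r)
    fit_inp_spectrum(batch[[arm]][[r]], control = batch$control[[r]],
                     level = level))
}
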