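#' Two-sample test of equal proportions with continuity correction
#'
#' Chi-squared test on the 2x2 table of successes and failures with the
#' Yates continuity correction; the correction term is capped so the
#' corrected deviation can never go negative. Degenerate margins (pooled
#' successes or failures all zero) yield statistic 0 and p = 1 with a
#' warning.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param continuity apply the Yates correction (default TRUE).
#' @return an object of class \code{htest} with \code{statistic} (the
#'   chi-squared value), \code{parameter} (df = 1), \code{p.value},
#'   \code{estimate} (the two proportions).
#' @examples
#' prop_test_2x2(10, 32, 0, 17)
#' @export
prop_test_2x2 <- function(k1, n1, k2, n2, continuity = TRUE) {
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2 || n1 < 1 || n2 < 1)
    stop("need 0 <= k_i <= n_i and n_i >= 1")
  a <- k1; b <- n1 - k1; c_ <- k2; d <- n2 - k2
  n <- n1 + n2
  meth <- "2-sample test for equality of proportions"
  if ((a + c_) == 0 || (b + d) == 0) {
    warning("degenerate margin: all successes or all failures; ",
            "statistic set to 0")
    stat <- 0; p <- 1
  } else {
    dev <- abs(a * d - b * c_)
    if (continuity) {
      dev <- max(0, dev - n / 2)
      meth <- paste(meth, "with continuity correction")
    }
    stat <- n * dev^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(
    list(statistic = c("X-squared" = stat), parameter = c(df = 1),
         p.value = p,
         estimate = c("prop 1" = k1 / n1, "prop 2" = k2 / n2),
         method = meth,
         data.name = sprintf("%d/%d vs %d/%d", k1, n1, k2, n2)),
    class = "htest")
}

# mid-ranks of the pooled data plus the tie-correction ingredients
pooled_ranks <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)          # mid-ranks for ties
  tab <- table(x)
  list(ranks = r, N = length(x), tie_sum = sum(tab^3 - tab),
       sizes = lengths(groups),
       idx = rep(seq_along(groups), lengths(groups)))
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic on mid-ranks with the standard tie correction and the
#' chi-squared approximation on k - 1 degrees of freedom. When all
#' pooled values are identical the statistic is 0 and p = 1.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return an object of class \code{htest}.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of at least 2 numeric vectors")
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  p <- pooled_ranks(groups)
  if (p$N < 3) stop("need at least 3 observations in total")
  k <- length(groups)
  R <- tapply(p$ranks, p$idx, sum)
  H <- 12 / (p$N * (p$N + 1)) * sum(R^2 / p$sizes) - 3 * (p$N + 1)
  C <- 1 - p$tie_sum / (p$N^3 - p$N)
  if (C <= 0) { H <- 0 } else { H <- H / C }
  H <- max(0, H)   # guard tiny negative rounding
  pv <- if (H == 0) 1 else stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  structure(
    list(statistic = c("Kruskal-Wallis chi-squared" = H),
         parameter = c(df = k - 1), p.value = pv,
         method = "Kruskal-Wallis rank sum test",
         data.name = sprintf("%d groups, N = %d", k, p$N)),
    class = "htest")
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics from rank means with the tie-corrected pooled
#' variance, two-sided p-values, and optional multiplicity adjustment
#' across the k(k-1)/2 pairs. Unadjusted p-values are the default.
#'
#' @param groups list of >= 2 non-empty numeric vectors; names are used
#'   to label pairs.
#' @param adjustment one of \code{"none"}, \code{"holm"}, \code{"bh"}.
#' @return a data.frame of class \code{dunn_test} with one row per pair:
#'   \code{group1}, \code{group2}, \code{z}, \code{p_value},
#'   \code{p_adjusted}.
#' @examples
#' dunn_posthoc(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
dunn_posthoc <- function(groups, adjustment = c("none", "holm", "bh")) {
  adjustment <- match.arg(adjustment)
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of at least 2 numeric vectors")
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  p <- pooled_ranks(groups)
  rbar <- tapply(p$ranks, p$idx, mean)
  sigma2 <- p$N * (p$N + 1) / 12 - p$tie_sum / (12 * (p$N - 1))
  pairs <- utils::combn(length(groups), 2)
  z <- pv <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(sigma2 * (1 / p$sizes[i1] + 1 / p$sizes[i2]))
    z[j] <- if (se == 0) 0 else (rbar[i1] - rbar[i2]) / se
    pv[j] <- if (se == 0) 1 else 2 * stats::pnorm(-abs(z[j]))
  }
  padj <- switch(adjustment,
                 none = pv,
                 holm = stats::p.adjust(pv, "holm"),
                 bh = stats::p.adjust(pv, "BH"))
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    z = z, p_value = pv, p_adjusted = padj,
                    stringsAsFactors = FALSE)
  attr(out, "adjustment") <- adjustment
  class(out) <- c("dunn_test", "data.frame")
  out
}
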