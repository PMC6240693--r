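#' Cumulative INP concentration from a corrected frozen fraction
#'
#' The Vali relation for immersion-freezing droplet assays under the
#' singular approximation: with frozen fraction \eqn{f} (background
#' corrected), cell concentration \eqn{c} (cells/uL) and droplet volume
#' \eqn{V} (uL), the cumulative number of ice-nucleating particles per
#' cell active at or above the setpoint is
#' \deqn{N_n(T) = -\ln(1 - f) / (c V).}
#' The function is strictly increasing in \code{ff_corrected} and
#' inversely proportional to both \code{c} and \code{V}.
#'
#' @param ff_corrected background-corrected frozen fraction in [0, 1).
#' @param droplet a \code{\link{droplet_spec}} with
#'   \code{cells_per_uL > 0}, or NULL when \code{cV} is given directly.
#' @param cV optional direct product c*V (cells per droplet); overrides
#'   \code{droplet}.
#' @return INP per cell (1/cell).
#' @examples
#' inp_per_cell(1 - exp(-1), droplet_spec(20, 100))  # 1/2000
#' inp_per_cell(0.5, cV = 1)                         # log(2)
#' @export
inp_per_cell <- function(ff_corrected, droplet = NULL, cV = NULL) {
  if (is.null(cV)) {
    stopifnot(inherits(droplet, "droplet_spec"))
    if (droplet$cells_per_uL <= 0)
      stop("cells_per_uL must be > 0 for a per-cell spectrum; ",
           "use per-droplet mode for cell-free material")
    cV <- droplet$cells_per_uL * droplet$volume_uL
  }
  if (any(cV <= 0)) stop("cV must be positive")
  if (any(ff_corrected < 0 | ff_corrected >= 1, na.rm = TRUE))
    stop("ff_corrected must lie in [0, 1); a fully frozen plate is a ",
         "saturation signal, not a point estimate")
  -log1p(-ff_corrected) / cV
}

#' Detection limits of a plate in INP per cell
#'
#' The smallest resolvable concentration corresponds to a single frozen
#' well out of \code{n_wells}; the largest to near-saturation, evaluated
#' at frozen fraction \eqn{(n - 0.5)/n} (a half-well continuity
#' correction, since the estimator diverges at full saturation).
#'
#' @param n_wells wells per plate (>= 2).
#' @param droplet a \code{\link{droplet_spec}}, or NULL with \code{cV}.
#' @param cV cells per droplet, overriding \code{droplet}.
#' @return named numeric \code{c(lower, upper)} in 1/cell.
#' @examples
#' detection_limits(32, cV = 2000)
#' @export
detection_limits <- function(n_wells, droplet = NULL, cV = NULL) {
  if (n_wells < 2) stop("n_wells must be >= 2")
  if (is.null(cV)) {
    stopifnot(inherits(droplet, "droplet_spec"))
    cV <- droplet$cells_per_uL * droplet$volume_uL
  }
  if (cV <= 0) stop("cV must be positive")
  c(lower = -log1p(-1 / n_wells) / cV,
    upper = -log1p(-(n_wells - 0.5) / n_wells) / cV)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, used for the
#' frozen fraction and propagated through the Vali equation (a monotone
#' map) to give confidence bounds on INP spectra.
#'
#' @param k_frozen number of frozen wells (0..n).
#' @param n_wells total wells.
#' @param level confidence level in (0, 1).
#' @return named numeric \code{c(low, high)}.
#' @examples
#' binomial_ci(8, 16)
#' @export
binomial_ci <- function(k_frozen, n_wells, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (k_frozen < 0 || k_frozen > n_wells) stop("need 0 <= k <= n")
  a <- (1 - level) / 2
  low <- if (k_frozen == 0) 0 else
    stats::qbeta(a, k_frozen, n_wells - k_frozen + 1)
  high <- if (k_frozen == n_wells) 1 else
    stats::qbeta(1 - a, k_frozen + 1, n_wells - k_frozen)
  c(low = low, high = high)
}

SPECTRUM_FLAGS <- c("ok", "below_detection", "saturated",
                    "negative_removed")

#' Fit a per-cell INP spectrum from a droplet freezing assay
#'
#' The central estimator of the package. From the cumulative frozen-well
#' counts of one plate (and, optionally, a buffer-control plate run under
#' the same protocol) it computes the background-corrected frozen
#' fraction at every setpoint and transforms it through the Vali equation
#' into a cumulative INP-per-cell spectrum with exact binomial confidence
#' bounds and per-setpoint quality flags:
#' \describe{
#'   \item{ok}{estimate at or above the single-well detection limit}
#'   \item{below_detection}{corrected freezing too weak to resolve
#'     (fewer than one well above background)}
#'   \item{saturated}{all wells frozen above background; the estimator
#'     diverges and a lower bound evaluated at frozen fraction
#'     \eqn{(n-0.5)/n} is reported instead, with an infinite upper bound}
#'   \item{negative_removed}{control froze more than the sample; the
#'     setpoint is excluded and carries no estimate}
#' }
#' Cell-free material (buffer controls, filtrates) has no per-cell scale;
#' for such plates the spectrum is reported per droplet, normalising by
#' the droplet volume alone, and the object is labelled accordingly.
#'
#' @param assay a \code{\link{plate_assay}} for the sample.
#' @param control optional \code{plate_assay} (or \code{ff_curve}) for
#'   the buffer control; NULL means no background freezing.
#' @param level confidence level for the Clopper-Pearson bounds.
#' @param mode \code{"auto"} picks per-cell when the droplet carries
#'   cells and per-droplet otherwise; can be forced.
#' @return an object of class \code{inp_spectrum}: a per-setpoint table
#'   of estimates, bounds and flags plus plate metadata and detection
#'   limits. Methods: \code{print}, \code{summary}, \code{plot},
#'   \code{as.data.frame}, \code{coef}, \code{confint}.
#' @examples
#' a <- plate_assay("s", "untreated", "r1", droplet_spec(20, 100),
#'                  freeze_protocol(c(-10, -12, -14)), c(4, 12, 16), 16)
#' fit_inp_spectrum(a)
#' @export
fit_inp_spectrum <- function(assay, control = NULL, level = 0.95,
                             mode = c("auto", "per_cell", "per_droplet")) {
  stopifnot(inherits(assay, "plate_assay"))
  mode <- match.arg(mode)
  ffs <- compute_frozen_fraction(assay, role = "sample")
  if (is.null(control)) {
    ffc <- ffs
    ffc$frozen_fraction <- rep(0, length(ffs$setpoints))
    ffc$k <- rep(0L, length(ffs$setpoints))
    ffc$role <- "control"
  } else if (inherits(control, "plate_assay")) {
    ffc <- compute_frozen_fraction(control, role = "control")
  } else if (inherits(control, "ff_curve")) {
    ffc <- control
  } else stop("control must be a plate_assay or ff_curve")
  corr <- correct_background(ffs, ffc)

  if (mode == "auto")
    mode <- if (assay$droplet$cells_per_uL > 0) "per_cell" else "per_droplet"
  if (mode == "per_cell" && assay$droplet$cells_per_uL <= 0)
    stop("per-cell spectrum requested but the droplet carries no cells")
  norm <- if (mode == "per_cell")
    assay$droplet$cells_per_uL * assay$droplet$volume_uL
  else assay$droplet$volume_uL
  dl <- detection_limits(max(assay$n_wells, 2), cV = norm)

  m <- length(ffs$setpoints)
  est <- lo <- hi <- rep(NA_real_, m)
  flag <- character(m)
  sat_ff <- (assay$n_wells - 0.5) / assay$n_wells
  for (i in seq_len(m)) {
    if (corr$excluded[i]) { flag[i] <- "negative_removed"; next }
    f <- corr$ff_corrected[i]
    ci <- binomial_ci(ffs$k[i], ffs$n_wells, level)
    ci_lo_f <- max(0, min(ci[["low"]] - ffc$frozen_fraction[i], 1))
    ci_hi_f <- max(0, min(ci[["high"]] - ffc$frozen_fraction[i], 1))
    if (f >= 1 || ffs$k[i] == assay$n_wells) {
      # a fully frozen plate is censored whatever the control did: only
      # a lower bound (at corrected fraction (n-0.5)/n - FF_control) is
      # known
      flag[i] <- "saturated"
      f_sat <- max(0, min(sat_ff - ffc$frozen_fraction[i], sat_ff))
      est[i] <- -log1p(-f_sat) / norm
      lo[i] <- -log1p(-min(ci_lo_f, f_sat)) / norm
      hi[i] <- Inf
      next
    }
    est[i] <- -log1p(-f) / norm
    lo[i] <- -log1p(-min(ci_lo_f, f)) / norm
    hi[i] <- if (ci_hi_f >= 1) Inf else -log1p(-ci_hi_f) / norm
    flag[i] <- if (est[i] >= dl["lower"]) "ok" else "below_detection"
  }
  structure(
    list(setpoints = ffs$setpoints, estimate = est, ci_low = lo,
         ci_high = hi, flag = flag, mode = mode, level = level,
         n_wells = assay$n_wells, droplet = assay$droplet,
         protocol = assay$protocol, detection = dl,
         sample_id = assay$sample_id, treatment = assay$treatment,
         replicate_id = assay$replicate_id,
         dilution_factor = assay$droplet$dilution_factor),
    class = "inp_spectrum")
}

#' @export
as.data.frame.inp_spectrum <- function(x, ...) {
  data.frame(sample_id = x$sample_id, treatment = x$treatment,
             replicate_id = x$replicate_id,
             dilution_factor = x$dilution_factor,
             temperature_C = x$setpoints, estimate = x$estimate,
             ci_low = x$ci_low, ci_high = x$ci_high, flag = x$flag,
             mode = x$mode, stringsAsFactors = FALSE)
}

#' @export
print.inp_spectrum <- function(x, digits = 4, ...) {
  unit <- if (x$mode == "per_cell") "INP/cell" else "INP/droplet"
  cat(sprintf("INP spectrum [%s]: %s / %s / rep %s (%d wells)\n", unit,
              x$sample_id, x$treatment, x$replicate_id, x$n_wells))
  df <- as.data.frame(x)[, c("temperature_C", "estimate", "ci_low",
                             "ci_high", "flag")]
  df$estimate <- signif(df$estimate, digits)
  df$ci_low <- signif(df$ci_low, digits)
  df$ci_high <- signif(df$ci_high, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.inp_spectrum <- function(object, ...) {
  ok <- object$flag == "ok"
  onset <- if (any(ok)) max(object$setpoints[ok]) else NA_real_
  out <- list(sample_id = object$sample_id, treatment = object$treatment,
              mode = object$mode, n_ok = sum(ok),
              n_saturated = sum(object$flag == "saturated"),
              n_below_detection = sum(object$flag == "below_detection"),
              n_negative_removed = sum(object$flag == "negative_removed"),
              onset = onset,
              max_estimate = if (any(ok)) max(object$estimate[ok]) else
                NA_real_,
              detection = object$detection)
  class(out) <- "summary.inp_spectrum"
  out
}

#' @export
print.summary.inp_spectrum <- function(x, ...) {
  cat(sprintf("INP spectrum summary for %s (%s, %s mode)\n", x$sample_id,
              x$treatment, x$mode))
  cat(sprintf("  setpoints ok/saturated/below-detection/removed: %d/%d/%d/%d\n",
              x$n_ok, x$n_saturated, x$n_below_detection,
              x$n_negative_removed))
  if (!is.na(x$onset))
    cat(sprintf("  first activity at %g degC; max %.3g per unit\n",
                x$onset, x$max_estimate))
  cat(sprintf("  detection limits: [%.3g, %.3g]\n", x$detection["lower"],
              x$detection["upper"]))
  invisible(x)
}

#' @export
coef.inp_spectrum <- function(object, ...) {
  stats::setNames(object$estimate, paste0(object$setpoints, "C"))
}

#' @export
confint.inp_spectrum <- function(object, parm, level, ...) {
  m <- cbind(low = object$ci_low, high = object$ci_high)
  rownames(m) <- paste0(object$setpoints, "C")
  m
}

#' @export
plot.inp_spectrum <- function(x, log = "y", ...) {
  ok <- x$flag %in% c("ok", "saturated")
  if (!any(ok)) {
    warning("no estimable setpoints to plot")
    return(invisible(x))
  }
  ylab <- if (x$mode == "per_cell") "INP per cell" else "INP per droplet"
  graphics::plot(x$setpoints[ok], x$estimate[ok], type = "b", pch = 16,
                 xlim = rev(range(x$setpoints)), log = log,
                 xlab = "Temperature (degC)", ylab = ylab, ...)
  graphics::arrows(x$setpoints[ok], pmax(x$ci_low[ok], .Machine$double.xmin),
                   x$setpoints[ok],
                   ifelse(is.finite(x$ci_high[ok]), x$ci_high[ok],
                          x$estimate[ok]),
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Merge a dilution series of INP spectra
#'
#' Per setpoint, only dilutions whose flag is \code{ok} contribute; the
#' combined estimate is the arithmetic mean of the usable per-cell
#' estimates (equal weights) and confidence bounds are averaged the same
#' way. Where no dilution is usable the flags propagate (saturated wins
#' over below_detection over negative_removed, so the most informative
#' failure is retained).
#'
#' @param spectra list of \code{inp_spectrum} objects on one protocol.
#' @return an \code{inp_spectrum} with \code{dilution_factor = NA}.
#' @export
merge_dilutions <- function(spectra) {
  if (length(spectra) == 0L) stop("no spectra supplied")
  stopifnot(all(vapply(spectra, inherits, TRUE, "inp_spectrum")))
  ref <- spectra[[1L]]
  for (s in spectra[-1L])
    if (!same_protocol(s$protocol, ref$protocol))
      stop("spectra use different temperature protocols")
  m <- length(ref$setpoints)
  est <- lo <- hi <- rep(NA_real_, m)
  flag <- character(m)
  for (i in seq_len(m)) {
    fl <- vapply(spectra, function(s) s$flag[i], "")
    use <- fl == "ok"
    if (any(use)) {
      est[i] <- mean(vapply(spectra[use], function(s) s$estimate[i], 0))
      lo[i] <- mean(vapply(spectra[use], function(s) s$ci_low[i], 0))
      hi[i] <- mean(vapply(spectra[use], function(s) s$ci_high[i], 0))
      flag[i] <- "ok"
    } else {
      flag[i] <- if (any(fl == "saturated")) "saturated"
      else if (any(fl == "below_detection")) "below_detection"
      else "negative_removed"
      if (flag[i] == "saturated") {
        sat <- fl == "saturated"
        est[i] <- mean(vapply(spectra[sat], function(s) s$estimate[i], 0))
        lo[i] <- mean(vapply(spectra[sat], function(s) s$ci_low[i], 0))
        hi[i] <- Inf
      }
    }
  }
  out <- ref
  out$estimate <- est; out$ci_low <- lo; out$ci_high <- hi
  out$flag <- flag
  out$dilution_factor <- NA_real_
  out$detection <- c(
    lower = min(vapply(spectra, function(s) s$detection["lower"], 0)),
    upper = max(vapply(spectra, function(s) s$detection["upper"], 0)))
  out
}

#' Three-replicate detection-limit filter
#'
#' A strain's freezing profile is measured on three biological
#' replicates; the strain is retained only when every replicate shows
#' detectable activity at some setpoint: an \code{ok} estimate at or
#' above its own single-well detection limit, or a \code{saturated}
#' setpoint (activity beyond the upper limit). Otherwise it is dropped
#' with the failing replicate named.
#'
#' @param spectra list of exactly 3 \code{inp_spectrum} replicates.
#' @return list with \code{keep} (logical), \code{reason} (character or
#'   NULL) and \code{spectra} (the retained set, or empty list).
#' @export
replicate_filter <- function(spectra) {
  if (length(spectra) != 3L)
    stop("the freezing-profile design uses exactly 3 biological ",
         "replicates; got ", length(spectra))
  stopifnot(all(vapply(spectra, inherits, TRUE, "inp_spectrum")))
  for (j in seq_along(spectra)) {
    s <- spectra[[j]]
    detectable <- (s$flag == "ok" & s$estimate >= s$detection["lower"]) |
      s$flag == "saturated"
    if (!any(detectable))
      return(list(keep = FALSE,
                  reason = sprintf(
                    "replicate %s entirely below detection limit",
                    s$replicate_id),
                  spectra = list()))
  }
  list(keep = TRUE, reason = NULL, spectra = spectra)
}
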