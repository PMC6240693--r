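#' Screen a strain for ice nucleation activity
#'
#' The screening rule: a strain is INA-positive when at least half of the
#' replicate wells are frozen at the screening temperature (-24 degC in
#' the standard protocol). Applied to the raw sample frozen fraction by
#' default (no background correction at the screening stage); pass a
#' corrected fraction if desired.
#'
#' @param frozen_count frozen wells at the screening setpoint.
#' @param n_wells total wells.
#' @param cutoff frozen-fraction threshold, inclusive (default 0.5).
#' @return logical flag.
#' @examples
#' screen_ina(8, 16)   # TRUE: boundary is inclusive
#' screen_ina(7, 16)   # FALSE
#' @export
screen_ina <- function(frozen_count, n_wells, cutoff = 0.5) {
  if (frozen_count < 0 || frozen_count > n_wells)
    stop("need 0 <= frozen_count <= n_wells")
  frozen_count / n_wells >= cutoff
}

#' Screen a plate assay at a given setpoint
#'
#' Convenience wrapper locating the screening temperature in the
#' protocol; errors if the setpoint is absent.
#'
#' @param assay a \code{\link{plate_assay}}.
#' @param at screening temperature (degC), default -24.
#' @param cutoff inclusive frozen-fraction threshold.
#' @return logical flag.
#' @export
screen_ina_assay <- function(assay, at = -24, cutoff = 0.5) {
  stopifnot(inherits(assay, "plate_assay"))
  i <- match(at, assay$protocol$setpoints)
  if (is.na(i))
    stop(sprintf("screening setpoint %g degC is not in the protocol", at))
  screen_ina(assay$frozen_counts[i], assay$n_wells, cutoff)
}

#' Confirm ice nucleation activity over repeated screens
#'
#' A strain is confirmed only when every one of at least two independent
#' screening runs is positive.
#'
#' @param screens logical vector of screen outcomes (length >= 2).
#' @return logical flag.
#' @export
confirm_ina <- function(screens) {
  if (length(screens) < 2L)
    stop("confirmation requires at least 2 independent screens")
  all(as.logical(screens))
}

#' Onset temperature from replicate spectra
#'
#' The warmest setpoint at which all replicates show activity above
#' background: an \code{ok} estimate greater than zero, or a
#' \code{saturated} setpoint (saturation is extreme activity, not its
#' absence); \code{NA} if no such setpoint exists. Requiring all
#' replicates (rather than any) mirrors the three-replicate quality
#' filter.
#'
#' @param spectra list of \code{inp_spectrum} replicates (usually 3).
#' @param rule \code{"all"} (default) or \code{"any"} replicates active.
#' @return onset temperature in degC, or \code{NA_real_}.
#' @export
onset_temperature <- function(spectra, rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "inp_spectrum")))
  ref <- spectra[[1L]]
  active <- vapply(spectra, function(s)
    (s$flag == "ok" & !is.na(s$estimate) & s$estimate > 0) |
      s$flag == "saturated", logical(length(ref$setpoints)))
  active <- matrix(active, nrow = length(ref$setpoints))
  hit <- if (rule == "all") apply(active, 1, all) else apply(active, 1, any)
  if (!any(hit)) return(NA_real_)
  max(ref$setpoints[hit])
}

#' Temperature class of an INA strain
#'
#' Bins the onset temperature into the activity classes used for
#' reporting: warm (>= -6 degC), mid (-6 > T >= -12), cool
#' (-12 > T >= -18), cold (-18 > T >= -24); onsets below the assay range
#' (< -24) return \code{"none"}, as does a missing onset.
#'
#' @param onset onset temperature in degC (<= -2), or NA.
#' @return one of \code{"warm"}, \code{"mid"}, \code{"cool"},
#'   \code{"cold"}, \code{"none"}.
#' @examples
#' temperature_class(-5)    # warm
#' temperature_class(-11)   # mid
#' temperature_class(-20)   # cold
#' @export
temperature_class <- function(onset) {
  if (is.na(onset)) return("none")
  if (onset > -2) stop("onset must be <= -2 degC (within the assay range)")
  if (onset >= -6) "warm"
  else if (onset >= -12) "mid"
  else if (onset >= -18) "cool"
  else if (onset >= -24) "cold"
  else "none"
}

#' Strain-level INA decision
#'
#' Combines screening, confirmation and onset into one record.
#'
#' @param screens logical vector of >= 2 screen outcomes.
#' @param replicate_spectra list of 3 replicate \code{inp_spectrum}s, or
#'   NULL when the strain was not profiled.
#' @param onset_rule passed to \code{\link{onset_temperature}}.
#' @return object of class \code{ina_decision} with fields
#'   \code{screened_positive}, \code{confirmed}, \code{onset_temperature},
#'   \code{temperature_class}.
#' @export
ina_decision <- function(screens, replicate_spectra = NULL,
                         onset_rule = "all") {
  screened <- any(as.logical(screens))
  confirmed <- length(screens) >= 2L && confirm_ina(screens)
  onset <- NA_real_
  if (confirmed && !is.null(replicate_spectra)) {
    rf <- replicate_filter(replicate_spectra)
    if (rf$keep) onset <- onset_temperature(rf$spectra, rule = onset_rule)
  }
  structure(
    list(screened_positive = screened, confirmed = confirmed,
         onset_temperature = onset,
         temperature_class = temperature_class(onset)),
    class = "ina_decision")
}

#' @export
print.ina_decision <- function(x, ...) {
  cat(sprintf(
    "INA decision: screened %s, confirmed %s, onset %s, class %s\n",
    if (x$screened_positive) "positive" else "negative",
    if (x$confirmed) "yes" else "no",
    if (is.na(x$onset_temperature)) "none" else
      paste0(x$onset_temperature, " degC"),
    x$temperature_class))
  invisible(x)
}
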