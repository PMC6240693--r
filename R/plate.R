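TREATMENTS <- c("untreated", "heated", "filtrate", "heated_filtrate",
                "axenic", "control")

#' Plate assay: cumulative frozen-well counts along a cooling ramp
#'
#' One plate assay records, for a single sample x treatment x replicate x
#' dilution, the cumulative number of frozen wells at each setpoint of the
#' protocol. Counts are cumulative because a frozen well stays frozen as
#' the plate cools; decreasing counts are rejected as malformed input
#' rather than silently repaired.
#'
#' @param sample_id,replicate_id identifiers (character scalars).
#' @param treatment one of \code{"untreated"}, \code{"heated"},
#'   \code{"filtrate"}, \code{"heated_filtrate"}, \code{"axenic"},
#'   \code{"control"}.
#' @param droplet a \code{\link{droplet_spec}}.
#' @param protocol a \code{\link{freeze_protocol}}.
#' @param frozen_counts integer vector, one cumulative count per setpoint,
#'   each in [0, n_wells], non-decreasing along the ramp.
#' @param n_wells number of replicate wells on the plate (>= 1).
#' @return an object of class \code{plate_assay}.
#' @examples
#' plate_assay("S2RM-16", "untreated", "r1", droplet_spec(20, 100),
#'             default_protocol(), c(0, 0, 1, 2, 4, 8, 10, 12, 14, 15,
#'                                   16, 16, 16, 16), n_wells = 16)
#' @export
plate_assay <- function(sample_id, treatment, replicate_id, droplet,
                        protocol, frozen_counts, n_wells) {
  treatment <- match.arg(treatment, TREATMENTS)
  stopifnot(inherits(droplet, "droplet_spec"),
            inherits(protocol, "freeze_protocol"))
  if (!is.numeric(n_wells) || length(n_wells) != 1L || n_wells < 1 ||
      n_wells != round(n_wells))
    stop("n_wells must be a single positive integer")
  frozen_counts <- as.numeric(frozen_counts)
  if (length(frozen_counts) != length(protocol$setpoints))
    stop(sprintf("frozen_counts has %d entries but the protocol has %d setpoints",
                 length(frozen_counts), length(protocol$setpoints)))
  if (any(frozen_counts != round(frozen_counts)) || anyNA(frozen_counts))
    stop("frozen_counts must be whole numbers")
  bad_hi <- which(frozen_counts > n_wells | frozen_counts < 0)
  if (length(bad_hi))
    stop(sprintf("frozen count out of [0, n_wells] at setpoint %g degC",
                 protocol$setpoints[bad_hi[1]]))
  if (length(frozen_counts) > 1L) {
    dec <- which(diff(frozen_counts) < 0)
    if (length(dec))
      stop(sprintf(
        "frozen counts decrease at setpoint %g degC; counts must be cumulative",
        protocol$setpoints[dec[1] + 1L]))
  }
  structure(
    list(sample_id = as.character(sample_id), treatment = treatment,
         replicate_id = as.character(replicate_id), droplet = droplet,
         protocol = protocol, frozen_counts = frozen_counts,
         n_wells = as.integer(n_wells)),
    class = "plate_assay")
}

#' @export
print.plate_assay <- function(x, ...) {
  cat(sprintf("Plate assay: %s / %s / rep %s, %d wells x%g dilution\n",
              x$sample_id, x$treatment, x$replicate_id, x$n_wells,
              x$droplet$dilution_factor))
  cat(sprintf("  %d..%d wells frozen over %g..%g degC\n",
              x$frozen_counts[1], x$frozen_counts[length(x$frozen_counts)],
              x$protocol$setpoints[1],
              x$protocol$setpoints[length(x$protocol$setpoints)]))
  invisible(x)
}

#' Frozen fraction curve of a plate assay
#'
#' The frozen fraction at a setpoint is the number of frozen replicate
#' wells divided by the total number of wells. The curve inherits the
#' cumulative monotonicity of the counts.
#'
#' @param assay a \code{\link{plate_assay}}.
#' @param role whether the curve is a \code{"sample"} or a buffer
#'   \code{"control"}; defaults to the assay's treatment label.
#' @return an object of class \code{ff_curve} with fields
#'   \code{setpoints}, \code{frozen_fraction}, \code{k} (counts),
#'   \code{n_wells}, \code{role}, \code{droplet}, \code{protocol}.
#' @examples
#' a <- plate_assay("s", "untreated", "r1", droplet_spec(20, 100),
#'                  freeze_protocol(c(-10, -12)), c(8, 16), 16)
#' compute_frozen_fraction(a)
#' @export
compute_frozen_fraction <- function(assay, role = NULL) {
  stopifnot(inherits(assay, "plate_assay"))
  if (is.null(role))
    role <- if (assay$treatment == "control") "control" else "sample"
  role <- match.arg(role, c("sample", "control"))
  structure(
    list(setpoints = assay$protocol$setpoints,
         frozen_fraction = assay$frozen_counts / assay$n_wells,
         k = assay$frozen_counts, n_wells = assay$n_wells, role = role,
         droplet = assay$droplet, protocol = assay$protocol,
         sample_id = assay$sample_id, treatment = assay$treatment,
         replicate_id = assay$replicate_id),
    class = "ff_curve")
}

#' @export
print.ff_curve <- function(x, digits = 3, ...) {
  cat(sprintf("Frozen-fraction curve (%s, n = %d wells)\n", x$role,
              x$n_wells))
  print(data.frame(temperature_C = x$setpoints,
                   frozen_fraction = round(x$frozen_fraction, digits)),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.ff_curve <- function(x, ...) {
  graphics::plot(x$setpoints, x$frozen_fraction, type = "b", pch = 16,
                 xlim = rev(range(x$setpoints)), ylim = c(0, 1),
                 xlab = "Temperature (degC)", ylab = "Frozen fraction",
                 ...)
  invisible(x)
}

#' Background-correct a sample frozen-fraction curve
#'
#' Subtracts the buffer-control frozen fraction from the sample frozen
#' fraction at every setpoint. Setpoints where the difference is negative
#' are flagged \code{"negative_removed"} and carry no estimate downstream;
#' they are excluded rather than clipped to zero.
#'
#' @param sample,control \code{ff_curve} objects sharing a protocol.
#' @return a list with \code{setpoints}, \code{ff_corrected} (NA where
#'   excluded), \code{excluded} (logical), plus the sample metadata;
#'   class \code{ff_corrected}.
#' @export
correct_background <- function(sample, control) {
  stopifnot(inherits(sample, "ff_curve"), inherits(control, "ff_curve"))
  if (!same_protocol(sample$protocol, control$protocol))
    stop("sample and control curves use different temperature protocols")
  d <- sample$frozen_fraction - control$frozen_fraction
  excluded <- d < 0
  d[excluded] <- NA_real_
  structure(
    list(setpoints = sample$setpoints, ff_corrected = d,
         excluded = excluded, sample = sample, control = control),
    class = "ff_corrected")
}
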