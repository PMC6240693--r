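#' Temperature protocol for a droplet freezing assay
#'
#' A protocol is the ordered set of sub-zero temperature setpoints through
#' which a well plate is cooled, together with the hold time at each
#' setpoint. It is the x-axis of every frozen-fraction curve and INP
#' spectrum in the package. Setpoints must be strictly decreasing (cooling
#' ramp), all below 0 degC, and consecutive steps must fall within the
#' permitted range (1--2 degC by default, matching the standard screening
#' ramp from -2 to -28 degC with 30-min holds).
#'
#' @param setpoints numeric vector of temperatures in degC, strictly
#'   decreasing, all < 0.
#' @param hold_minutes positive hold duration per setpoint (minutes).
#' @param step_range permitted range (degC) for the absolute difference
#'   between consecutive setpoints; length-2 numeric.
#' @return an object of class \code{freeze_protocol}.
#' @examples
#' default_protocol()
#' freeze_protocol(seq(-2, -28, by = -1))
#' @export
freeze_protocol <- function(setpoints, hold_minutes = 30,
                            step_range = c(1, 2)) {
  setpoints <- as.numeric(setpoints)
  if (length(setpoints) < 1L || anyNA(setpoints))
    stop("setpoints must be a non-empty numeric vector without NA")
  if (any(setpoints >= 0))
    stop("all setpoints must be below 0 degC")
  if (length(setpoints) > 1L) {
    steps <- -diff(setpoints)
    if (any(steps <= 0))
      stop("setpoints must be strictly decreasing (a cooling ramp)")
    tol <- 1e-8
    if (any(steps < step_range[1] - tol | steps > step_range[2] + tol))
      stop(sprintf(
        "consecutive setpoint gaps must lie in [%g, %g] degC; found %g",
        step_range[1], step_range[2], steps[which.max(
          pmax(step_range[1] - steps, steps - step_range[2]))]))
  }
  if (!is.numeric(hold_minutes) || length(hold_minutes) != 1L ||
      hold_minutes <= 0)
    stop("hold_minutes must be a single positive number")
  structure(
    list(setpoints = setpoints, hold_minutes = as.numeric(hold_minutes)),
    class = "freeze_protocol")
}

#' Default screening protocol: -2 to -28 degC in 2 degC steps, 30-min holds
#'
#' @return a \code{freeze_protocol} with 14 setpoints.
#' @export
default_protocol <- function() {
  freeze_protocol(seq(-2, -28, by = -2), hold_minutes = 30)
}

#' @export
print.freeze_protocol <- function(x, ...) {
  cat(sprintf(
    "Freezing protocol: %d setpoints from %g to %g degC, %g min holds\n",
    length(x$setpoints), x$setpoints[1],
    x$setpoints[length(x$setpoints)], x$hold_minutes))
  invisible(x)
}

#' @export
length.freeze_protocol <- function(x) length(x$setpoints)

same_protocol <- function(a, b) {
  isTRUE(all.equal(a$setpoints, b$setpoints))
}

#' Droplet specification
#'
#' Describes the droplets of one plate: volume, microalgal cell
#' concentration, and the dilution factor relative to the stock suspension.
#' A zero cell concentration is permitted only for cell-free material
#' (buffer controls and filtrates), in which case spectra are reported per
#' droplet rather than per cell.
#'
#' @param volume_uL droplet volume in microlitres (> 0; assays typically use
#'   20--30 uL).
#' @param cells_per_uL microalgal cell concentration in the droplet
#'   (cells/uL, >= 0).
#' @param dilution_factor multiplicative dilution from stock (>= 1).
#' @return an object of class \code{droplet_spec}.
#' @examples
#' droplet_spec(20, 100)
#' @export
droplet_spec <- function(volume_uL = 20, cells_per_uL = 0,
                         dilution_factor = 1) {
  if (!is.numeric(volume_uL) || length(volume_uL) != 1L || volume_uL <= 0)
    stop("volume_uL must be a single positive number")
  if (!is.numeric(cells_per_uL) || length(cells_per_uL) != 1L ||
      cells_per_uL < 0)
    stop("cells_per_uL must be a single non-negative number")
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1L ||
      dilution_factor < 1)
    stop("dilution_factor must be >= 1")
  structure(
    list(volume_uL = as.numeric(volume_uL),
         cells_per_uL = as.numeric(cells_per_uL),
         dilution_factor = as.numeric(dilution_factor)),
    class = "droplet_spec")
}

#' @export
print.droplet_spec <- function(x, ...) {
  cat(sprintf("Droplets: %g uL, %g cells/uL (dilution x%g)\n",
              x$volume_uL, x$cells_per_uL, x$dilution_factor))
  invisible(x)
}
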