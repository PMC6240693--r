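#' One component of a parametric per-cell INP spectrum
#'
#' The simulator's ground truth is a mixture of log-linear (exponential)
#' cumulative spectrum components. A component contributes
#' \deqn{K(T) = A \exp(\gamma (T_{on} - T))} INP per cell for
#' \eqn{T \le T_{on}} and 0 above its onset; K is non-decreasing as the
#' temperature drops. Components carry the compound-class labels that the
#' heat/filtration treatments act on, and an optional epibiont flag for
#' the axenic treatment.
#'
#' @param protein_class \code{"proteinaceous"} or
#'   \code{"non_proteinaceous"}; heating removes proteinaceous
#'   components.
#' @param localization \code{"particulate"} (cell-associated) or
#'   \code{"soluble"}; filtration keeps only soluble components.
#' @param onset_T onset temperature (degC, < 0).
#' @param amplitude_A INP per cell at onset (>= 0).
#' @param slope_gamma exponential steepness per degC of cooling (>= 0).
#' @param epibiont whether the component is produced by phycosphere
#'   bacteria rather than the alga itself (targeted by the axenic
#'   treatment).
#' @return object of class \code{spectrum_component}.
#' @export
spectrum_component <- function(protein_class = c("proteinaceous",
                                                 "non_proteinaceous"),
                               localization = c("particulate", "soluble"),
                               onset_T, amplitude_A, slope_gamma = 0.5,
                               epibiont = FALSE) {
  protein_class <- match.arg(protein_class)
  localization <- match.arg(localization)
  stopifnot(onset_T < 0, amplitude_A >= 0, slope_gamma >= 0)
  structure(
    list(protein_class = protein_class, localization = localization,
         onset_T = onset_T, amplitude_A = amplitude_A,
         slope_gamma = slope_gamma, epibiont = isTRUE(epibiont)),
    class = "spectrum_component")
}

component_K <- function(comp, temperature) {
  ifelse(temperature <= comp$onset_T,
         comp$amplitude_A *
           exp(comp$slope_gamma * (comp$onset_T - temperature)),
         0)
}

#' Parametric ground-truth INP spectrum model
#'
#' A mixture of \code{\link{spectrum_component}}s giving the cumulative
#' per-cell INP concentration, plus an optional per-droplet background
#' component representing buffer/impurity freezing that applies to every
#' droplet including cell-free controls. The default background is tuned
#' so a 16-well buffer control rarely freezes above -24 degC.
#'
#' @param components list of \code{spectrum_component}s (may be empty).
#' @param background a \code{spectrum_component} on a per-droplet scale,
#'   or NULL for none; the default is a weak soluble non-proteinaceous
#'   impurity spectrum.
#' @param per_droplet if TRUE the component amplitudes are already per
#'   droplet (the state after a filtrate treatment) and cell
#'   concentration is ignored when simulating.
#' @return object of class \code{spectrum_model} with \code{predict} and
#'   \code{simulate} methods.
#' @export
spectrum_model <- function(components = list(),
                           background = default_background(),
                           per_droplet = FALSE) {
  if (inherits(components, "spectrum_component"))
    components <- list(components)
  stopifnot(all(vapply(components, inherits, TRUE, "spectrum_component")))
  if (!is.null(background))
    stopifnot(inherits(background, "spectrum_component"))
  structure(
    list(components = components, background = background,
         per_droplet = isTRUE(per_droplet)),
    class = "spectrum_model")
}

#' Default per-droplet background spectrum of the buffer
#'
#' A weak impurity component: onset -24 degC, 0.02 INP per droplet at
#' onset, steepness 0.6 per degC. With 16-well controls this gives an
#' expected frozen fraction of about 2\% at -24 degC, i.e. the control
#' plate rarely freezes above -24 degC.
#'
#' @return a \code{spectrum_component}.
#' @export
default_background <- function() {
  spectrum_component("non_proteinaceous", "soluble", onset_T = -24,
                     amplitude_A = 0.02, slope_gamma = 0.6)
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("Spectrum model: %d component(s)%s%s\n",
              length(x$components),
              if (x$per_droplet) " [per droplet]" else " [per cell]",
              if (is.null(x$background)) ", no background" else
                ", with background"))
  for (cm in x$components)
    cat(sprintf("  %s/%s%s: onset %g degC, A = %.3g, gamma = %.3g\n",
                cm$protein_class, cm$localization,
                if (cm$epibiont) " (epibiont)" else "", cm$onset_T,
                cm$amplitude_A, cm$slope_gamma))
  invisible(x)
}

#' Evaluate the cumulative spectrum of a model
#'
#' @param object a \code{spectrum_model}.
#' @param temperature temperatures (degC) at which to evaluate.
#' @param ... unused.
#' @return numeric vector of cumulative INP per cell (or per droplet if
#'   the model is on that scale), excluding the background.
#' @export
predict.spectrum_model <- function(object, temperature, ...) {
  if (length(object$components) == 0L)
    return(rep(0, length(temperature)))
  rowSums(matrix(vapply(object$components, component_K,
                        numeric(length(temperature)),
                        temperature = temperature),
                 nrow = length(temperature)))
}

background_K <- function(model, temperature) {
  if (is.null(model$background)) rep(0, length(temperature))
  else component_K(model$background, temperature)
}

# deterministic 31-bit sub-seed from a master seed and string labels
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (s in as.character(c(...))) {
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate one droplet-freezing plate from a spectrum model
#'
#' Freezing follows the singular (time-independent) Poisson model that
#' the Vali estimator inverts: a droplet cooled to setpoint T freezes
#' with probability \eqn{1 - \exp(-[K(T) c V + K_{bg}(T)])}. Each well
#' draws one uniform variate; its freezing setpoint is the warmest
#' setpoint at which the cumulative freezing probability reaches the
#' draw, which yields cumulative frozen counts along the ramp.
#' Identical seeds give identical plates.
#'
#' @param model a \code{\link{spectrum_model}}.
#' @param droplet a \code{\link{droplet_spec}}.
#' @param protocol a \code{\link{freeze_protocol}}.
#' @param n_wells wells on the plate.
#' @param seed integer seed.
#' @param sample_id,treatment,replicate_id metadata for the resulting
#'   assay.
#' @return a \code{\link{plate_assay}}.
#' @export
simulate_plate <- function(model, droplet, protocol, n_wells, seed,
                           sample_id = "sim", treatment = "untreated",
                           replicate_id = "r1") {
  stopifnot(inherits(model, "spectrum_model"),
            inherits(droplet, "droplet_spec"),
            inherits(protocol, "freeze_protocol"), n_wells >= 1)
  scale <- if (model$per_droplet) 1 else
    droplet$cells_per_uL * droplet$volume_uL
  lambda <- predict(model, protocol$setpoints) * scale +
    background_K(model, protocol$setpoints)
  p <- -expm1(-cummax(lambda))   # cumulative freezing probability
  u <- with_seed(seed, stats::runif(n_wells))
  counts <- vapply(p, function(pp) sum(u <= pp), 0)
  plate_assay(sample_id, treatment, replicate_id, droplet, protocol,
              counts, n_wells)
}

#' Simulate replicate plates from a spectrum model
#'
#' @param object a \code{\link{spectrum_model}}.
#' @param nsim number of replicate plates.
#' @param seed master seed; replicate sub-seeds are derived from it.
#' @param droplet,protocol,n_wells plate design.
#' @param ... unused.
#' @return list of \code{plate_assay} objects.
#' @importFrom stats simulate predict coef confint
#' @export
simulate.spectrum_model <- function(object, nsim = 1, seed = NULL,
                                    droplet = droplet_spec(20, 100),
                                    protocol = default_protocol(),
                                    n_wells = 32, ...) {
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  lapply(seq_len(nsim), function(i)
    simulate_plate(object, droplet, protocol, n_wells,
                   seed = derive_seed(seed, "sim", i),
                   replicate_id = paste0("r", i)))
}

#' Transform a spectrum model under a laboratory treatment
#'
#' \describe{
#'   \item{heated}{100 degC for 10 min denatures proteins: proteinaceous
#'     components are removed, others kept. Idempotent.}
#'   \item{filtrate}{0.2-um filtration removes cells and fragments: only
#'     soluble components survive, and the model moves to a per-droplet
#'     scale (soluble compound released by c*V cells is present in each
#'     droplet of the filtrate). Idempotent: re-filtering a filtrate
#'     changes nothing.}
#'   \item{heated_filtrate}{both, composed.}
#'   \item{axenic}{antibiotic removal of phycosphere bacteria:
#'     components flagged as epibiont are attenuated by
#'     \code{axenic_attenuation}.}
#' }
#'
#' @param model a \code{\link{spectrum_model}}.
#' @param treatment one of \code{"heated"}, \code{"filtrate"},
#'   \code{"heated_filtrate"}, \code{"axenic"}.
#' @param droplet the droplet spec of the source suspension; required
#'   for the per-droplet conversion of a filtrate.
#' @param axenic_attenuation multiplier applied to epibiont components
#'   (default 0: epibionts fully removed).
#' @return a transformed \code{spectrum_model}.
#' @export
apply_treatment <- function(model,
                            treatment = c("heated", "filtrate",
                                          "heated_filtrate", "axenic"),
                            droplet = NULL, axenic_attenuation = 0) {
  stopifnot(inherits(model, "spectrum_model"))
  treatment <- match.arg(treatment)
  if (treatment == "heated_filtrate")
    return(apply_treatment(
      apply_treatment(model, "heated"), "filtrate", droplet = droplet))
  comps <- model$components
  per_droplet <- model$per_droplet
  if (treatment == "heated") {
    comps <- Filter(function(cm) cm$protein_class != "proteinaceous",
                    comps)
  } else if (treatment == "filtrate") {
    comps <- Filter(function(cm) cm$localization == "soluble", comps)
    if (!per_droplet) {
      if (is.null(droplet))
        stop("filtrate treatment needs the source droplet spec to ",
             "convert per-cell amplitudes to per-droplet")
      cV <- droplet$cells_per_uL * droplet$volume_uL
      comps <- lapply(comps, function(cm) {
        cm$amplitude_A <- cm$amplitude_A * cV
        cm
      })
      per_droplet <- TRUE
    }
  } else if (treatment == "axenic") {
    stopifnot(axenic_attenuation >= 0)
    comps <- lapply(comps, function(cm) {
      if (cm$epibiont) cm$amplitude_A <- cm$amplitude_A * axenic_attenuation
      cm
    })
  }
  spectrum_model(comps, background = model$background,
                 per_droplet = per_droplet)
}

#' Simulate a full treatment batch for one strain
#'
#' Produces replicate plates for the untreated culture, the heated
#' culture and the filtrate, ready for \code{\link{fit_inp_spectrum}}
#' and \code{\link{infer_nature}}.
#'
#' @param model ground-truth \code{spectrum_model} of the strain.
#' @param droplet droplet spec of the untreated suspension.
#' @param protocol freezing protocol.
#' @param n_wells wells per plate.
#' @param n_replicates biological replicates per arm.
#' @param seed master seed.
#' @param sample_id strain identifier.
#' @return named list of lists of \code{plate_assay} objects
#'   (\code{untreated}, \code{heated}, \code{filtrate}), plus
#'   \code{control} (one buffer plate per replicate).
#' @export
simulate_treatment_batch <- function(model, droplet, protocol,
                                     n_wells = 32, n_replicates = 3,
                                     seed = 1, sample_id = "sim") {
  filt_droplet <- droplet_spec(droplet$volume_uL, 0)
  arms <- list(
    untreated = list(model = model, droplet = droplet),
    heated = list(model = apply_treatment(model, "heated"),
                  droplet = droplet),
    filtrate = list(model = apply_treatment(model, "filtrate",
                                            droplet = droplet),
                    droplet = filt_droplet))
  out <- lapply(names(arms), function(arm) {
    lapply(seq_len(n_replicates), function(r)
      simulate_plate(arms[[arm]]$model, arms[[arm]]$droplet, protocol,
                     n_wells, seed = derive_seed(seed, sample_id, arm, r),
                     sample_id = sample_id, treatment = arm,
                     replicate_id = paste0("r", r)))
  })
  names(out) <- names(arms)
  ctrl_model <- spectrum_model(list(), background = model$background,
                               per_droplet = TRUE)
  out$control <- lapply(seq_len(n_replicates), function(r)
    simulate_plate(ctrl_model, filt_droplet, protocol, n_wells,
                   seed = derive_seed(seed, sample_id, "control", r),
                   sample_id = sample_id, treatment = "control",
                   replicate_id = paste0("r", r)))
  out
}
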