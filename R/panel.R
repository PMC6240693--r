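#' Configuration of a synthetic strain panel
#'
#' The defaults emulate the design of a combined airborne/aquatic
#' microalgal survey: 81 airborne strains isolated from snow and 32
#' aquatic culture-collection strains; 14/81 and 16/32 of them
#' ice-nucleation active; airborne taxonomy split 40 Trebouxiophyceae +
#' 6 Chlorophyceae (46 chlorophyta) / 11 Stramenopiles / 24 unknown;
#' onset-temperature classes warmer for airborne INA strains (6 warm, 5
#' mid, 2 cool, 1 cold) than aquatic ones (2 mid, 12 cool, 2 cold); 38
#' airborne strains freeze-tested and all surviving, 10/32 aquatic
#' freeze survivors, 11 aquatic strains desiccation-tested and none
#' surviving; roughly half of the airborne strains generalists across
#' the three depositional media. Screens use 16-well plates, freezing
#' profiles 32 wells x 3 replicates x a 10-fold dilution series.
#'
#' @param n_airborne,n_aquatic panel sizes.
#' @param ina_airborne,ina_aquatic number of truly INA strains per
#'   source.
#' @param airborne_classes,aquatic_classes named integer vectors
#'   allocating INA strains to onset classes (warm/mid/cool/cold).
#' @param airborne_taxa named integer allocation of airborne strains to
#'   taxonomic classes.
#' @param freeze_tested_airborne airborne strains subjected to the
#'   freeze-survival test (all survive).
#' @param freeze_survivors_aquatic aquatic freeze survivors.
#' @param desiccation_tested_aquatic aquatic strains desiccation-tested
#'   (none survive).
#' @param generalist_fraction fraction of strains growing in >= 2
#'   media.
#' @param nature_probs probabilities of the four
#'   (protein_class, localization) combinations for INA components, in
#'   the order proteinaceous/particulate, proteinaceous/soluble,
#'   non-proteinaceous/soluble, non-proteinaceous/particulate.
#' @param screen_wells,profile_wells,n_replicates,dilutions plate
#'   design.
#' @param droplet_volume_uL,stock_cells_per_uL droplet design of the
#'   undiluted suspension.
#' @return a validated list of class \code{panel_config}.
#' @export
panel_config <- function(n_airborne = 81, n_aquatic = 32,
                         ina_airborne = 14, ina_aquatic = 16,
                         airborne_classes = c(warm = 6, mid = 5,
                                              cool = 2, cold = 1),
                         aquatic_classes = c(warm = 0, mid = 2,
                                             cool = 12, cold = 2),
                         airborne_taxa = c(Trebouxiophyceae = 40,
                                           Chlorophyceae = 6,
                                           Stramenopiles = 11,
                                           unknown = 24),
                         freeze_tested_airborne = 38,
                         freeze_survivors_aquatic = 10,
                         desiccation_tested_aquatic = 11,
                         generalist_fraction = 0.5,
                         nature_probs = c(pp = 0.7, ps = 0.1,
                                          ns = 0.1, np = 0.1),
                         screen_wells = 16, profile_wells = 32,
                         n_replicates = 3, dilutions = c(1, 10, 100),
                         droplet_volume_uL = 20,
                         stock_cells_per_uL = 100) {
  cfg <- as.list(environment())
  if (ina_airborne > n_airborne || ina_aquatic > n_aquatic)
    stop("INA prevalence cannot exceed the panel size")
  if (sum(airborne_classes) != ina_airborne)
    stop("airborne_classes must allocate exactly ina_airborne strains")
  if (sum(aquatic_classes) != ina_aquatic)
    stop("aquatic_classes must allocate exactly ina_aquatic strains")
  if (sum(airborne_taxa) != n_airborne)
    stop("airborne_taxa must allocate exactly n_airborne strains")
  if (freeze_tested_airborne > n_airborne ||
      freeze_survivors_aquatic > n_aquatic ||
      desiccation_tested_aquatic > n_aquatic)
    stop("tested/survivor counts cannot exceed the panel size")
  if (generalist_fraction < 0 || generalist_fraction > 1)
    stop("generalist_fraction must be in [0, 1]")
  if (abs(sum(nature_probs) - 1) > 1e-8 || any(nature_probs < 0))
    stop("nature_probs must be a probability vector over 4 classes")
  class(cfg) <- "panel_config"
  cfg
}

ONSET_RANGES <- list(warm = c(-6, -4), mid = c(-12, -7),
                     cool = c(-18, -13), cold = c(-24, -19))

NATURE_COMBOS <- list(
  pp = c("proteinaceous", "particulate"),
  ps = c("proteinaceous", "soluble"),
  ns = c("non_proteinaceous", "soluble"),
  np = c("non_proteinaceous", "particulate"))

# ground-truth model for one INA strain in a given onset class
draw_strain_model <- function(class_label, nature_probs) {
  rng <- ONSET_RANGES[[class_label]]
  onset <- stats::runif(1, rng[1], rng[2])
  amp <- 10^stats::runif(1, -3.5, -2)   # 3e-4 .. 1e-2 INP/cell at onset
  combo <- NATURE_COMBOS[[sample(names(NATURE_COMBOS), 1,
                                 prob = nature_probs)]]
  spectrum_model(spectrum_component(combo[1], combo[2], onset_T = onset,
                                    amplitude_A = amp,
                                    slope_gamma = 0.5))
}

MEDIA <- c("ARW", "MWC", "f2_25", "f2_100")

#' Generate a synthetic strain panel with plates
#'
#' Builds a reproducible panel of strain records, ground-truth spectrum
#' models, 16-well screening plates (two independent screens per strain,
#' each with a paired buffer control) and, for truly INA strains,
#' 32-well freezing-profile plates over 3 biological replicates and a
#' 10-fold dilution series, each replicate with its own control plate.
#' Composition (INA prevalence, taxonomy, survival, habitat strategy) is
#' allocated exactly per the configuration and then randomly assigned to
#' strains; the same seed and configuration give byte-identical panels.
#'
#' @param config a \code{\link{panel_config}}.
#' @param seed master integer seed; all per-plate sub-seeds derive from
#'   it deterministically.
#' @return an object of class \code{strain_panel}: list with
#'   \code{strains} (data.frame), \code{truth} (named list of
#'   \code{spectrum_model}s), \code{screens}, \code{profiles},
#'   \code{config}, \code{seed}.
#' @export
generate_strain_panel <- function(config = panel_config(), seed = 1) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(derive_seed(seed, "panel"), {
    build_panel(config, seed)
  })
}

build_panel <- function(config, seed) {
  ids <- c(sprintf("A-%02d", seq_len(config$n_airborne)),
           sprintf("Q-%02d", seq_len(config$n_aquatic)))
  source <- rep(c("airborne", "aquatic"),
                c(config$n_airborne, config$n_aquatic))

  taxon <- character(length(ids))
  taxon[source == "airborne"] <-
    sample(rep(names(config$airborne_taxa), config$airborne_taxa))
  aquatic_taxa <- c("Gonyostomum", "Peridinium", "Polarella",
                    "Microcystis", "Apocalathium", "Cryptomonas")
  taxon[source == "aquatic"] <-
    sample(aquatic_taxa, config$n_aquatic, replace = TRUE)

  # exact INA allocation with onset classes
  onset_class <- rep(NA_character_, length(ids))
  air_idx <- which(source == "airborne")
  aq_idx <- which(source == "aquatic")
  air_ina <- sample(air_idx, config$ina_airborne)
  aq_ina <- sample(aq_idx, config$ina_aquatic)
  onset_class[air_ina] <- sample(rep(names(config$airborne_classes),
                                     config$airborne_classes))
  onset_class[aq_ina] <- sample(rep(names(config$aquatic_classes),
                                    config$aquatic_classes))
  ina_true <- !is.na(onset_class)

  truth <- vector("list", length(ids))
  names(truth) <- ids
  for (i in seq_along(ids)) {
    truth[[i]] <- if (ina_true[i])
      draw_strain_model(onset_class[i], config$nature_probs)
    else spectrum_model(list())
  }

  # survival outcomes: exact allocation
  freeze <- rep("untested", length(ids))
  tested_air <- sample(air_idx, config$freeze_tested_airborne)
  freeze[tested_air] <- "survived"
  freeze[aq_idx] <- "killed"
  freeze[sample(aq_idx, config$freeze_survivors_aquatic)] <- "survived"
  desiccation <- rep("untested", length(ids))
  desiccation[sample(aq_idx, config$desiccation_tested_aquatic)] <-
    "killed"

  # habitat: generalists grow in >= 2 media, specialists in exactly 1
  n_gen <- round(config$generalist_fraction * length(ids))
  generalist <- rep(FALSE, length(ids))
  generalist[sample(seq_along(ids), n_gen)] <- TRUE
  growth <- matrix(FALSE, length(ids), length(MEDIA),
                   dimnames = list(NULL, MEDIA))
  isolation <- character(length(ids))
  for (i in seq_along(ids)) {
    k <- if (generalist[i]) sample(2:3, 1) else 1L
    pos <- sample(MEDIA[1:3], k)
    growth[i, pos] <- TRUE
    isolation[i] <- pos[1]
  }

  strains <- data.frame(
    strain_id = ids, source = source, taxon = taxon,
    ina_true = ina_true, onset_class = ifelse(is.na(onset_class),
                                              "none", onset_class),
    freeze_survival = freeze, desiccation = desiccation,
    isolation_medium = isolation, stringsAsFactors = FALSE)
  colnames(growth) <- paste0("growth_", MEDIA)
  strains <- cbind(strains, as.data.frame(growth))

  # screening plates: 2 independent 16-well screens + paired controls
  screen_droplet <- droplet_spec(config$droplet_volume_uL,
                                 config$stock_cells_per_uL)
  ctrl_droplet <- droplet_spec(config$droplet_volume_uL, 0)
  protocol <- default_protocol()
  ctrl_model <- spectrum_model(list(), per_droplet = TRUE)
  screens <- lapply(seq_along(ids), function(i) {
    lapply(1:2, function(s) list(
      sample = simulate_plate(
        truth[[i]], screen_droplet, protocol, config$screen_wells,
        seed = derive_seed(seed, ids[i], "screen", s),
        sample_id = ids[i], replicate_id = paste0("screen", s)),
      control = simulate_plate(
        ctrl_model, ctrl_droplet, protocol, config$screen_wells,
        seed = derive_seed(seed, ids[i], "screenctrl", s),
        sample_id = ids[i], treatment = "control",
        replicate_id = paste0("screen", s))))
  })
  names(screens) <- ids

  # freezing profiles for truly INA strains
  profiles <- list()
  for (i in which(ina_true)) {
    reps <- lapply(seq_len(config$n_replicates), function(r) {
      dil <- lapply(config$dilutions, function(d) {
        dr <- droplet_spec(config$droplet_volume_uL,
                           config$stock_cells_per_uL / d,
                           dilution_factor = d)
        simulate_plate(truth[[i]], dr, protocol, config$profile_wells,
                       seed = derive_seed(seed, ids[i], "prof", r, d),
                       sample_id = ids[i],
                       replicate_id = paste0("r", r))
      })
      ctrl <- simulate_plate(
        ctrl_model, ctrl_droplet, protocol, config$profile_wells,
        seed = derive_seed(seed, ids[i], "profctrl", r),
        sample_id = ids[i], treatment = "control",
        replicate_id = paste0("r", r))
      list(dilutions = dil, control = ctrl)
    })
    profiles[[ids[i]]] <- reps
  }

  structure(list(strains = strains, truth = truth, screens = screens,
                 profiles = profiles, config = config, seed = seed),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf(
    "Synthetic strain panel: %d airborne + %d aquatic strains (seed %d)\n",
    x$config$n_airborne, x$config$n_aquatic, x$seed))
  cat(sprintf("  truly INA: %d airborne, %d aquatic; %d profiled strains\n",
              x$config$ina_airborne, x$config$ina_aquatic,
              length(x$profiles)))
  invisible(x)
}
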