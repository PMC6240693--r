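#' Run configuration for the end-to-end pipeline
#'
#' Validates a configuration list (or a YAML/JSON file path) for
#' \code{\link{run_pipeline}}. Either \code{plates} names an existing
#' plate CSV, or \code{simulate = TRUE} requests a synthetic panel
#' (whose design is taken from \code{panel} arguments, defaulting to
#' \code{\link{panel_config}()}).
#'
#' @param config list or path to a YAML/JSON file with fields
#'   \code{plates}, \code{simulate}, \code{panel}, \code{ci_level},
#'   \code{significance}, \code{dunn_adjustment}, \code{screen_at},
#'   \code{screen_cutoff}, \code{seed}, \code{output_dir}.
#' @return validated configuration list of class \code{run_config}.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the yaml package is needed to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(plates = NULL, simulate = is.null(config$plates),
                   panel = list(), ci_level = 0.95, significance = 0.05,
                   dunn_adjustment = "none", screen_at = -24,
                   screen_cutoff = 0.5, seed = 1,
                   output_dir = tempfile("inp_run_"))
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$ci_level > 0, cfg$ci_level < 1,
            cfg$significance > 0, cfg$significance < 1,
            cfg$screen_cutoff > 0, cfg$screen_cutoff <= 1,
            cfg$screen_at < 0)
  cfg$dunn_adjustment <- match.arg(cfg$dunn_adjustment,
                                   c("none", "holm", "bh"))
  if (!is.null(cfg$plates) && !file.exists(cfg$plates))
    stop("plate file does not exist: ", cfg$plates)
  if (is.null(cfg$plates) && !isTRUE(cfg$simulate))
    stop("config must either name a plate file or request simulation")
  class(cfg) <- c("run_config", "list")
  cfg
}

fnv1a <- function(s) {
  h <- 2166136261
  for (code in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full droplet-freezing analysis pipeline
#'
#' Ties simulation (or plate input), spectrum estimation, INA
#' classification and strain summaries into one reproducible run.
#' Outputs written to \code{config$output_dir}: \code{spectra.json} and
#' \code{spectra.csv} (per-setpoint estimates with flags),
#' \code{decisions.csv} (per-strain screen/confirm/onset/class),
#' \code{summaries.csv} (composition and survival tables, simulated
#' panels only), \code{log.csv} (one record per stage per strain,
#' including dropped-data reasons) and \code{manifest.json} (package
#' version, configuration hash, seed). Identical configuration and seed
#' give an identical manifest hash.
#'
#' @param config a \code{\link{run_config}} (or anything it accepts).
#' @return invisible list with the output paths, the decision table and
#'   the manifest.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, id, message)
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, strain = id, message = message,
      stringsAsFactors = FALSE)

  spectra <- list()
  decisions <- list()
  summaries <- NULL

  if (isTRUE(cfg$simulate) && is.null(cfg$plates)) {
    panel <- generate_strain_panel(do.call(panel_config, cfg$panel),
                                   seed = cfg$seed)
    note("simulate", "panel", sprintf(
      "generated %d strains with seed %d", nrow(panel$strains),
      cfg$seed))
    for (id in panel$strains$strain_id) {
      scr <- vapply(panel$screens[[id]], function(s) {
        i <- match(cfg$screen_at, s$sample$protocol$setpoints)
        screen_ina(s$sample$frozen_counts[i], s$sample$n_wells,
                   cfg$screen_cutoff)
      }, TRUE)
      rep_spectra <- NULL
      if (!is.null(panel$profiles[[id]])) {
        rep_spectra <- lapply(panel$profiles[[id]], function(rep) {
          per_dil <- lapply(rep$dilutions, function(a)
            fit_inp_spectrum(a, control = rep$control,
                             level = cfg$ci_level))
          merge_dilutions(per_dil)
        })
        rf <- replicate_filter(rep_spectra)
        if (!rf$keep) {
          note("replicate_filter", id, rf$reason)
          rep_spectra <- NULL
        } else {
          spectra <- c(spectra, rep_spectra)
        }
      }
      dec <- ina_decision(scr, rep_spectra)
      decisions[[id]] <- data.frame(
        strain_id = id,
        screened_positive = dec$screened_positive,
        confirmed = dec$confirmed,
        onset_temperature = dec$onset_temperature,
        temperature_class = dec$temperature_class,
        stringsAsFactors = FALSE)
      note("classify", id, sprintf("confirmed=%s class=%s",
                                   dec$confirmed, dec$temperature_class))
    }
    comp <- composition_summary(panel$strains, by = "taxon")
    surv_f <- survival_summary(panel$strains, "freezing")
    surv_d <- survival_summary(panel$strains, "desiccation")
    summaries <- list(
      composition = data.frame(table = "composition_taxon",
                               group = comp$group, n = comp$count,
                               denominator = comp$total,
                               percent = comp$percent),
      freezing = data.frame(table = "survival_freezing",
                            group = surv_f$source, n = surv_f$survived,
                            denominator = surv_f$tested,
                            percent = surv_f$percent),
      desiccation = data.frame(table = "survival_desiccation",
                               group = surv_d$source,
                               n = surv_d$survived,
                               denominator = surv_d$tested,
                               percent = surv_d$percent))
    write_strain_tsv(panel$strains,
                     file.path(cfg$output_dir, "strains.tsv"))
  } else {
    rd <- read_plate_csv(cfg$plates)
    for (j in seq_len(nrow(rd$errors)))
      note("read", rd$errors$plate[j],
           sprintf("lines %s: %s", rd$errors$lines[j],
                   rd$errors$message[j]))
    assays <- rd$assays
    is_ctrl <- vapply(assays, function(a) a$treatment == "control", TRUE)
    controls <- assays[is_ctrl]
    ctrl_key <- vapply(controls, function(a)
      paste(a$sample_id, a$replicate_id), "")
    for (a in assays[!is_ctrl]) {
      ctrl <- controls[match(paste(a$sample_id, a$replicate_id),
                             ctrl_key)][[1]]
      s <- fit_inp_spectrum(a, control = ctrl, level = cfg$ci_level)
      spectra[[length(spectra) + 1L]] <- s
      removed <- sum(s$flag == "negative_removed")
      if (removed > 0)
        note("spectrum", a$sample_id,
             sprintf("%d setpoint(s) negative after background %s",
                     removed, "correction; removed"))
      i <- match(cfg$screen_at, a$protocol$setpoints)
      if (!is.na(i) && a$treatment == "untreated") {
        pos <- screen_ina(a$frozen_counts[i], a$n_wells,
                          cfg$screen_cutoff)
        decisions[[paste(a$sample_id, a$replicate_id)]] <- data.frame(
          strain_id = a$sample_id, screened_positive = pos,
          confirmed = NA, onset_temperature = NA_real_,
          temperature_class = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }

  paths <- list(
    spectra_json = file.path(cfg$output_dir, "spectra.json"),
    spectra_csv = file.path(cfg$output_dir, "spectra.csv"),
    decisions_csv = file.path(cfg$output_dir, "decisions.csv"),
    log_csv = file.path(cfg$output_dir, "log.csv"),
    manifest_json = file.path(cfg$output_dir, "manifest.json"))
  if (length(spectra))
    write_spectra_json(spectra, paths$spectra_json, paths$spectra_csv)
  dec_df <- do.call(rbind, decisions)
  if (!is.null(dec_df))
    utils::write.csv(dec_df, paths$decisions_csv, row.names = FALSE)
  if (!is.null(summaries)) {
    paths$summaries_csv <- file.path(cfg$output_dir, "summaries.csv")
    utils::write.csv(do.call(rbind, summaries), paths$summaries_csv,
                     row.names = FALSE)
  }
  log_df <- do.call(rbind, log)
  utils::write.csv(log_df, paths$log_csv, row.names = FALSE)

  cfg_plain <- unclass(cfg)
  cfg_plain$output_dir <- NULL
  manifest <- list(
    package = "inpspectra",
    version = as.character(utils::packageVersion("inpspectra")),
    seed = cfg$seed,
    config_hash = fnv1a(as.character(jsonlite::toJSON(
      cfg_plain, auto_unbox = TRUE, digits = NA))),
    n_spectra = length(spectra),
    n_decisions = if (is.null(dec_df)) 0L else nrow(dec_df))
  jsonlite::write_json(manifest, paths$manifest_json,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, decisions = dec_df,
                 summaries = summaries, manifest = manifest,
                 log = log_df))
}
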