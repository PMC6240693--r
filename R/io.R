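PLATE_COLUMNS <- c("sample_id", "treatment", "replicate_id",
                   "dilution_factor", "cells_per_uL", "droplet_uL",
                   "temperature_C", "frozen_count", "n_wells")

#' Write plate assays to delimited text
#'
#' One row per setpoint with the full plate key, comma-separated with a
#' mandatory header; temperatures as signed decimals in degC.
#'
#' @param assays a \code{plate_assay} or list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_plate_csv <- function(assays, path) {
  if (inherits(assays, "plate_assay")) assays <- list(assays)
  rows <- do.call(rbind, lapply(assays, function(a)
    data.frame(sample_id = a$sample_id, treatment = a$treatment,
               replicate_id = a$replicate_id,
               dilution_factor = a$droplet$dilution_factor,
               cells_per_uL = a$droplet$cells_per_uL,
               droplet_uL = a$droplet$volume_uL,
               temperature_C = a$protocol$setpoints,
               frozen_count = a$frozen_counts, n_wells = a$n_wells,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plate assays from delimited text
#'
#' Strictly validates the file before any computation: the header must
#' contain the full column set, and each plate's rows must form a valid
#' cumulative freezing record. Malformed plates are collected into an
#' error report carrying the offending line numbers; the read aborts
#' only when no valid plate remains.
#'
#' @param path CSV file written by \code{\link{write_plate_csv}} or of
#'   the same layout.
#' @param hold_minutes hold time to attach to reconstructed protocols.
#' @param step_range permitted setpoint step range, passed to
#'   \code{\link{freeze_protocol}}.
#' @return list with \code{assays} (list of \code{plate_assay}) and
#'   \code{errors} (data.frame of \code{plate}, \code{lines},
#'   \code{message}).
#' @export
read_plate_csv <- function(path, hold_minutes = 30,
                           step_range = c(1, 2)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PLATE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("plate file is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  df$.line <- seq_len(nrow(df)) + 1L   # header is line 1
  key <- interaction(df$sample_id, df$treatment, df$replicate_id,
                     df$dilution_factor, drop = TRUE)
  assays <- list()
  errors <- data.frame(plate = character(), lines = character(),
                       message = character(), stringsAsFactors = FALSE)
  for (grp in split(df, key)) {
    grp <- grp[order(-grp$temperature_C), , drop = FALSE]
    label <- sprintf("%s/%s/%s/x%g", grp$sample_id[1], grp$treatment[1],
                     grp$replicate_id[1], grp$dilution_factor[1])
    res <- tryCatch({
      proto <- freeze_protocol(grp$temperature_C,
                               hold_minutes = hold_minutes,
                               step_range = step_range)
      dr <- droplet_spec(grp$droplet_uL[1], grp$cells_per_uL[1],
                         max(1, grp$dilution_factor[1]))
      plate_assay(grp$sample_id[1], grp$treatment[1],
                  grp$replicate_id[1], dr, proto, grp$frozen_count,
                  grp$n_wells[1])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(
        plate = label,
        lines = paste(range(grp$.line), collapse = "-"),
        message = conditionMessage(res), stringsAsFactors = FALSE))
    } else assays[[length(assays) + 1L]] <- res
  }
  if (length(assays) == 0L)
    stop("no valid plates in ", path, ": ",
         paste(errors$message, collapse = "; "))
  list(assays = assays, errors = errors)
}

#' Write INP spectra to JSON (with a flat CSV twin)
#'
#' Records are keyed by sample/treatment/replicate and carry the
#' per-setpoint estimate, confidence bounds and flag.
#'
#' @param spectra an \code{inp_spectrum} or list of them.
#' @param path JSON output file.
#' @param csv_path optional path for the flat CSV twin.
#' @return \code{path}, invisibly.
#' @export
write_spectra_json <- function(spectra, path, csv_path = NULL) {
  if (inherits(spectra, "inp_spectrum")) spectra <- list(spectra)
  df <- do.call(rbind, lapply(spectra, as.data.frame))
  # infinite bounds (saturated setpoints) are encoded as the string "Inf"
  enc <- function(x) lapply(x, function(v)
    if (!is.na(v) && is.infinite(v)) "Inf" else v)
  recs <- lapply(spectra, function(s) list(
    sample_id = s$sample_id, treatment = s$treatment,
    replicate_id = s$replicate_id,
    dilution_factor = s$dilution_factor, mode = s$mode,
    level = s$level, n_wells = s$n_wells,
    setpoints = s$setpoints, estimate = enc(s$estimate),
    ci_low = enc(s$ci_low), ci_high = enc(s$ci_high), flag = s$flag))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(path)
}

#' Read INP spectra back from JSON
#'
#' Inverse of \code{\link{write_spectra_json}}: reconstructs the flat
#' per-setpoint table (the same as row-binding
#' \code{as.data.frame} over the written spectra).
#'
#' @param path JSON file.
#' @return data.frame of per-setpoint records.
#' @export
read_spectra_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  do.call(rbind, lapply(recs, function(r) {
    data.frame(sample_id = r$sample_id, treatment = r$treatment,
               replicate_id = r$replicate_id,
               dilution_factor = null_na(list(r$dilution_factor)),
               temperature_C = null_na(r$setpoints),
               estimate = null_na(r$estimate),
               ci_low = null_na(r$ci_low),
               ci_high = null_na(r$ci_high),
               flag = vapply(r$flag, as.character, ""),
               mode = r$mode, stringsAsFactors = FALSE)
  }))
}

# JSON null (or string "Inf") -> numeric with NA/Inf preserved
null_na <- function(x) {
  vapply(x, function(v) {
    if (is.null(v)) NA_real_
    else if (is.character(v)) as.numeric(v)
    else as.numeric(v)
  }, numeric(1))
}

#' Write / read a strain metadata table (TSV)
#'
#' @param records strain data.frame.
#' @param path file path.
#' @return path (writer) or data.frame (reader).
#' @export
write_strain_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_strain_tsv
#' @export
read_strain_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
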