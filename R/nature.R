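#' Per-setpoint estimates usable as treatment-contrast observations
#'
#' Pools the estimable values (flags \code{ok}, \code{below_detection}
#' and \code{saturated}; excluded setpoints are dropped) of one or more
#' replicate spectra into one numeric vector, optionally restricted to a
#' temperature window.
#'
#' @param spectra an \code{inp_spectrum} or list of them.
#' @param setpoint_range optional \code{c(coldest, warmest)} window in
#'   degC; only setpoints within it contribute.
#' @return numeric vector of INP estimates.
#' @export
spectrum_values <- function(spectra, setpoint_range = NULL) {
  if (inherits(spectra, "inp_spectrum")) spectra <- list(spectra)
  unlist(lapply(spectra, function(s) {
    keep <- s$flag %in% c("ok", "below_detection", "saturated")
    if (!is.null(setpoint_range))
      keep <- keep & s$setpoints >= min(setpoint_range) &
        s$setpoints <= max(setpoint_range)
    s$estimate[keep]
  }), use.names = FALSE)
}

#' Infer the nature of the ice-nucleating compound
#'
#' Uses the heat and filtration treatment contrasts to place the active
#' compound on two axes. Heating to 100 degC denatures proteins, so a
#' significant loss of activity after heating indicates a proteinaceous
#' compound. The filtrate (< 0.2 um fraction) holds only material
#' released by the cells, so activity that survives filtration is
#' soluble while activity lost with the cells is cell-associated.
#'
#' A Kruskal-Wallis test is run across the supplied treatment arms and
#' followed by Dunn pairwise comparisons; an axis is called only when
#' both the omnibus test and the deciding pairwise contrast are
#' significant at \code{stats_threshold} in the direction of reduced
#' activity. Note the filtrate arm is naturally on a per-droplet scale
#' while untreated spectra are per cell; because the decision is
#' direction-aware (the treated arm must be significantly LOWER), the
#' scale difference cannot create a spurious cell-associated call.
#'
#' A missing treatment arm yields \code{"indeterminate"} on its axis.
#' Temperature-resolved verdicts are obtained by passing a
#' \code{setpoint_range} window.
#'
#' @param untreated spectra (or list of replicate spectra) of the
#'   untreated culture.
#' @param heated spectra after 10-min 100 degC heating, or NULL.
#' @param filtrate per-droplet spectra of the 0.2-um filtrate, or NULL.
#' @param stats_threshold significance level for the decision
#'   (default 0.05).
#' @param setpoint_range optional temperature window (degC).
#' @return object of class \code{nature_verdict} with fields
#'   \code{protein_axis}, \code{localization_axis} and \code{evidence}
#'   (the Kruskal-Wallis \code{htest} and the Dunn table).
#' @export
infer_nature <- function(untreated, heated = NULL, filtrate = NULL,
                         stats_threshold = 0.05, setpoint_range = NULL) {
  groups <- list(untreated = spectrum_values(untreated, setpoint_range))
  if (length(groups$untreated) == 0L)
    stop("untreated arm has no estimable setpoints")
  if (!is.null(heated))
    groups$heated <- spectrum_values(heated, setpoint_range)
  if (!is.null(filtrate))
    groups$filtrate <- spectrum_values(filtrate, setpoint_range)

  kw <- NULL; dunn <- NULL
  if (length(groups) >= 2L) {
    kw <- kruskal_wallis(groups)
    dunn <- dunn_posthoc(groups, adjustment = "none")
  }
  omnibus_sig <- !is.null(kw) && kw$p.value < stats_threshold

  contrast <- function(arm) {
    row <- dunn[(dunn$group1 == "untreated" & dunn$group2 == arm) |
                  (dunn$group2 == "untreated" & dunn$group1 == arm), ]
    if (nrow(row) != 1L) return(NULL)
    # z is rank-mean(group1) - rank-mean(group2); make it untreated - arm
    z <- if (row$group1 == "untreated") row$z else -row$z
    list(z = z, p = row$p_value,
         reduced = z > 0, significant = row$p_value < stats_threshold)
  }

  protein_axis <- "indeterminate"
  heat_note <- NULL
  if (is.null(heated)) {
    heat_note <- "heated arm missing"
  } else {
    ct <- contrast("heated")
    protein_axis <- if (omnibus_sig && ct$significant && ct$reduced)
      "proteinaceous" else "non_proteinaceous"
  }

  localization_axis <- "indeterminate"
  filt_note <- NULL
  if (is.null(filtrate)) {
    filt_note <- "filtrate arm missing"
  } else {
    ct <- contrast("filtrate")
    localization_axis <- if (omnibus_sig && ct$significant && ct$reduced)
      "cell_associated" else "soluble"
  }

  structure(
    list(protein_axis = protein_axis,
         localization_axis = localization_axis,
         evidence = list(kruskal_wallis = kw, dunn = dunn,
                         threshold = stats_threshold,
                         notes = c(heat_note, filt_note))),
    class = "nature_verdict")
}

#' @export
print.nature_verdict <- function(x, ...) {
  cat(sprintf("INA compound verdict: %s, %s\n", x$protein_axis,
              x$localization_axis))
  if (!is.null(x$evidence$kruskal_wallis))
    cat(sprintf("  Kruskal-Wallis chi-squared = %.3g, df = %d, p = %.3g\n",
                x$evidence$kruskal_wallis$statistic,
                x$evidence$kruskal_wallis$parameter,
                x$evidence$kruskal_wallis$p.value))
  if (!is.null(x$evidence$dunn)) {
    cat("  Dunn pairwise p-values:\n")
    d <- x$evidence$dunn
    for (j in seq_len(nrow(d)))
      cat(sprintf("    %s vs %s: z = %.3g, p = %.3g\n", d$group1[j],
                  d$group2[j], d$z[j], d$p_value[j]))
  }
  for (nt in x$evidence$notes) cat("  note:", nt, "\n")
  invisible(x)
}
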