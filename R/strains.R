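#' Assign a taxonomic rank from sequence-alignment statistics
#'
#' Applies the identity/coverage/e-value thresholds used for marker-gene
#' taxonomy: no assignment unless the alignment covers at least 89\% of
#' the query with identity strictly above 89\% and an e-value below the
#' threshold; then species at identity >= 97\%, genus at >= 95\%, and a
#' higher rank otherwise. Rank never coarsens as identity rises.
#'
#' The e-value bound is written "e^-189" in the conventions this
#' follows; by default it is read literally as exp(-189), with the
#' base-10 reading selectable.
#'
#' @param identity_pct alignment identity in percent (0--100).
#' @param query_coverage_pct query coverage in percent (0--100).
#' @param e_value alignment e-value (>= 0).
#' @param e_value_threshold upper bound on the e-value; defaults per
#'   \code{e_value_base}.
#' @param e_value_base \code{"e"} (natural, exp(-189)) or \code{"10"}
#'   (1e-189).
#' @return one of \code{"species"}, \code{"genus"},
#'   \code{"higher_rank"}, \code{"unassigned"} (vectorised).
#' @examples
#' assign_taxonomic_rank(98, 95, 0)   # species
#' assign_taxonomic_rank(96, 95, 0)   # genus
#' assign_taxonomic_rank(99, 80, 0)   # unassigned: coverage too low
#' @export
assign_taxonomic_rank <- function(identity_pct, query_coverage_pct,
                                  e_value,
                                  e_value_threshold = NULL,
                                  e_value_base = c("e", "10")) {
  e_value_base <- match.arg(e_value_base)
  if (is.null(e_value_threshold))
    e_value_threshold <- if (e_value_base == "e") exp(-189) else 1e-189
  stopifnot(all(identity_pct >= 0 & identity_pct <= 100),
            all(query_coverage_pct >= 0 & query_coverage_pct <= 100),
            all(e_value >= 0))
  out <- rep("higher_rank", length(identity_pct))
  out[identity_pct >= 95] <- "genus"
  out[identity_pct >= 97] <- "species"
  out[query_coverage_pct < 89 | identity_pct <= 89 |
        e_value >= e_value_threshold] <- "unassigned"
  out
}

#' Habitat strategy from growth outcomes across media
#'
#' Taxa growing in two or more of the tested depositional media are
#' generalists; growth in exactly one medium marks a specialist; no
#' growth in any tested medium is unknown.
#'
#' @param growth logical vector (or matrix with one row per strain) of
#'   per-medium growth outcomes; at least one medium must be present.
#' @return \code{"generalist"}, \code{"specialist"} or \code{"unknown"}
#'   (vector when \code{growth} is a matrix).
#' @examples
#' habitat_strategy(c(ARW = TRUE, MWC = FALSE, f2_25 = TRUE))
#' @export
habitat_strategy <- function(growth) {
  if (is.matrix(growth) || is.data.frame(growth)) {
    if (ncol(growth) < 1L) stop("no media tested")
    return(apply(as.matrix(growth), 1, habitat_strategy))
  }
  if (length(growth) < 1L) stop("no media tested")
  n_pos <- sum(as.logical(growth), na.rm = TRUE)
  if (n_pos >= 2) "generalist" else if (n_pos == 1) "specialist"
  else "unknown"
}

#' Composition summary of a strain table
#'
#' Counts and percentages (rounded to one decimal) of strains per group,
#' with the denominator reported explicitly.
#'
#' @param records data.frame of strain records.
#' @param by name of the grouping column.
#' @return data.frame with \code{group}, \code{count}, \code{total},
#'   \code{percent}; percentages sum to 100 up to rounding.
#' @examples
#' composition_summary(
#'   data.frame(taxon = rep(c("chlorophyta", "other"), c(46, 35))),
#'   by = "taxon")
#' @export
composition_summary <- function(records, by) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  if (!by %in% names(records))
    stop(sprintf("grouping column '%s' not found", by))
  tab <- table(records[[by]])
  total <- sum(tab)
  data.frame(group = names(tab), count = as.integer(tab),
             total = total,
             percent = round(100 * as.integer(tab) / total, 1),
             stringsAsFactors = FALSE)
}

#' Survival summary by source
#'
#' Proportion of strains surviving a stressor, per source, with untested
#' strains excluded from the denominator. Headline percentages are
#' rounded to the nearest integer.
#'
#' @param records data.frame with columns \code{source} and the stressor
#'   column (values \code{"survived"}, \code{"killed"},
#'   \code{"untested"}).
#' @param stressor \code{"freezing"} or \code{"desiccation"}; the
#'   column read is \code{freeze_survival} or \code{desiccation}.
#' @return data.frame with \code{source}, \code{survived},
#'   \code{tested}, \code{percent}.
#' @export
survival_summary <- function(records,
                             stressor = c("freezing", "desiccation")) {
  stressor <- match.arg(stressor)
  col <- if (stressor == "freezing") "freeze_survival" else "desiccation"
  if (!col %in% names(records))
    stop(sprintf("column '%s' not found", col))
  tested <- records[records[[col]] != "untested", , drop = FALSE]
  if (nrow(tested) == 0L) stop("no tested records for ", stressor)
  out <- do.call(rbind, lapply(split(tested, tested$source), function(d)
    data.frame(source = d$source[1],
               survived = sum(d[[col]] == "survived"),
               tested = nrow(d), stringsAsFactors = FALSE)))
  out$percent <- round(100 * out$survived / out$tested)
  rownames(out) <- NULL
  out
}
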