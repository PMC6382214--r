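#' @title miRNA target-gene screening filters
#' @description Applies the screening and prioritization rules to an
#'   externally produced differential-expression table (the DE statistics
#'   themselves — array preprocessing, moderated t-tests — are consumed,
#'   not recomputed). Fold-changes follow the signed linear convention of
#'   [fold_change()]: downregulation has a negative sign and
#'   |fold-change| >= 1.
#' @name target-filter
NULL

de_cols <- function(time) {
  list(p = paste0("p_", time), fc = paste0("fc_", time))
}

#' Filter candidate target transcripts at one time point
#'
#' Keeps records with p < 0.05 (strict) and fold-change <= -1.5
#' (inclusive), i.e. transcripts significantly downregulated by more than
#' a third.
#'
#' @param records data.frame with columns `p_<time>` and `fc_<time>`.
#' @param time time-point label, e.g. `"24h"`.
#' @param alpha nominal significance level (default 0.05, strict <).
#' @param fc_cut fold-change cutoff (default -1.5, inclusive <=).
#' @return The subset of `records` passing both thresholds.
#' @export
filter_candidates <- function(records, time, alpha = 0.05, fc_cut = -1.5) {
  cols <- de_cols(time)
  miss <- setdiff(unlist(cols), names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  p <- records[[cols$p]]; fc <- records[[cols$fc]]
  keep <- !is.na(p) & !is.na(fc) & p < alpha & fc <= fc_cut
  records[keep, , drop = FALSE]
}

#' Prioritize probable direct targets
#'
#' Keeps transcripts downregulated at both time points, with robust
#' control-condition expression (average log2 signal > 10 in either
#' control group) and, where a minimum-free-energy column from an external
#' hybridization tool is provided, a stable predicted duplex
#' (mfe <= -15 kcal/mol). Ranked by the 24 h fold-change (strongest
#' downregulation first).
#'
#' "Downregulated at both time points" has two readings: the default
#' `"nominal"` mode requires p < alpha and fold-change < -1 at each time
#' point; `"strict"` mode additionally requires the full fold-change cut
#' at both time points.
#'
#' @param records data.frame with columns `p_24h`, `fc_24h`, `p_48h`,
#'   `fc_48h`, `control_log2_24h`, `control_log2_48h`, optionally `mfe`.
#' @param mode `"nominal"` (default) or `"strict"`.
#' @param alpha significance level per time point.
#' @param fc_cut strict-mode fold-change cutoff.
#' @param expr_gate control-group log2 expression gate (default 10).
#' @param mfe_cut minimum-free-energy cutoff in kcal/mol (default -15).
#' @return The prioritized subset, ordered by `fc_24h` ascending.
#' @export
prioritize <- function(records, mode = c("nominal", "strict"),
                       alpha = 0.05, fc_cut = -1.5, expr_gate = 10,
                       mfe_cut = -15) {
  mode <- match.arg(mode)
  need <- c("p_24h", "fc_24h", "p_48h", "fc_48h",
            "control_log2_24h", "control_log2_48h")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  down_at <- function(time) {
    cols <- de_cols(time)
    p <- records[[cols$p]]; fc <- records[[cols$fc]]
    ok <- !is.na(p) & !is.na(fc) & p < alpha &
      (if (mode == "strict") fc <= fc_cut else fc < -1)
    ok
  }
  keep <- down_at("24h") & down_at("48h") &
    (pmax(records$control_log2_24h, records$control_log2_48h) > expr_gate)
  if ("mfe" %in% names(records))
    keep <- keep & !is.na(records$mfe) & records$mfe <= mfe_cut
  out <- records[keep, , drop = FALSE]
  out[order(out$fc_24h), , drop = FALSE]
}

#' Prediction-consensus gate
#'
#' TRUE where at least `min_algorithms` of the target-prediction
#' algorithms consistently predict a 3' UTR binding site. Missing
#' consensus counts are conservatively FALSE (with a warning).
#'
#' @param records data.frame with a `prediction_consensus` column
#'   (count of agreeing algorithms out of 12).
#' @param min_algorithms consensus threshold (default 6, inclusive).
#' @return Logical vector parallel to `records`.
#' @export
consensus_gate <- function(records, min_algorithms = 6) {
  if (!"prediction_consensus" %in% names(records))
    stop("missing column: prediction_consensus")
  cc <- records$prediction_consensus
  if (any(is.na(cc)))
    warning(sum(is.na(cc)), " record(s) with missing consensus treated as FALSE")
  !is.na(cc) & cc >= min_algorithms
}
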