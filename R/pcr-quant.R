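#' @title qPCR and reporter-assay quantification
#' @description Threshold-cycle (Ct) aggregation with a detection floor,
#'   delta-Ct relative expression, the delta-delta-Ct allele comparison,
#'   signed linear fold-changes, and dual-luciferase (GLuc/SEAP) reporter
#'   normalization.
#' @name pcr-quant
NULL

CT_FLOOR <- 45

#' Build a validated Ct table
#'
#' Well-level threshold cycles keyed by sample, assay and replicate.
#' Wells whose signal never passed the threshold are "undetected" and are
#' floored to Ct = 45 (the cycle count of the runs).
#'
#' @param sample,assay,replicate,ct parallel vectors; `ct` may be NA for
#'   undetected wells.
#' @param detected logical; defaults to `!is.na(ct) & ct < 45`.
#' @return data.frame of class `ct_table` with columns
#'   `sample`, `assay`, `replicate`, `ct`, `detected`; undetected wells
#'   carry ct = 45.
#' @export
ct_table <- function(sample, assay, replicate, ct, detected = NULL) {
  if (is.null(detected)) detected <- !is.na(ct) & ct < CT_FLOOR
  ct[!detected] <- CT_FLOOR
  if (any(ct <= 0 | ct > CT_FLOOR))
    stop("Ct values must lie in (0, ", CT_FLOOR, "]")
  out <- data.frame(sample = as.character(sample),
                    assay = as.character(assay),
                    replicate = as.integer(replicate),
                    ct = as.numeric(ct), detected = as.logical(detected))
  class(out) <- c("ct_table", class(out))
  out
}

#' Aggregate replicate Ct values
#'
#' Mean or median per (sample, assay) after applying the Ct = 45 floor to
#' undetected wells. Aggregates that include at least one floored well are
#' flagged `at_detection_limit` (they were retained in the source analyses
#' but reflect the assay's sensitivity limit rather than a measurement).
#'
#' @param table a [ct_table()].
#' @param method `"mean"` (cohort-style triplicates) or `"median"`
#'   (cell-culture-style triplicates).
#' @return data.frame with `sample`, `assay`, `ct`, `n_wells`,
#'   `at_detection_limit`.
#' @export
aggregate_ct <- function(table, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "ct_table") || is.data.frame(table))
  if (!nrow(table)) stop("empty Ct table")
  f <- if (method == "mean") mean else stats::median
  key <- interaction(table$sample, table$assay, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    data.frame(sample = table$sample[idx[1]], assay = table$assay[idx[1]],
               ct = f(table$ct[idx]), n_wells = length(idx),
               at_detection_limit = any(!table$detected[idx]))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$sample, out$assay), , drop = FALSE]
}

#' Delta-Ct relative expression
#'
#' delta_ct = Ct_target - Ct_reference; relative expression =
#' 2^-delta_ct x scale. The default x1000 scale factor is cosmetic (all
#' downstream statistics are scale invariant).
#'
#' @param ct_target,ct_reference aggregated Ct values (same sample).
#' @param scale linear scale factor (default 1000).
#' @param at_detection_limit carried through from [aggregate_ct()].
#' @return A list with `delta_ct`, `rel_expr`, `at_detection_limit`.
#' @export
delta_ct_expression <- function(ct_target, ct_reference, scale = 1000,
                                at_detection_limit = FALSE) {
  if (any(is.na(ct_target)) || any(is.na(ct_reference)))
    stop("missing Ct value for target or reference")
  delta <- ct_target - ct_reference
  list(delta_ct = delta, rel_expr = 2^(-delta) * scale,
       at_detection_limit = at_detection_limit)
}

#' Delta-delta-Ct ratio
#'
#' ddCt = (Ct_mir - Ct_ref_mir) - (Ct_precursor - Ct_ref_gene); the
#' returned linear ratio is 2^-ddCt — the mature-miRNA level normalized to
#' the stem-loop precursor level, each against its own reference assay.
#' Invariant to adding a constant to all four Cts (plate shifts).
#'
#' @param ct_mir mature-miRNA Ct.
#' @param ct_ref_mir reference-miRNA Ct.
#' @param ct_precursor precursor-transcript Ct.
#' @param ct_ref_gene reference-gene Ct.
#' @return Numeric linear ratio 2^-ddCt.
#' @export
delta_delta_ct <- function(ct_mir, ct_ref_mir, ct_precursor, ct_ref_gene) {
  args <- list(ct_mir, ct_ref_mir, ct_precursor, ct_ref_gene)
  if (any(vapply(args, function(x) any(is.na(x)), TRUE)))
    stop("all four Ct components are required")
  ddct <- (ct_mir - ct_ref_mir) - (ct_precursor - ct_ref_gene)
  2^(-ddct)
}

#' Rescale ratios to a baseline condition
#'
#' Divides each value by the value of a designated baseline so the
#' baseline equals 1 (e.g. the A allele within each time point, or the
#' 24 h time point within each allele).
#'
#' @param values numeric vector of linear ratios.
#' @param condition vector of condition labels parallel to `values`.
#' @param baseline the condition whose (mean) value becomes 1.
#' @param within optional grouping vector; rescaling is done within each
#'   group separately.
#' @return Numeric vector of rescaled ratios.
#' @export
rescale_to_baseline <- function(values, condition, baseline, within = NULL) {
  if (!baseline %in% condition) stop("baseline condition not present")
  if (is.null(within)) within <- rep(1, length(values))
  out <- values
  for (grp in unique(within)) {
    idx <- within == grp
    base <- mean(values[idx & condition == baseline])
    if (!is.finite(base) || base == 0)
      stop("invalid baseline value in group ", grp)
    out[idx] <- values[idx] / base
  }
  out
}

#' Signed linear fold-change
#'
#' ratio = mean_a / mean_b; for downregulation (ratio < 1) the ratio is
#' inverted and multiplied by -1, so |fold-change| >= 1 always and
#' fold_change(a, b) = -fold_change(b, a) for unequal means.
#'
#' @param mean_a,mean_b positive linear-scale group means.
#' @return Signed fold-change.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(c(mean_a, mean_b) <= 0)) stop("group means must be positive")
  ratio <- mean_a / mean_b
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Normalize dual-luciferase reporter data
#'
#' Per well, duplicate luminescence reads are averaged and the GLuc/SEAP
#' ratio formed; per construct x condition, the mean ratio is normalized
#' to the cotransfection with the 3' UTR control vector (same condition);
#' the percent change of the miRNA condition versus the scrambled
#' condition is reported with a Welch t-test across biological replicates.
#'
#' @param rows data.frame with columns `construct`, `condition`,
#'   `replicate` (biological replicate id), `read` (duplicate index),
#'   `gluc`, `seap`.
#' @param control_construct id of the 3' UTR control vector.
#' @param scrambled_condition id of the scrambled-sequence condition.
#' @return data.frame, one row per non-control construct, with the mean
#'   normalized ratios under both conditions, `percent_change`, `welch_t`,
#'   `welch_df`, `welch_p`.
#' @export
reporter_normalize <- function(rows, control_construct,
                               scrambled_condition) {
  need <- c("construct", "condition", "replicate", "read", "gluc", "seap")
  stopifnot(all(need %in% names(rows)))
  if (!control_construct %in% rows$construct)
    stop("control construct '", control_construct, "' not found")
  if (any(rows$seap <= 0)) stop("non-positive SEAP luminescence")
  # average duplicate reads per (construct, condition, replicate) well
  key <- interaction(rows$construct, rows$condition, rows$replicate,
                     drop = TRUE)
  wells <- do.call(rbind, lapply(split(rows, key), function(d)
    data.frame(construct = d$construct[1], condition = d$condition[1],
               replicate = d$replicate[1],
               ratio = mean(d$gluc) / mean(d$seap))))
  norm_ratio <- function(constr, cond) {
    r <- wells$ratio[wells$construct == constr & wells$condition == cond]
    ctrl <- wells$ratio[wells$construct == control_construct &
                          wells$condition == cond]
    if (!length(ctrl)) stop("missing control rows for condition ", cond)
    if (mean(ctrl) == 0) stop("control ratio is zero for condition ", cond)
    r / mean(ctrl)
  }
  constructs <- setdiff(unique(wells$construct), control_construct)
  conditions <- unique(wells$condition)
  mir_condition <- setdiff(conditions, scrambled_condition)
  if (length(mir_condition) != 1)
    stop("expected exactly one non-scrambled condition, got: ",
         paste(mir_condition, collapse = ", "))
  out <- do.call(rbind, lapply(constructs, function(co) {
    r_mir <- norm_ratio(co, mir_condition)
    r_scr <- norm_ratio(co, scrambled_condition)
    if (mean(r_scr) == 0) stop("scrambled-condition ratio is zero for ", co)
    identical_groups <- length(r_mir) == length(r_scr) &&
      all(r_mir == r_scr)
    w <- if (identical_groups)
      list(statistic = 0, df = 2 * (length(r_mir) - 1), p_value = 1)
    else {
      t <- welch_t(r_mir, r_scr)
      list(statistic = t$statistic, df = t$df, p_value = t$p_value)
    }
    data.frame(construct = co, condition = mir_condition,
               mean_ratio_mir = mean(r_mir),
               mean_ratio_scrambled = mean(r_scr),
               percent_change = (mean(r_mir) / mean(r_scr) - 1) * 100,
               welch_t = w$statistic, welch_df = w$df, welch_p = w$p_value)
  }))
  rownames(out) <- NULL
  out
}
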