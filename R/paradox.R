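#' @title Paradox taxonomy for eQTL results
#' @description Classifies association results into Simpson-like masking
#'   (significant only after adjusting for population), full reversal,
#'   non-transitive correlation triples, and miRNA/host-gene uncoupling.
#'   The decision rules are reconstructions of the published screening
#'   criteria (the original work reports counts but not an explicit rule),
#'   stated here exactly as implemented.
#' @name paradox
NULL

sign0 <- function(x) if (is.na(x) || x == 0) 0 else sign(x)

#' Detect Simpson-like masking or reversal
#'
#' `"masked"`: the genotype effect is significant in the
#' population-adjusted ANCOVA but not in the pooled SLR.
#' `"reversal"`: additionally all per-population slopes share one nonzero
#' sign and the pooled slope has the opposite nonzero sign.
#' `"none"` otherwise.
#'
#' @param slr SLR test result (pooled; its `estimate` is the pooled slope).
#' @param ancova_genotype ANCOVA genotype test result for the same pair.
#' @param per_population_slopes numeric vector of within-population slopes.
#' @param alpha significance level (default 0.05).
#' @return One of `"masked"`, `"reversal"`, `"none"`.
#' @export
detect_simpson <- function(slr, ancova_genotype, per_population_slopes,
                           alpha = 0.05) {
  if (is.null(ancova_genotype) || is.na(ancova_genotype$p_value))
    stop("detect_simpson requires an ANCOVA genotype result")
  masked <- ancova_genotype$p_value < alpha && slr$p_value >= alpha
  if (!masked) return("none")
  ss <- vapply(per_population_slopes, sign0, 0)
  pooled <- sign0(slr$estimate)
  if (length(ss) && all(ss == ss[1]) && ss[1] != 0 && pooled == -ss[1])
    return("reversal")
  "masked"
}

#' Detect a non-transitive correlation triple
#'
#' Fires when the variant correlates with the miRNA and the host transcript
#' in opposite (nonzero) directions while the two RNAs themselves are
#' positively correlated — the signature of a shared primary transcript
#' with an inverse allele-specific processing effect. Correlations that are
#' exactly zero carry no sign and never fire. Setting
#' `require_positive_coupling = FALSE` drops the miR-host condition.
#'
#' @param r_mir_snp,r_host_snp,r_mir_host (population-adjusted)
#'   correlations for the locus.
#' @param require_positive_coupling require `r_mir_host > 0` (default).
#' @return Logical flag.
#' @export
detect_nontransitivity <- function(r_mir_snp, r_host_snp, r_mir_host,
                                   require_positive_coupling = TRUE) {
  opposite <- sign0(r_mir_snp) * sign0(r_host_snp) < 0
  if (!require_positive_coupling) return(opposite)
  opposite && !is.na(r_mir_host) && r_mir_host > 0
}

#' miRNA/host-gene uncoupling score
#'
#' Absolute difference between the variant's correlation with the mature
#' miRNA and with the host transcript; a difference strictly greater than
#' the threshold (default 0.2) counts as substantial uncoupling,
#' suggesting transcription initiation and miRNA processing are controlled
#' independently.
#'
#' @param r_mir_snp,r_host_snp correlations in \[-1, 1\].
#' @param threshold uncoupling threshold (default 0.2, strict >).
#' @return A list with `score` and `flag`.
#' @export
uncoupling_score <- function(r_mir_snp, r_host_snp, threshold = 0.2) {
  stopifnot(abs(r_mir_snp) <= 1, abs(r_host_snp) <= 1)
  score <- abs(r_mir_snp - r_host_snp)
  list(score = score, flag = score > threshold)
}

#' Full paradox classification for one locus
#'
#' Convenience wrapper combining the three detectors from the miRNA and
#' host eQTL records of one (variant, stem-loop) pair. Population-adjusted
#' correlations feed all detectors.
#'
#' @param mir_record,host_record `eqtl_record`s for mature miRNA and host
#'   transcript against the same variant.
#' @param r_mir_host population-adjusted correlation between miRNA and
#'   host levels.
#' @param per_population_slopes within-population slopes for the miRNA.
#' @param alpha significance level.
#' @param uncoupling_threshold threshold for [uncoupling_score()].
#' @param require_positive_coupling passed to [detect_nontransitivity()].
#' @return A list of class `paradox_flags`.
#' @export
paradox_flags <- function(mir_record, host_record, r_mir_host,
                          per_population_slopes = numeric(0), alpha = 0.05,
                          uncoupling_threshold = 0.2,
                          require_positive_coupling = TRUE) {
  r_mir_snp <- mir_record$cor_partial$estimate
  r_host_snp <- host_record$cor_partial$estimate
  unc <- uncoupling_score(r_mir_snp, r_host_snp, uncoupling_threshold)
  structure(list(
    simpson_like = detect_simpson(mir_record$slr, mir_record$ancova$genotype,
                                  per_population_slopes, alpha),
    non_transitive = detect_nontransitivity(r_mir_snp, r_host_snp,
                                            r_mir_host,
                                            require_positive_coupling),
    uncoupled = unc$flag, uncoupling_score = unc$score,
    r_mir_snp = r_mir_snp, r_host_snp = r_host_snp,
    r_mir_host = r_mir_host), class = "paradox_flags")
}

#' @export
print.paradox_flags <- function(x, ...) {
  cat(sprintf("paradox flags: simpson = %s, non-transitive = %s, uncoupled = %s (score %.3f)\n",
              x$simpson_like, x$non_transitive, x$uncoupled,
              x$uncoupling_score))
  cat(sprintf("  r(miR,SNP) = %.3f, r(host,SNP) = %.3f, r(miR,host) = %.3f\n",
              x$r_mir_snp, x$r_host_snp, x$r_mir_host))
  invisible(x)
}
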