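#' @title Genome-wide stem-loop SNP scan
#' @description Selects biallelic SNPs inside or within a flanking window
#'   of annotated miRNA stem-loops, annotates their position relative to
#'   the precursor (strand-aware), runs the association panel for each
#'   mature miRNA and the host transcript, retains variants with a
#'   significant genotype effect on the mature miRNA, and attaches paradox
#'   flags.
#' @name mir-scan
NULL

#' Scan configuration
#'
#' @param flank bases beyond the stem-loop on each side (default 25,
#'   the published window).
#' @param alpha genotype-effect retention threshold (default 0.05).
#' @param uncoupling_threshold uncoupling threshold (default 0.2).
#' @param interaction include genotype x population interaction in ANCOVA.
#' @param lmm also fit the random-intercept LMM per retained pair.
#' @param autosomes_only restrict to autosomal variants (chromosomes
#'   1-22, with or without a "chr" prefix).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(flank = 25L, alpha = 0.05,
                        uncoupling_threshold = 0.2, interaction = FALSE,
                        lmm = TRUE, autosomes_only = TRUE) {
  stopifnot(flank >= 0, alpha >= 0, alpha <= 1)
  structure(list(flank = as.integer(flank), alpha = alpha,
                 uncoupling_threshold = uncoupling_threshold,
                 interaction = interaction, lmm = lmm,
                 autosomes_only = autosomes_only), class = "scan_config")
}

is_autosome <- function(chrom) {
  grepl("^(chr)?([1-9]|1[0-9]|2[0-2])$", chrom)
}

#' Select biallelic SNPs in or near miRNA stem-loops
#'
#' Keeps biallelic single-nucleotide variants whose 0-based position falls
#' in the half-open window `[start - flank, end + flank)` of a stem-loop
#' ("in the stem-loop or within `flank` bases of flanking sequence").
#' Multiallelic or indel records are dropped and counted.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based,
#'   VCF convention), `ref`, `alt`.
#' @param stem_loops data.frame of stem-loop annotations (see
#'   [read_stem_loops()]): `mir_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `host_id`, optionally `mature_5p`, `mature_3p`.
#' @param config a [scan_config()].
#' @return data.frame of (variant, stem-loop) hits with variant and
#'   stem-loop columns plus `position_label`; attribute `n_dropped`
#'   counts non-SNP/multiallelic records.
#' @export
filter_stem_loop_snps <- function(variants, stem_loops,
                                  config = scan_config()) {
  stopifnot(all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
            all(c("mir_id", "chrom", "start", "end", "strand") %in%
                  names(stem_loops)))
  strip <- function(ch) sub("^chr", "", as.character(ch))
  if (length(intersect(strip(variants$chrom), strip(stem_loops$chrom))) == 0 &&
      nrow(variants) && nrow(stem_loops))
    stop("no shared chromosome names between variants and stem-loops; ",
         "check the 'chr' prefix convention of the two files")
  snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    !grepl(",", variants$alt) & variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T")
  n_dropped <- sum(!snv)
  if (n_dropped)
    message(n_dropped, " non-biallelic-SNP record(s) dropped")
  vv <- variants[snv, , drop = FALSE]
  if (config$autosomes_only) vv <- vv[is_autosome(vv$chrom), , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(stem_loops))) {
    sl <- stem_loops[i, ]
    pos0 <- vv$pos - 1L  # VCF 1-based -> 0-based
    inwin <- strip(vv$chrom) == strip(sl$chrom) &
      pos0 >= sl$start - config$flank & pos0 < sl$end + config$flank
    if (!any(inwin)) next
    sub <- vv[inwin, , drop = FALSE]
    sub$mir_id <- sl$mir_id
    sub$sl_chrom <- sl$chrom
    sub$sl_start <- sl$start
    sub$sl_end <- sl$end
    sub$strand <- sl$strand
    sub$host_id <- if ("host_id" %in% names(sl)) sl$host_id else NA_character_
    for (arm in c("mature_5p", "mature_3p"))
      sub[[arm]] <- if (arm %in% names(sl)) sl[[arm]] else NA_character_
    sub$position_label <- vapply(sub$pos, function(p)
      annotate_relative_position(p, sl), "")
    hits[[length(hits) + 1]] <- sub
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    cbind(vv[0, , drop = FALSE],
          data.frame(mir_id = character(0), sl_chrom = character(0),
                     sl_start = integer(0), sl_end = integer(0),
                     strand = character(0), host_id = character(0),
                     mature_5p = character(0), mature_3p = character(0),
                     position_label = character(0)))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Position of a variant relative to a stem-loop
#'
#' Returns `"P"` for positions inside the precursor (`[start, end)` in
#' 0-based coordinates), `"+k"` for k bases past the 3' end and `"-k"` for
#' k bases before the 5' end, in transcription orientation: on minus-strand
#' stem-loops the genomic left flank is downstream (+) and the genomic
#' right flank is upstream (-). The first flanking base is k = 1.
#'
#' @param pos 1-based variant position (VCF convention).
#' @param stem_loop one-row stem-loop data.frame (`start`, `end` 0-based
#'   half-open, `strand`).
#' @return Character label.
#' @export
annotate_relative_position <- function(pos, stem_loop) {
  pos0 <- pos - 1L
  start <- stem_loop$start; end <- stem_loop$end
  if (pos0 >= start && pos0 < end) return("P")
  if (pos0 < start) {
    k <- start - pos0
    lab <- if (stem_loop$strand == "+") paste0("-", k) else paste0("+", k)
  } else if (pos0 >= end) {
    k <- pos0 - end + 1L
    lab <- if (stem_loop$strand == "+") paste0("+", k) else paste0("-", k)
  }
  lab
}

per_population_slopes <- function(y, g, pop) {
  vapply(split(seq_along(y), pop), function(idx) {
    yy <- y[idx]; gg <- g[idx]
    if (length(unique(gg[!is.na(gg)])) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(yy ~ gg))[2])
  }, 0)
}

#' Genome-wide cis-miR-eQTL scan
#'
#' For every (variant, stem-loop) pair passing [filter_stem_loop_snps()],
#' runs the association panel for each annotated mature miRNA present in
#' the expression data and for the host transcript, retains pairs whose
#' ANCOVA genotype effect on the mature miRNA is significant at
#' `config$alpha`, and attaches population-adjusted correlations and
#' paradox flags. When a stem-loop yields both 5p and 3p mature miRNAs,
#' each is tested separately. Stem-loops whose host transcript is absent
#' from `host_expr` are skipped with a message. Output rows are sorted by
#' genomic position; re-running on identical inputs is deterministic.
#'
#' @param mir_expr [expression_table()] of mature miRNA levels
#'   (linear scale; zeros retained).
#' @param host_expr [expression_table()] of host transcript levels.
#' @param genotypes a [genotype_matrix()].
#' @param metadata data.frame with `sample` and `population`, covering the
#'   rows of the expression tables and genotypes (matched by sample id).
#' @param stem_loops stem-loop annotation data.frame (see
#'   [filter_stem_loop_snps()]); a `host_id` column is required, and
#'   `mature_5p` / `mature_3p` name the mature miRNA feature(s); if both
#'   are NA the `mir_id` itself is looked up in `mir_expr`.
#' @param config a [scan_config()].
#' @return data.frame of class `scan_result`, one row per retained
#'   (variant, mature miRNA) pair, with association statistics,
#'   correlations, paradox columns and a Benjamini-Hochberg adjusted
#'   p-value column (informational; retention uses the nominal alpha).
#' @export
scan_stem_loops <- function(mir_expr, host_expr, genotypes, metadata,
                            stem_loops, config = scan_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            "host_id" %in% names(stem_loops))
  hits <- filter_stem_loop_snps(genotypes$variants, stem_loops, config)
  samples <- metadata$sample
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (is.na(h$host_id) || !(h$host_id %in% colnames(host_expr))) {
      message("skipping ", h$mir_id, ": host transcript ", h$host_id,
              " not in host expression table")
      next
    }
    matures <- c(h$mature_5p, h$mature_3p)
    matures <- matures[!is.na(matures)]
    if (!length(matures)) matures <- h$mir_id
    matures <- intersect(matures, colnames(mir_expr))
    if (!length(matures)) {
      message("skipping ", h$mir_id, ": no mature miRNA in expression table")
      next
    }
    g <- genotypes$geno[match(samples, rownames(genotypes$geno)), h$id]
    host <- host_expr[match(samples, rownames(host_expr)), h$host_id]
    for (m in matures) {
      mir <- mir_expr[match(samples, rownames(mir_expr)), m]
      mrec <- tryCatch(run_eqtl(mir, g, metadata, interaction = config$interaction,
                                lmm = config$lmm, alpha = config$alpha,
                                feature_id = m, variant_id = h$id),
                       error = function(e) NULL)
      if (is.null(mrec) || mrec$ancova$genotype$p_value >= config$alpha) next
      hrec <- tryCatch(run_eqtl(host, g, metadata,
                                interaction = config$interaction,
                                lmm = FALSE, alpha = config$alpha,
                                feature_id = h$host_id, variant_id = h$id),
                       error = function(e) NULL)
      if (is.null(hrec)) next
      keep <- !is.na(mir) & !is.na(host) & !is.na(g)
      r_mh <- partial_pearson(mir[keep], host[keep],
                              metadata$population[keep])$estimate
      slopes <- per_population_slopes(mir, g, metadata$population)
      fl <- paradox_flags(mrec, hrec, r_mh, slopes, config$alpha,
                          config$uncoupling_threshold)
      rows[[length(rows) + 1]] <- data.frame(
        mir_id = h$mir_id, mature_id = m, host_id = h$host_id,
        variant_id = h$id, chrom = h$chrom, pos = h$pos,
        position_label = h$position_label, strand = h$strand,
        n = mrec$n,
        mir_slr_p = mrec$slr$p_value,
        mir_anova_pop_p = mrec$anova_population$p_value,
        mir_ancova_p = mrec$ancova$genotype$p_value,
        mir_ancova_slope = mrec$ancova$genotype$estimate,
        mir_lmm_p = if (!is.null(mrec$lmm)) mrec$lmm$genotype_wald$p_value else NA_real_,
        host_slr_p = hrec$slr$p_value,
        host_ancova_p = hrec$ancova$genotype$p_value,
        host_ancova_slope = hrec$ancova$genotype$estimate,
        r_mir_snp = fl$r_mir_snp, r_host_snp = fl$r_host_snp,
        r_mir_host = fl$r_mir_host,
        uncoupling_score = fl$uncoupling_score,
        simpson = fl$simpson_like,
        non_transitive = fl$non_transitive,
        uncoupled = fl$uncoupled)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(out)) {
    out <- out[order(out$chrom, out$pos, out$mature_id), , drop = FALSE]
    out$mir_ancova_p_bh <- stats::p.adjust(out$mir_ancova_p, "BH")
    rownames(out) <- NULL
  }
  class(out) <- c("scan_result", class(out))
  out
}
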