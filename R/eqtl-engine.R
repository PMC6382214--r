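#' @title Per-feature eQTL analysis panel
#' @description Runs the full association panel for one (variant, feature)
#'   pair: genotype-group counts and means, SLR, one-way ANOVA on
#'   population, type II ANCOVA, optional random-intercept LMM, pairwise
#'   Welch t-tests between genotype groups, and plain plus
#'   population-adjusted correlations.
#' @name eqtl-engine
NULL

#' Average replicate measurements per individual
#'
#' Arithmetic mean per individual per feature on the table's stored scale;
#' missing replicates are dropped (pairwise-complete), so an individual's
#' value is the mean of the replicates actually present.
#'
#' @param expr an [expression_table()] whose rows are replicates.
#' @param replicate_map data.frame with columns `replicate` (matching
#'   rownames of `expr`) and `individual`.
#' @return An [expression_table()] with one row per individual and an
#'   `n_replicates` attribute (individuals x features count matrix).
#' @export
average_replicates <- function(expr, replicate_map) {
  stopifnot(inherits(expr, "expression_table"),
            all(c("replicate", "individual") %in% names(replicate_map)))
  miss <- setdiff(rownames(expr), replicate_map$replicate)
  if (length(miss))
    stop("replicates without an individual mapping: ",
         paste(miss, collapse = ", "))
  idx <- match(rownames(expr), replicate_map$replicate)
  ind <- factor(replicate_map$individual[idx],
                levels = unique(replicate_map$individual[idx]))
  vals <- unclass(expr)
  means <- apply(vals, 2, function(col) tapply(col, ind, mean, na.rm = TRUE))
  ns <- apply(vals, 2, function(col) tapply(!is.na(col), ind, sum))
  means <- matrix(means, nrow = nlevels(ind),
                  dimnames = list(levels(ind), colnames(vals)))
  means[is.nan(means)] <- NA_real_
  out <- expression_table(means, scale = attr(expr, "scale"),
                          kind = attr(expr, "kind"))
  attr(out, "n_replicates") <- matrix(ns, nrow = nlevels(ind),
                                      dimnames = dimnames(means))
  out
}

#' Run the full eQTL association panel
#'
#' @param y numeric expression vector for one feature (analysis scale as
#'   stored: log2 data stay log2, count/RPKM data stay linear).
#' @param g numeric genotype vector (0/1/2 additive allele counts).
#' @param metadata data.frame with a `population` column, rows parallel to
#'   `y` and `g`.
#' @param interaction include a genotype x population interaction in the
#'   ANCOVA.
#' @param lmm also fit the random-intercept LMM.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05, the conventional nominal level).
#' @param feature_id,variant_id identifiers carried into the record.
#' @return A list of class `eqtl_record` with per-genotype `counts` and
#'   `means`, `slr`, `anova_population`, `ancova`, optional `lmm`,
#'   `pairwise_welch` (named by genotype pair; groups with < 2 samples are
#'   excluded), `cor_plain`, `cor_partial`, `significant`
#'   (ANCOVA genotype p < alpha) and `n`.
#' @export
run_eqtl <- function(y, g, metadata, interaction = FALSE, lmm = FALSE,
                     alpha = 0.05, feature_id = NA_character_,
                     variant_id = NA_character_) {
  stopifnot(is.data.frame(metadata), "population" %in% names(metadata))
  pop <- metadata$population
  v <- complete_cases_of(as.numeric(y), as.numeric(g), as.character(pop))
  y <- v[[1]]; g <- v[[2]]; pop <- factor(v[[3]])
  n <- length(y)
  if (n < 3) stop("run_eqtl needs >= 3 complete samples")
  gf <- factor(g, levels = 0:2)
  counts <- table(gf)
  if (sum(counts > 0) < 2)
    stop("single genotype group for variant ", variant_id,
         "; association is undefined")
  means <- tapply(y, gf, mean)
  rec <- list(feature_id = feature_id, variant_id = variant_id,
              counts = counts, means = means, n = n,
              slr = slr_ftest(y, g),
              anova_population = anova_oneway(y, pop),
              ancova = ancova_type2(y, g, pop, with_interaction = interaction))
  if (lmm) rec$lmm <- lmm_random_intercept(y, g, pop)
  pairs <- utils::combn(which(counts >= 2) - 1L, 2, simplify = FALSE)
  welch <- lapply(pairs, function(pr)
    welch_t(y[g == pr[1]], y[g == pr[2]]))
  names(welch) <- vapply(pairs, function(pr)
    paste0(pr[1], "-", pr[2]), "")
  rec$pairwise_welch <- welch
  rec$cor_plain <- pearson(g, y)
  rec$cor_partial <- partial_pearson(g, y, pop)
  rec$alpha <- alpha
  rec$significant <- rec$ancova$genotype$p_value < alpha
  structure(rec, class = "eqtl_record")
}

#' @export
print.eqtl_record <- function(x, ...) {
  cat(sprintf("eQTL record: %s ~ %s (n = %d)\n", x$feature_id, x$variant_id, x$n))
  cat("  genotype counts:", paste(names(x$counts), x$counts, sep = "=",
                                  collapse = " "), "\n")
  cat(sprintf("  SLR p = %.4g | ANOVA(pop) p = %.4g | ANCOVA genotype p = %.4g\n",
              x$slr$p_value, x$anova_population$p_value,
              x$ancova$genotype$p_value))
  if (!is.null(x$lmm))
    cat(sprintf("  LMM genotype Wald p = %.4g\n", x$lmm$genotype_wald$p_value))
  cat(sprintf("  r = %.3f (plain), %.3f (population-adjusted)\n",
              x$cor_plain$estimate, x$cor_partial$estimate))
  invisible(x)
}

#' Ratio eQTL of miRNA to host-gene levels
#'
#' Computes the per-sample ratio miR / host on the linear scale and runs
#' the full panel on the ratio. The F-tests are invariant to any global
#' rescaling of either input, so cosmetic scale factors (for example a
#' x1000 convenience factor on 2^-dCt values) do not change the p-values;
#' the returned ratios are on the scale of the inputs as given.
#'
#' @param mir,host numeric linear-scale vectors; `host` must be strictly
#'   positive.
#' @inheritParams run_eqtl
#' @return An `eqtl_record` for the ratio.
#' @export
ratio_eqtl <- function(mir, host, g, metadata, interaction = FALSE,
                       lmm = FALSE, alpha = 0.05,
                       feature_id = "miR/host ratio",
                       variant_id = NA_character_) {
  bad <- which(!is.na(host) & host <= 0)
  if (length(bad))
    stop("non-positive host values for sample(s): ",
         paste(bad, collapse = ", "))
  run_eqtl(mir / host, g, metadata, interaction = interaction, lmm = lmm,
           alpha = alpha, feature_id = feature_id, variant_id = variant_id)
}
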