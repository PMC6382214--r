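#' Expression table
#'
#' A samples x features numeric matrix carrying its analysis scale and the
#' kind of feature it holds. Log2 microarray intensities stay in log2;
#' RPKM and normalized miRNA counts stay linear. Downstream analyses use the
#' values as stored (the analysis scale follows the source platform).
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids).
#' @param scale `"log2"` or `"linear"`.
#' @param kind `"mRNA"` or `"miRNA"`.
#' @return An object of class `expression_table` (a numeric matrix with
#'   `scale` and `kind` attributes).
#' @export
expression_table <- function(values, scale = c("linear", "log2"),
                             kind = c("mRNA", "miRNA")) {
  scale <- match.arg(scale)
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  structure(values, scale = scale, kind = kind,
            class = c("expression_table", class(values)))
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d samples x %d features (%s, %s scale)\n",
              nrow(x), ncol(x), attr(x, "kind"), attr(x, "scale")))
  invisible(x)
}

#' Genotype matrix
#'
#' Additive allele counts (0/1/2, NA allowed) for samples x variants, with
#' per-variant coordinates and alleles. Coordinates are stored 1-based
#' (as in VCF); conversion to the internal 0-based half-open convention
#' happens where intervals are compared.
#'
#' @param geno numeric matrix samples x variants of values in {0,1,2,NA}.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per column of `geno`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, variants) {
  geno <- as.matrix(geno)
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  if (ncol(geno) != nrow(variants))
    stop("geno has ", ncol(geno), " variant columns but variants has ",
         nrow(variants), " rows")
  ok <- geno %in% c(0, 1, 2) | is.na(geno)
  if (!all(ok)) stop("genotypes must be additive allele counts 0/1/2 or NA")
  colnames(geno) <- variants$id
  structure(list(geno = geno, variants = variants), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$geno), nrow(x$variants)))
  invisible(x)
}

# Internal constructor for a single-test result. Every statistical
# primitive returns one of these so records can be assembled uniformly.
test_result <- function(statistic, df, p_value, estimate = NA_real_,
                        n = NA_integer_, method = NA_character_) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), estimate = unname(estimate),
                 n = as.integer(n), method = method),
            class = "mireqtl_test")
}

#' @export
print.mireqtl_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g, estimate = %.4g (n = %d)\n",
              x$method, x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value, x$estimate, x$n))
  invisible(x)
}
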