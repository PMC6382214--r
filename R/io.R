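#' @title Readers and writers for standard formats
#' @description VCF / 0-1-2 TSV genotype input, BED6 / GFF3 stem-loop
#'   annotation input, and the scan report writer. Internal interval
#'   coordinates are uniformly 0-based half-open; all conversions happen
#'   at the I/O boundary (VCF and GFF3 are 1-based, BED is 0-based).
#' @name io
NULL

#' Read a genotype matrix
#'
#' VCF genotypes are converted to additive alternate-allele counts from
#' the GT field (phase is ignored; `./.` becomes NA). A 0-1-2 TSV has
#' sample rows x variant columns of values in \{0, 1, 2, NA\}; variant
#' coordinates can then be supplied via `variants`.
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv012"`; default guesses from the
#'   extension.
#' @param multiallelic for VCF, `"skip"` (default) drops multiallelic
#'   sites with a message; `"error"` stops.
#' @param variants for `tsv012`, an optional data.frame
#'   (`id`, `chrom`, `pos`, `ref`, `alt`); placeholder coordinates are
#'   used if omitted.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv012"),
                           multiallelic = c("skip", "error"),
                           variants = NULL) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv012"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) {
      if (multiallelic == "error") stop(sum(multi), " multiallelic site(s)")
      message(sum(multi), " multiallelic site(s) skipped")
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    count_alt <- function(x) {
      alleles <- strsplit(gsub("\\|", "/", x), "/")
      vapply(alleles, function(a) {
        if (any(a == "." | is.na(a))) return(NA_real_)
        sum(a != "0")
      }, 0)
    }
    geno <- t(apply(gt, 1, count_alt))
    geno[is.na(gt)] <- NA
    ids <- fix$ID
    ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
    genotype_matrix(t(geno),
                    data.frame(id = ids, chrom = fix$CHROM,
                               pos = as.integer(fix$POS),
                               ref = fix$REF, alt = fix$ALT))
  } else {
    tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    geno <- as.matrix(tab)
    if (is.null(variants))
      variants <- data.frame(id = colnames(geno), chrom = NA_character_,
                             pos = NA_integer_, ref = NA_character_,
                             alt = NA_character_)
    genotype_matrix(geno, variants)
  }
}

#' Read an expression table
#'
#' TSV with sample rows x feature columns; the first column holds sample
#' ids.
#'
#' @param path input TSV.
#' @param scale,kind passed to [expression_table()].
#' @return An [expression_table()].
#' @export
read_expression <- function(path, scale = c("linear", "log2"),
                            kind = c("mRNA", "miRNA")) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  expression_table(as.matrix(tab), scale = match.arg(scale),
                   kind = match.arg(kind))
}

#' Read miRNA stem-loop annotations
#'
#' BED6 (0-based half-open) or GFF3 (1-based closed) input, unified to the
#' internal 0-based half-open convention. The BED name column / the GFF3
#' `Name` (or `ID`) attribute becomes `mir_id`; a GFF3 `host_gene`
#' attribute (or a separate `host_map` data.frame of `mir_id`, `host_id`,
#' optionally `mature_5p`, `mature_3p`) supplies the host-gene pairing.
#' Strand is required.
#'
#' @param path input file.
#' @param format `"bed"`, `"gff3"`, or `"auto"` (extension-based).
#' @param host_map optional pairing data.frame joined on `mir_id`.
#' @return data.frame with columns `mir_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `host_id`, `mature_5p`, `mature_3p`.
#' @export
read_stem_loops <- function(path, format = c("auto", "bed", "gff3"),
                            host_map = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(gff3?|gff)$", path)) "gff3" else "bed"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("stem-loop strand is required ('.'/'*' found)")
  md <- as.data.frame(gr)
  mir_id <- if (format == "bed") md$name else {
    nm <- if ("Name" %in% names(md)) md$Name else NULL
    if (is.null(nm) || all(is.na(nm))) nm <- md$ID
    nm
  }
  if (is.null(mir_id) || any(is.na(mir_id)))
    stop("every stem-loop needs a name (BED name column / GFF3 Name or ID)")
  out <- data.frame(
    mir_id = as.character(mir_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # GRanges is 1-based closed internally -> 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    host_id = if ("host_gene" %in% names(md)) as.character(md$host_gene) else NA_character_,
    mature_5p = if ("mature_5p" %in% names(md)) as.character(md$mature_5p) else NA_character_,
    mature_3p = if ("mature_3p" %in% names(md)) as.character(md$mature_3p) else NA_character_)
  if (!is.null(host_map)) {
    stopifnot(all(c("mir_id", "host_id") %in% names(host_map)))
    i <- match(out$mir_id, host_map$mir_id)
    out$host_id <- ifelse(is.na(i), out$host_id, host_map$host_id[i])
    for (arm in c("mature_5p", "mature_3p"))
      if (arm %in% names(host_map))
        out[[arm]] <- ifelse(is.na(i), out[[arm]], host_map[[arm]][i])
  }
  out
}

#' Read sample metadata
#'
#' TSV with at least `sample` and `population` columns.
#'
#' @param path input TSV.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE)
  miss <- setdiff(c("sample", "population"), names(md))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  md
}

#' Write the scan report
#'
#' Deterministic TSV: fixed column order, rows sorted by (chrom, pos,
#' mature_id), floating values at fixed precision. A JSON sidecar records
#' the configuration, seed and package version, so a report can always be
#' traced back to its run.
#'
#' @param rows a `scan_result` (or compatible data.frame).
#' @param path output TSV path.
#' @param config the [scan_config()] used.
#' @param seed the seed used for any simulated inputs (NA for real data).
#' @param digits significant digits for floating columns (default 6).
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(rows, path, config = scan_config(),
                              seed = NA_integer_, digits = 6) {
  cols <- c("mir_id", "mature_id", "host_id", "variant_id", "chrom", "pos",
            "position_label", "strand", "n", "mir_slr_p", "mir_anova_pop_p",
            "mir_ancova_p", "mir_ancova_slope", "mir_lmm_p", "host_slr_p",
            "host_ancova_p", "host_ancova_slope", "r_mir_snp", "r_host_snp",
            "r_mir_host", "uncoupling_score", "simpson", "non_transitive",
            "uncoupled", "mir_ancova_p_bh")
  if (nrow(rows) == 0) {
    empty <- stats::setNames(rep(list(character(0)), length(cols)), cols)
    utils::write.table(as.data.frame(empty), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    out <- rows[, intersect(cols, names(rows)), drop = FALSE]
    out <- out[order(out$chrom, out$pos, out$mature_id), , drop = FALSE]
    num <- vapply(out, is.numeric, TRUE) &
      !vapply(out, is.integer, TRUE)
    out[num] <- lapply(out[num], signif, digits = digits)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  side <- list(config = unclass(config), seed = seed,
               package = "mireqtl",
               version = as.character(utils::packageVersion("mireqtl")),
               n_rows = nrow(rows))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
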