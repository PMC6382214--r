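# Text fixtures built in code at test time.

write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "1000", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "2000", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0|1", "./.", "1/1", sep = "\t"),
    paste("1", "3000", "rs3", "G", "A,T", ".", "PASS", ".", "GT",
          "0/1", "0/0", "0/0", sep = "\t"),
    paste("1", "4000", "indel1", "AT", "A", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"))
  writeLines(lines, path)
  path
}

write_toy_bed <- function(path = tempfile(fileext = ".bed")) {
  writeLines(paste("1", "99", "120", "mir-x", "0", "+", sep = "\t"), path)
  path
}

write_toy_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    paste("1", "toy", "miRNA_primary_transcript", "100", "120", ".", "+",
          ".", "ID=mir-x;Name=mir-x;host_gene=HOSTX", sep = "\t")), path)
  path
}

# one-variant / one-stem-loop scan inputs around a simulated cohort; the
# variant sits inside the stem-loop so it always passes the window filter
scan_inputs <- function(design = cohort_design(), seed = 1L) {
  co <- simulate_cohort(design, seed = seed, variant_id = "rs_sim",
                        host_id = "HOST", mir_id = "miR-sim")
  co$genotypes$variants$chrom <- "1"
  co$genotypes$variants$pos <- 1000L
  stem_loops <- data.frame(mir_id = "mir-sim", chrom = "1", start = 980L,
                           end = 1060L, strand = "+", host_id = "HOST",
                           mature_5p = "miR-sim", mature_3p = NA_character_)
  c(co, list(stem_loops = stem_loops))
}

# multi-variant null scan inputs: k independent null (variant, stem-loop,
# miRNA, host) quartets in one cohort
null_scan_inputs <- function(k = 24, n = 465, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))
  pop <- factor(rep(c("CEU", "FIN", "GBR", "TSI", "YRI"),
                    length.out = n))
  freq <- ifelse(pop == "YRI", 0.40, 0.86)
  geno <- sapply(seq_len(k), function(j) rbinom(n, 2, freq))
  dimnames(geno) <- list(ids, sprintf("rs%03d", seq_len(k)))
  variants <- data.frame(id = colnames(geno), chrom = "1",
                         pos = 1000L + 200L * seq_len(k),
                         ref = "A", alt = "G")
  base <- as.numeric(pop) * 5
  host <- sapply(seq_len(k), function(j) 50 + base + rnorm(n, 0, 6))
  mir <- sapply(seq_len(k), function(j) {
    m <- pmax(0, 8 + rnorm(n, 0, 2))
    m[runif(n) < 0.403] <- 0
    m
  })
  dimnames(host) <- list(ids, sprintf("HOST%03d", seq_len(k)))
  dimnames(mir) <- list(ids, sprintf("miR%03d", seq_len(k)))
  stem_loops <- data.frame(mir_id = sprintf("mir%03d", seq_len(k)),
                           chrom = "1", start = 1000L + 200L * seq_len(k) - 10L,
                           end = 1000L + 200L * seq_len(k) + 70L,
                           strand = "+", host_id = colnames(host),
                           mature_5p = colnames(mir),
                           mature_3p = NA_character_)
  list(genotypes = genotype_matrix(geno, variants),
       host = expression_table(host, "linear", "mRNA"),
       mir = expression_table(mir, "linear", "miRNA"),
       metadata = data.frame(sample = ids, population = pop),
       stem_loops = stem_loops)
}
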