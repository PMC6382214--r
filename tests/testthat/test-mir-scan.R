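toy_variants <- function(pos, id = sprintf("v%02d", seq_along(pos)),
                         ref = "A", alt = "G", chrom = "1") {
  data.frame(id = id, chrom = chrom, pos = pos, ref = ref, alt = alt)
}

toy_sl <- function(start = 1000L, end = 1100L, strand = "+", chrom = "1") {
  data.frame(mir_id = "mir-t", chrom = chrom, start = start, end = end,
             strand = strand, host_id = "HOSTT",
             mature_5p = NA_character_, mature_3p = NA_character_)
}

test_that("the flank window keeps 'within 25 bases' and drops beyond", {
  sl <- toy_sl(1000L, 1100L)   # 0-based half-open
  # VCF pos is 1-based: pos0 = pos - 1
  vv <- toy_variants(c(
    976,    # pos0 975 = start - 25: exactly 25 bases upstream -> kept
    975,    # pos0 974 = start - 26 -> dropped
    1001,   # pos0 1000 = start -> inside
    1100,   # pos0 1099 = last precursor base -> inside
    1125,   # pos0 1124 = end + 24 -> 25th downstream base, kept
    1126))  # pos0 1125 = end + 25 -> 26 bases downstream, dropped
  hits <- filter_stem_loop_snps(vv, sl)
  expect_setequal(hits$id, c("v01", "v03", "v04", "v05"))
  expect_equal(hits$position_label[hits$id == "v01"], "-25")
  expect_equal(hits$position_label[hits$id == "v03"], "P")
  expect_equal(hits$position_label[hits$id == "v04"], "P")
  expect_equal(hits$position_label[hits$id == "v05"], "+25")
})

test_that("indels and multiallelic records are dropped and counted", {
  vv <- rbind(toy_variants(1050, "snp"),
              data.frame(id = "ind", chrom = "1", pos = 1051, ref = "AT",
                         alt = "A"),
              data.frame(id = "multi", chrom = "1", pos = 1052, ref = "G",
                         alt = "A,T"))
  hits <- suppressMessages(filter_stem_loop_snps(vv, toy_sl()))
  expect_equal(hits$id, "snp")
  expect_equal(attr(hits, "n_dropped"), 2)
})

test_that("sex-chromosome variants are excluded unless requested", {
  vv <- toy_variants(c(1050, 1050), id = c("a1", "x1"),
                     chrom = c("1", "X"))
  sls <- rbind(toy_sl(chrom = "1"), toy_sl(chrom = "X"))
  auto <- filter_stem_loop_snps(vv, sls)
  expect_equal(auto$id, "a1")
  all_chr <- filter_stem_loop_snps(vv, sls,
                                   scan_config(autosomes_only = FALSE))
  expect_setequal(all_chr$id, c("a1", "x1"))
})

test_that("chromosome naming mismatches raise a hint", {
  expect_error(filter_stem_loop_snps(toy_variants(1050, chrom = "2"),
                                     toy_sl(chrom = "1")),
               "chr")
})

test_that("relative position labels are strand aware", {
  plus <- toy_sl(1000L, 1100L, "+")
  minus <- toy_sl(1000L, 1100L, "-")
  # 11 bases past the 3' end on the plus strand (pos0 = end + 10)
  expect_equal(annotate_relative_position(1111, plus), "+11")
  # the same genomic offset is upstream of a minus-strand loop
  expect_equal(annotate_relative_position(1111, minus), "-11")
  # genomic left flank: upstream of plus, downstream of minus
  expect_equal(annotate_relative_position(995, plus), "-6")
  expect_equal(annotate_relative_position(995, minus), "+6")
  # precursor positions are P on either strand
  expect_equal(annotate_relative_position(1001, plus), "P")
  expect_equal(annotate_relative_position(1001, minus), "P")
})

test_that("a planted inverse eQTL is recovered with its paradox flags", {
  si <- scan_inputs(seed = 5)
  res <- scan_stem_loops(si$mir, si$host, si$genotypes, si$metadata,
                         si$stem_loops, scan_config(lmm = TRUE))
  expect_equal(nrow(res), 1)
  expect_equal(res$variant_id, "rs_sim")
  expect_equal(res$position_label, "P")
  expect_lt(res$mir_ancova_p, 0.05)
  expect_true(res$non_transitive)
  expect_true(res$uncoupled)
  expect_gt(res$r_mir_snp, 0)
  expect_lt(res$r_host_snp, 0)
  expect_gt(res$r_mir_host, 0)
  expect_false(is.na(res$mir_lmm_p))
  # retention rule holds on every emitted row
  expect_true(all(res$mir_ancova_p < 0.05))
})

test_that("alpha = 0 yields an empty scan and missing hosts are skipped", {
  si <- scan_inputs(seed = 5)
  none <- scan_stem_loops(si$mir, si$host, si$genotypes, si$metadata,
                          si$stem_loops, scan_config(alpha = 0))
  expect_equal(nrow(none), 0)

  sl_bad <- si$stem_loops
  sl_bad$host_id <- "MISSING"
  expect_message(
    skipped <- scan_stem_loops(si$mir, si$host, si$genotypes, si$metadata,
                               sl_bad),
    "not in host expression")
  expect_equal(nrow(skipped), 0)
})

test_that("scanning is deterministic and sorted by position", {
  ni <- null_scan_inputs(k = 8, seed = 3)
  # plant one strong effect so some rows survive
  g <- ni$genotypes$geno[, 1]
  mir1 <- pmax(0, 8 + 3 * g + rnorm(length(g), 0, 2))
  vals <- unclass(ni$mir); vals[, 1] <- mir1
  ni$mir <- expression_table(vals, "linear", "miRNA")
  r1 <- scan_stem_loops(ni$mir, ni$host, ni$genotypes, ni$metadata,
                        ni$stem_loops, scan_config(lmm = FALSE))
  r2 <- scan_stem_loops(ni$mir, ni$host, ni$genotypes, ni$metadata,
                        ni$stem_loops, scan_config(lmm = FALSE))
  expect_identical(r1, r2)
  if (nrow(r1) > 1) expect_true(!is.unsorted(r1$pos))
})

test_that("both mature arms of a stem-loop are tested separately", {
  si <- scan_inputs(seed = 9)
  # add a 3p arm sharing the planted signal
  vals <- cbind(unclass(si$mir), unclass(si$mir)[, 1] + 0.5)
  colnames(vals) <- c("miR-sim", "miR-sim-3p")
  mir2 <- expression_table(vals, "linear", "miRNA")
  sl <- si$stem_loops
  sl$mature_3p <- "miR-sim-3p"
  res <- scan_stem_loops(mir2, si$host, si$genotypes, si$metadata, sl,
                         scan_config(lmm = FALSE))
  expect_setequal(res$mature_id, c("miR-sim", "miR-sim-3p"))
})
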