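#!/usr/bin/env Rscript
# Simulates the default multi-population cohort (five populations,
# 92/95/96/93/89 samples, risk-allele frequencies 0.86 / 0.40, inverse
# genotype effects on host mRNA and miRNA, 40.3% miRNA dropout) and runs
# the full association panel for the miRNA, the host transcript, and the
# miRNA/host ratio.

suppressMessages(library(mireqtl))
dir.create("results", showWarnings = FALSE)
seed <- 1L

co <- simulate_cohort(cohort_design(), seed = seed)
g <- co$genotypes$geno[, 1]
cat("Cohort:", nrow(co$metadata), "samples;",
    sprintf("%.1f%% with nonzero miRNA counts\n\n", 100 * mean(co$mir > 0)))

mir_rec <- run_eqtl(co$mir[, 1], g, co$metadata, lmm = TRUE,
                    feature_id = "miR-sim", variant_id = "rs_sim")
host_rec <- run_eqtl(co$host[, 1], g, co$metadata, lmm = TRUE,
                     feature_id = "HOST", variant_id = "rs_sim")
cat("-- mature miRNA --\n"); print(mir_rec)
cat("\n-- host transcript --\n"); print(host_rec)

# ratio analysis needs a strictly positive denominator; the simulated host
# RPKMs are positive throughout
ratio_rec <- ratio_eqtl(co$mir[, 1], co$host[, 1], g, co$metadata,
                        variant_id = "rs_sim")
cat("\n-- miRNA/host ratio --\n"); print(ratio_rec)

panel <- data.frame(
  feature = c("miRNA", "host", "ratio"),
  slr_p = c(mir_rec$slr$p_value, host_rec$slr$p_value, ratio_rec$slr$p_value),
  anova_pop_p = c(mir_rec$anova_population$p_value,
                  host_rec$anova_population$p_value,
                  ratio_rec$anova_population$p_value),
  ancova_genotype_p = c(mir_rec$ancova$genotype$p_value,
                        host_rec$ancova$genotype$p_value,
                        ratio_rec$ancova$genotype$p_value),
  ancova_slope = c(mir_rec$ancova$genotype$estimate,
                   host_rec$ancova$genotype$estimate,
                   ratio_rec$ancova$genotype$estimate),
  lmm_p = c(mir_rec$lmm$genotype_wald$p_value,
            host_rec$lmm$genotype_wald$p_value, NA),
  r_partial = c(mir_rec$cor_partial$estimate, host_rec$cor_partial$estimate,
                ratio_rec$cor_partial$estimate))
write.table(panel, "results/cohort_eqtl_panel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nOpposite ANCOVA slopes with positive miR-host coupling: the",
    "\ninverse-regulation signature. Panel written to results/cohort_eqtl_panel.tsv\n")
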