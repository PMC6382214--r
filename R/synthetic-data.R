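#' @title Synthetic paradox and cohort data
#' @description Constructors for the two illustrative paradox datasets
#'   (Simpson-like masking across two populations; non-transitive
#'   correlation between a SNP and two coupled RNAs) and a multi-population
#'   cohort simulator with Hardy-Weinberg genotypes and zero-inflated
#'   miRNA counts. Exact mode pins the empirical cell means / sample
#'   correlations to their nominal targets so the headline quantities are
#'   deterministic regardless of seed.
#' @name synthetic-data
NULL

#' Simpson-paradox design
#'
#' Two populations share a biallelic SNP whose major allele in one
#' population is the minor allele in the other. Expression depends on
#' genotype with the same per-allele trend in both populations but a large
#' population baseline shift; cell counts are solved so that the pooled
#' per-genotype means are all equal, masking the eQTL in pooled analysis.
#'
#' @param n_per_genotype individuals per pooled genotype group (default 60).
#' @param pop_means list of two length-3 numeric vectors: per-genotype
#'   expression means for populations 1 and 2 (defaults `c(15,10,5)` and
#'   `c(30,25,20)`).
#' @param pooled_mean target pooled mean per genotype group (default 18).
#' @param residual_sd within-cell noise standard deviation (default 2).
#' @param exact if `TRUE` (default) empirical cell means and SDs are pinned
#'   to their nominal values.
#' @return A list of class `simpson_design`.
#' @export
simpson_design <- function(n_per_genotype = 60,
                           pop_means = list(c(15, 10, 5), c(30, 25, 20)),
                           pooled_mean = 18, residual_sd = 2, exact = TRUE) {
  stopifnot(n_per_genotype >= 2, length(pop_means) == 2,
            lengths(pop_means) == c(3, 3), residual_sd >= 0)
  structure(list(n_per_genotype = n_per_genotype, pop_means = pop_means,
                 pooled_mean = pooled_mean, residual_sd = residual_sd,
                 exact = exact), class = "simpson_design")
}

#' Solve the Simpson-design cell counts
#'
#' For each genotype g, finds counts (c1, c2) with c1 + c2 = n per genotype
#' and (c1 m1g + c2 m2g) / n = pooled mean, i.e. the mixing weight
#' w = (m2g - pooled) / (m2g - m1g) for population 1.
#'
#' @param design a [simpson_design()].
#' @return A list with `counts` (2 x 3 matrix, populations x genotypes)
#'   and `pop_totals` (length-2 vector of implied population sizes).
#' @export
solve_simpson_design <- function(design) {
  stopifnot(inherits(design, "simpson_design"))
  m1 <- design$pop_means[[1]]; m2 <- design$pop_means[[2]]
  n <- design$n_per_genotype
  counts <- matrix(NA_real_, 2, 3,
                   dimnames = list(c("pop1", "pop2"), c("g0", "g1", "g2")))
  for (g in 1:3) {
    if (m1[g] == m2[g]) {
      if (design$pooled_mean != m1[g])
        stop("design infeasible: pooled mean ", design$pooled_mean,
             " unattainable for genotype ", g - 1,
             " (both population means are ", m1[g], ")")
      w <- 1
    } else {
      w <- (m2[g] - design$pooled_mean) / (m2[g] - m1[g])
    }
    if (w < 0 || w > 1)
      stop("design infeasible: pooled mean ", design$pooled_mean,
           " lies outside [", min(m1[g], m2[g]), ", ", max(m1[g], m2[g]),
           "] for genotype ", g - 1)
    c1 <- w * n
    if (abs(c1 - round(c1)) > 1e-9)
      stop("non-integer cell count for genotype ", g - 1,
           ": weight ", w, " times n = ", n, " gives ", c1)
    counts[1, g] <- round(c1)
    counts[2, g] <- n - round(c1)
  }
  list(counts = counts, pop_totals = rowSums(counts))
}

#' Generate the Simpson-paradox dataset
#'
#' In exact mode, residuals within every population x genotype cell are
#' centered and rescaled so the empirical cell mean equals its nominal
#' mean (to ~1e-10) and the empirical cell SD equals `residual_sd`; the
#' pooled per-genotype means then equal the pooled target exactly and the
#' pooled regression of expression on genotype has slope 0.
#'
#' @param design a [simpson_design()].
#' @param seed integer RNG seed.
#' @return A data.frame with columns `individual`, `population` (factor),
#'   `genotype` (0/1/2) and `expression`.
#' @export
make_simpson_dataset <- function(design = simpson_design(), seed = 1L) {
  sol <- solve_simpson_design(design)
  set.seed(seed)
  rows <- list()
  for (p in 1:2) for (g in 1:3) {
    n_cell <- sol$counts[p, g]
    if (n_cell == 0) next
    if (n_cell == 1 && design$exact)
      stop("cell of size 1 cannot be rescaled to the target SD; ",
           "use a larger n_per_genotype or exact = FALSE")
    e <- stats::rnorm(n_cell, 0, design$residual_sd)
    if (design$exact && n_cell > 1) {
      e <- e - mean(e)
      s <- stats::sd(e)
      if (s > 0) e <- e / s * design$residual_sd
    }
    rows[[length(rows) + 1]] <- data.frame(
      population = paste0("pop", p), genotype = g - 1L,
      expression = design$pop_means[[p]][g] + e)
  }
  out <- do.call(rbind, rows)
  out <- data.frame(individual = sprintf("ind%03d", seq_len(nrow(out))),
                    population = factor(out$population),
                    genotype = out$genotype, expression = out$expression)
  rownames(out) <- NULL
  out
}

#' Non-transitivity design
#'
#' Target correlation structure among (genotype, RNA1, RNA2): the SNP is
#' positively correlated with RNA1, the two RNAs are positively correlated,
#' yet the SNP is negatively correlated with RNA2.
#'
#' @param n_per_genotype individuals per genotype (default 20; genotype
#'   counts are fixed and balanced).
#' @param target_corr 3x3 symmetric correlation matrix over
#'   (genotype, rna1, rna2) with unit diagonal; default targets
#'   r(g, rna1) = 0.472, r(rna1, rna2) = 0.508, r(g, rna2) = -0.471.
#' @param exact if `TRUE` (default) empirical sample correlations equal
#'   the targets (to ~1e-8).
#' @return A list of class `nontransitivity_design`.
#' @export
nontransitivity_design <- function(n_per_genotype = 20,
                                   target_corr = matrix(c(1, 0.472, -0.471,
                                                          0.472, 1, 0.508,
                                                          -0.471, 0.508, 1),
                                                        3, 3),
                                   exact = TRUE) {
  stopifnot(n_per_genotype >= 2, is.matrix(target_corr),
            dim(target_corr) == c(3, 3))
  if (max(abs(target_corr - t(target_corr))) > 1e-12 ||
      max(abs(diag(target_corr) - 1)) > 1e-12)
    stop("target_corr must be symmetric with unit diagonal")
  dimnames(target_corr) <- list(c("genotype", "rna1", "rna2"),
                                c("genotype", "rna1", "rna2"))
  structure(list(n_per_genotype = n_per_genotype, target_corr = target_corr,
                 exact = exact), class = "nontransitivity_design")
}

# unit-norm vector orthogonal to the columns of basis (and centered, since
# the all-ones vector is always included in basis)
ortho_unit <- function(x, basis) {
  r <- x - basis %*% (crossprod(basis, x))  # basis has orthonormal columns
  nr <- sqrt(sum(r^2))
  if (nr < 1e-12) stop("degenerate random draw; try another seed")
  r / nr
}

#' Generate the non-transitivity dataset
#'
#' Construction (exact mode): standardize the fixed balanced genotype
#' vector to a centered unit vector ghat; draw u1, u2 unit vectors
#' orthogonal to the intercept, ghat (and each other); set
#' rna1* = r_g1 ghat + sqrt(1 - r_g1^2) u1 and
#' rna2* = a ghat + b u1 + c u2 with a = r_g2,
#' b = (r_12 - r_g1 r_g2)/sqrt(1 - r_g1^2), c = sqrt(1 - a^2 - b^2).
#' Sample Pearson correlations then equal the targets exactly. The
#' standardized columns are shifted/scaled onto an expression-like scale
#' (affine, so correlations are untouched).
#'
#' @param design a [nontransitivity_design()].
#' @param seed integer RNG seed.
#' @return A data.frame with columns `individual`, `genotype`, `rna1`,
#'   `rna2`, with attribute `coefficients` = c(alpha, beta, gamma).
#' @export
make_nontransitivity_dataset <- function(design = nontransitivity_design(),
                                         seed = 1L) {
  stopifnot(inherits(design, "nontransitivity_design"))
  tc <- design$target_corr
  r_g1 <- tc["genotype", "rna1"]
  r_g2 <- tc["genotype", "rna2"]
  r_12 <- tc["rna1", "rna2"]
  if (abs(r_g1) >= 1) stop("infeasible correlation: |r(g, rna1)| must be < 1")
  alpha <- r_g2
  beta <- (r_12 - r_g1 * r_g2) / sqrt(1 - r_g1^2)
  gamma2 <- 1 - alpha^2 - beta^2
  if (gamma2 < -1e-12)
    stop("infeasible correlation targets: not positive definite ",
         "(gamma^2 = ", signif(gamma2, 4), " < 0)")
  gamma <- sqrt(max(gamma2, 0))
  n <- 3L * design$n_per_genotype
  g <- rep(0:2, each = design$n_per_genotype)
  set.seed(seed)
  one <- rep(1 / sqrt(n), n)
  ghat <- g - mean(g)
  ghat <- ghat / sqrt(sum(ghat^2))
  basis <- cbind(one, ghat)
  u1 <- ortho_unit(stats::rnorm(n), basis)
  u2 <- ortho_unit(stats::rnorm(n), cbind(basis, u1))
  rna1s <- r_g1 * ghat + sqrt(1 - r_g1^2) * u1
  rna2s <- alpha * ghat + beta * u1 + gamma * u2
  if (!design$exact) {
    # noisy mode: iid Gaussian draws with the target correlation in
    # expectation, via the same loadings applied to fresh noise
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    gs <- (g - mean(g)) / stats::sd(g)
    rna1s <- r_g1 * gs + sqrt(1 - r_g1^2) * z1
    rna2s <- alpha * gs + beta * z1 + gamma * z2
    rna1s <- rna1s / sqrt(sum(rna1s^2) / (n - 1))
    rna2s <- rna2s / sqrt(sum(rna2s^2) / (n - 1))
  }
  # put on an expression-like scale: mean 10, sd 2 (affine)
  scale_up <- function(v) {
    v <- v / stats::sd(v)
    10 + 2 * (v - mean(v))
  }
  out <- data.frame(individual = sprintf("ind%03d", seq_len(n)),
                    genotype = g, rna1 = scale_up(rna1s),
                    rna2 = scale_up(rna2s))
  attr(out, "coefficients") <- c(alpha = alpha, beta = beta, gamma = gamma)
  out
}

#' Multi-population cohort design
#'
#' Defaults emulate a Geuvadis-like collection: five lymphoblastoid
#' cell-line populations (92/95/96/93/89 samples), risk-allele frequency
#' 0.86 in the four European populations and 0.40 in YRI, an additive
#' genotype effect of opposite sign on the host mRNA (RPKM-like scale) and
#' the mature miRNA (normalized-count scale), population baseline shifts
#' that are large for the host gene and small for the miRNA, a shared
#' per-sample primary-transcript component that couples the two RNAs
#' positively, and an independent miRNA dropout mask (detection failure)
#' zeroing a fixed fraction of samples.
#'
#' @param populations data.frame with columns `name`, `size`, `freq`
#'   (risk-allele frequency in \[0,1\]).
#' @param slope_host per-allele additive effect on the host transcript.
#' @param slope_mir per-allele additive effect on the miRNA.
#' @param host_baseline,mir_baseline per-population baseline vectors
#'   (recycled if length 1).
#' @param host_sd,mir_sd independent noise SDs.
#' @param shared_sd SD of the shared primary-transcript activity term.
#' @param mir_shared_load loading of the shared term on the miRNA (the
#'   host loading is fixed at 1).
#' @param dropout probability that a sample's miRNA measurement is zeroed
#'   (default 0.403, leaving ~59.7% of samples with nonzero counts).
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(populations = data.frame(
                            name = c("CEU", "FIN", "GBR", "TSI", "YRI"),
                            size = c(92L, 95L, 96L, 93L, 89L),
                            freq = c(0.86, 0.86, 0.86, 0.86, 0.40)),
                          slope_host = -3, slope_mir = 2.5,
                          host_baseline = c(62, 66, 58, 60, 48),
                          mir_baseline = 4,
                          host_sd = 6, mir_sd = 1.5,
                          shared_sd = 5, mir_shared_load = 0.3,
                          dropout = 0.403) {
  stopifnot(is.data.frame(populations),
            all(c("name", "size", "freq") %in% names(populations)),
            all(populations$size > 0),
            all(populations$freq >= 0 & populations$freq <= 1),
            dropout >= 0, dropout <= 1,
            host_sd >= 0, mir_sd >= 0, shared_sd >= 0)
  k <- nrow(populations)
  structure(list(populations = populations,
                 slope_host = slope_host, slope_mir = slope_mir,
                 host_baseline = rep_len(host_baseline, k),
                 mir_baseline = rep_len(mir_baseline, k),
                 host_sd = host_sd, mir_sd = mir_sd,
                 shared_sd = shared_sd, mir_shared_load = mir_shared_load,
                 dropout = dropout), class = "cohort_design")
}

#' Simulate a multi-population cohort
#'
#' Genotypes are drawn per population as Binomial(2, freq)
#' (Hardy-Weinberg). Host expression is
#' baseline + slope_host * g + shared + noise; miRNA counts are
#' max(0, baseline + slope_mir * g + load * shared + noise) with an
#' independent dropout mask setting a design-specified fraction to zero.
#'
#' @param design a [cohort_design()].
#' @param seed integer RNG seed.
#' @param variant_id,host_id,mir_id feature/variant identifiers used in
#'   the returned objects.
#' @return A list with `genotypes` (a [genotype_matrix()]), `host`
#'   (linear-scale mRNA [expression_table()]), `mir` (linear-scale miRNA
#'   [expression_table()]) and `metadata` (data.frame sample, population).
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1L,
                            variant_id = "rs_sim", host_id = "HOST",
                            mir_id = "miR-sim") {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  pops <- design$populations
  n <- sum(pops$size)
  population <- factor(rep(pops$name, pops$size), levels = pops$name)
  g <- unlist(lapply(seq_len(nrow(pops)), function(i)
    stats::rbinom(pops$size[i], 2, pops$freq[i])))
  shared <- stats::rnorm(n, 0, design$shared_sd)
  host <- rep(design$host_baseline, pops$size) + design$slope_host * g +
    shared + stats::rnorm(n, 0, design$host_sd)
  mir <- rep(design$mir_baseline, pops$size) + design$slope_mir * g +
    design$mir_shared_load * shared + stats::rnorm(n, 0, design$mir_sd)
  mir <- pmax(0, mir)
  drop_mask <- stats::runif(n) < design$dropout
  mir[drop_mask] <- 0
  ids <- sprintf("S%04d", seq_len(n))
  gm <- genotype_matrix(matrix(g, ncol = 1, dimnames = list(ids, variant_id)),
                        data.frame(id = variant_id, chrom = "1", pos = 1000L,
                                   ref = "A", alt = "G"))
  list(genotypes = gm,
       host = expression_table(matrix(host, ncol = 1,
                                      dimnames = list(ids, host_id)),
                               scale = "linear", kind = "mRNA"),
       mir = expression_table(matrix(mir, ncol = 1,
                                     dimnames = list(ids, mir_id)),
                              scale = "linear", kind = "miRNA"),
       metadata = data.frame(sample = ids, population = population))
}

#' Write a simulated dataset with a JSON design sidecar
#'
#' Writes a data.frame as TSV plus `<path>.json` recording the design
#' fields and seed, so simulated inputs are self-describing.
#'
#' @param data data.frame to write.
#' @param path output TSV path.
#' @param design the design object used to generate `data`.
#' @param seed the seed used.
#' @return `path`, invisibly.
#' @export
write_simulated <- function(data, path, design, seed) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(unclass(design), list(seed = seed, class = class(design)[1]))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
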