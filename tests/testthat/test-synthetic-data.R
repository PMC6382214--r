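test_that("Simpson design solver reproduces the balanced-pooling cell counts", {
  sol <- solve_simpson_design(simpson_design())
  expect_equal(unname(sol$counts["pop1", ]), c(48, 28, 8))
  expect_equal(unname(sol$counts["pop2", ]), c(12, 32, 52))
  expect_equal(unname(sol$pop_totals), c(84, 96))

  # boundary weight: identical pooled and population-1 means puts everyone
  # in population 1
  d <- simpson_design(pop_means = list(c(15, 15, 15), c(30, 30, 30)),
                      pooled_mean = 15)
  sol2 <- solve_simpson_design(d)
  expect_equal(unname(sol2$counts["pop1", ]), c(60, 60, 60))
  expect_equal(unname(sol2$pop_totals), c(180, 0))

  # pooled mean outside the convex hull of the population means
  expect_error(solve_simpson_design(simpson_design(pooled_mean = 40)),
               "infeasible")
  # non-integer cell counts are reported with the offending genotype
  expect_error(solve_simpson_design(simpson_design(n_per_genotype = 7)),
               "genotype")
})

test_that("solver is invariant to swapping the two populations", {
  d1 <- simpson_design()
  d2 <- simpson_design(pop_means = rev(d1$pop_means))
  s1 <- solve_simpson_design(d1)
  s2 <- solve_simpson_design(d2)
  expect_equal(unname(s1$counts["pop1", ]), unname(s2$counts["pop2", ]))
  expect_equal(unname(s1$pop_totals), unname(rev(s2$pop_totals)))
})

test_that("exact-mode Simpson data pin cell means and mask the pooled eQTL", {
  for (seed in c(1, 42, 2024)) {
    d <- make_simpson_dataset(simpson_design(), seed = seed)
    expect_equal(nrow(d), 180)
    cell_means <- tapply(d$expression,
                         list(d$population, d$genotype), mean)
    expect_equal(unname(cell_means["pop1", ]), c(15, 10, 5), tolerance = 1e-10)
    expect_equal(unname(cell_means["pop2", ]), c(30, 25, 20), tolerance = 1e-10)
    pooled <- tapply(d$expression, d$genotype, mean)
    expect_equal(as.numeric(pooled), c(18, 18, 18), tolerance = 1e-10)
    expect_equal(unname(coef(lm(expression ~ genotype, d))[2]), 0,
                 tolerance = 1e-10)
    # changing the noise scale never moves a mean
    d2 <- make_simpson_dataset(simpson_design(residual_sd = 7), seed = seed)
    expect_equal(as.numeric(tapply(d2$expression, d2$genotype, mean)), as.numeric(pooled),
                 tolerance = 1e-10)
  }
})

test_that("singleton cells cannot be rescaled in exact mode", {
  d <- simpson_design(n_per_genotype = 5,
                      pop_means = list(c(15, 10, 5), c(30, 25, 20)),
                      pooled_mean = 18)
  # weights 0.8, 7/15, 2/15 times 5 are non-integer -> solver error first
  expect_error(make_simpson_dataset(d, seed = 1))
  d2 <- simpson_design(n_per_genotype = 4,
                       pop_means = list(c(16, 12, 8), c(20, 32, 44)),
                       pooled_mean = 17)
  # weight 3/4 for every genotype -> cell sizes 3 and 1
  expect_error(make_simpson_dataset(d2, seed = 1), "size 1")
})

test_that("exact-mode non-transitivity data reproduce any PD target exactly", {
  targets <- list(
    c(0.472, 0.508, -0.471),   # the published triple
    c(0.3, 0.2, 0.1),
    c(-0.5, 0.4, 0.3))
  for (tg in targets) for (seed in c(1, 99)) {
    tc <- diag(3)
    tc[1, 2] <- tc[2, 1] <- tg[1]
    tc[2, 3] <- tc[3, 2] <- tg[2]
    tc[1, 3] <- tc[3, 1] <- tg[3]
    d <- make_nontransitivity_dataset(nontransitivity_design(target_corr = tc),
                                      seed = seed)
    emp <- cor(d[, c("genotype", "rna1", "rna2")])
    expect_equal(unname(emp), unname(tc), tolerance = 1e-8)
    expect_equal(nrow(d), 60)
  }
})

test_that("non-transitivity construction coefficients match the Gram-Schmidt algebra", {
  d <- make_nontransitivity_dataset(seed = 5)
  co <- attr(d, "coefficients")
  r_g1 <- 0.472; r_12 <- 0.508; r_g2 <- -0.471
  beta <- (r_12 - r_g1 * r_g2) / sqrt(1 - r_g1^2)
  expect_equal(unname(co["alpha"]), r_g2)
  expect_equal(unname(co["beta"]), beta, tolerance = 1e-12)
  expect_equal(unname(co["gamma"]), sqrt(1 - r_g2^2 - beta^2),
               tolerance = 1e-12)
})

test_that("identity target gives uncorrelated columns; infeasible targets error", {
  d <- make_nontransitivity_dataset(nontransitivity_design(target_corr = diag(3)),
                                    seed = 2)
  emp <- cor(d[, c("genotype", "rna1", "rna2")])
  expect_equal(unname(emp), diag(3), tolerance = 1e-8)

  tc <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(make_nontransitivity_dataset(nontransitivity_design(target_corr = tc)),
               "infeasible")
})

test_that("cohort simulator matches the designed sizes and detection rate", {
  co <- simulate_cohort(seed = 11)
  expect_equal(nrow(co$metadata), 465)
  expect_equal(as.integer(table(co$metadata$population)),
               c(92, 95, 96, 93, 89))
  expect_true(all(co$genotypes$geno %in% 0:2))
  expect_true(all(co$mir >= 0))
  # detection fraction over seeds: dropout 0.403 -> ~59.7% nonzero
  fr <- vapply(1:20, function(s) mean(simulate_cohort(seed = s)$mir > 0), 0)
  expect_lt(abs(mean(fr) - 0.597), 0.05)
  # reproducible under a fixed seed
  co2 <- simulate_cohort(seed = 11)
  expect_identical(co$genotypes$geno, co2$genotypes$geno)
  expect_identical(unclass(co$mir), unclass(co2$mir))
})

test_that("ANCOVA recovers the planted host slope within its 95% CI", {
  hits <- vapply(1:100, function(s) {
    co <- simulate_cohort(seed = s)
    fit <- lm(co$host[, 1] ~ g + population,
              data.frame(g = co$genotypes$geno[, 1],
                         population = co$metadata$population))
    est <- coef(summary(fit))["g", ]
    abs(est["Estimate"] - (-3)) <= 1.96 * est["Std. Error"]
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("simulated datasets round-trip through the TSV + JSON sidecar", {
  d <- make_simpson_dataset(seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_simulated(d, path, simpson_design(), seed = 1)
  back <- read.delim(path)
  expect_equal(back$expression, d$expression, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 1)
  expect_equal(side$pooled_mean, 18)
})
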