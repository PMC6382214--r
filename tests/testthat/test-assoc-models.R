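test_that("SLR F-test matches its closed form and handles degenerate fits", {
  set.seed(1)
  g <- rep(0:2, each = 10)
  y <- 1.5 * g + rnorm(30)
  res <- slr_ftest(y, g)
  fit <- lm(y ~ g)
  expect_equal(res$statistic, summary(fit)$fstatistic[["value"]])
  expect_equal(res$estimate, unname(coef(fit)[2]))
  expect_equal(res$df, c(1, 28))

  # perfect fit: p collapses to zero
  g9 <- rep(0:2, each = 3)
  perfect <- slr_ftest(2 * g9, g9)
  expect_equal(perfect$p_value, 0)
  expect_equal(perfect$estimate, 2)

  expect_error(slr_ftest(rnorm(10), rep(1, 10)), "constant")
  expect_error(slr_ftest(1:2, 0:1), "3")
})

test_that("SLR p-values are uniform under the null", {
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    slr_ftest(rnorm(40), rbinom(40, 2, 0.5))$p_value
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("one-way ANOVA has the standard df and calibrated size", {
  set.seed(2)
  y <- c(rnorm(10, 0), rnorm(12, 5))
  grp <- rep(c("a", "b"), c(10, 12))
  res <- anova_oneway(y, grp)
  expect_equal(res$df, c(1, 20))
  expect_lt(res$p_value, 1e-8)
  expect_error(anova_oneway(rnorm(5), rep("a", 5)), "2 groups")

  rej <- vapply(1:1000, function(s) {
    set.seed(s)
    anova_oneway(rnorm(30), rep(c("a", "b", "c"), 10))$p_value < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("type II ANCOVA equals the explicit model-comparison oracle", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(12:30, 1)
    pop <- factor(sample(c("p1", "p2", "p3"), n, replace = TRUE))
    g <- rbinom(n, 2, 0.5)
    if (length(unique(g)) < 2 || nlevels(droplevels(pop)) < 2) next
    y <- 0.5 * g + as.numeric(pop) + rnorm(n)
    res <- tryCatch(ancova_type2(y, g, pop), error = function(e) NULL)
    if (is.null(res)) next
    full <- lm(y ~ g + pop)
    no_g <- lm(y ~ pop)
    no_p <- lm(y ~ g)
    rss <- function(m) sum(resid(m)^2)
    df_res <- df.residual(full)
    f_g <- (rss(no_g) - rss(full)) / (rss(full) / df_res)
    df_p <- no_p$rank - 1 + length(levels(droplevels(pop))) - 1
    f_pop <- ((rss(no_p) - rss(full)) / (nlevels(droplevels(pop)) - 1)) /
      (rss(full) / df_res)
    expect_equal(res$genotype$statistic, f_g, tolerance = 1e-8)
    expect_equal(res$genotype$p_value,
                 pf(f_g, 1, df_res, lower.tail = FALSE), tolerance = 1e-8)
    expect_equal(res$population$statistic, f_pop, tolerance = 1e-8)
    expect_equal(res$residual_df, df_res)
  }
})

test_that("type II ANCOVA with interaction uses the interaction-model residual", {
  set.seed(7)
  n <- 60
  pop <- factor(rep(c("p1", "p2"), each = 30))
  g <- rbinom(n, 2, 0.5)
  y <- g + 2 * (pop == "p2") + 0.5 * g * (pop == "p2") + rnorm(n)
  res <- ancova_type2(y, g, pop, with_interaction = TRUE)
  rss <- function(f) sum(resid(lm(f))^2)
  full_int <- lm(y ~ g * pop)
  df_res <- df.residual(full_int)
  f_g <- (rss(y ~ pop) - rss(y ~ g + pop)) / (sum(resid(full_int)^2) / df_res)
  f_int <- (rss(y ~ g + pop) - sum(resid(full_int)^2)) /
    (sum(resid(full_int)^2) / df_res)
  expect_equal(res$genotype$statistic, f_g, tolerance = 1e-8)
  expect_equal(res$interaction$statistic, f_int, tolerance = 1e-8)
  expect_equal(res$residual_df, df_res)
})

test_that("type II equals type I sums of squares in a balanced orthogonal design", {
  g <- rep(rep(0:2, each = 4), 2)
  pop <- factor(rep(c("p1", "p2"), each = 12))
  set.seed(3)
  y <- g - 3 * (pop == "p2") + rnorm(24)
  res <- ancova_type2(y, g, pop)
  type1 <- anova(lm(y ~ g + pop))
  expect_equal(res$genotype$statistic, type1["g", "F value"],
               tolerance = 1e-10)
  expect_equal(res$population$statistic, type1["pop", "F value"],
               tolerance = 1e-10)
})

test_that("ANCOVA genotype slope equals the within-population-centered SLR slope", {
  set.seed(4)
  pop <- factor(rep(c("p1", "p2"), c(40, 50)))
  g <- rbinom(90, 2, ifelse(pop == "p1", 0.8, 0.3))
  y <- -2 * g + 10 * (pop == "p2") + rnorm(90)
  res <- ancova_type2(y, g, pop)
  yc <- unlist(tapply(y, pop, scale, scale = FALSE))
  gc <- unlist(tapply(g, pop, scale, scale = FALSE))
  expect_equal(res$genotype$estimate, unname(coef(lm(yc ~ gc))[2]),
               tolerance = 1e-10)
})

test_that("ANCOVA rejects singular designs", {
  pop <- factor(rep(c("p1", "p2"), each = 10))
  g <- as.numeric(pop == "p2") * 2  # constant within each level
  expect_error(ancova_type2(rnorm(20), g, pop), "singular")
  expect_error(ancova_type2(rnorm(20), rep(1, 20), pop), "singular")
})

test_that("Welch test reduces to the pooled t-test with equal variances and n", {
  set.seed(5)
  a <- rnorm(12)
  b <- a + 3  # identical sample variance, shifted mean
  w <- welch_t(a, b)
  pooled <- t.test(a, b, var.equal = TRUE)
  expect_equal(w$statistic, unname(pooled$statistic), tolerance = 1e-10)
  expect_equal(w$p_value, pooled$p.value, tolerance = 1e-10)
  expect_equal(w$df, 2 * length(a) - 2, tolerance = 1e-10)
  expect_equal(w$estimate, -3)

  same <- welch_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(welch_t(1, rnorm(3)), ">= 2")
  expect_error(welch_t(rep(1, 3), rep(2, 3)), "zero variance")
})

test_that("random-intercept LMM recovers slopes and flags degenerate variance", {
  # parameter recovery against the cohort simulator
  hits <- vapply(1:200, function(s) {
    co <- simulate_cohort(seed = s)
    fit <- lmm_random_intercept(co$host[, 1], co$genotypes$geno[, 1],
                                co$metadata$population)
    se <- abs(fit$fixed_slope / sqrt(fit$genotype_wald$statistic))
    abs(fit$fixed_slope - (-3)) <= 1.96 * se
  }, TRUE)
  expect_gte(mean(hits), 0.90)

  # no population effect: the random-intercept variance sits at the boundary
  set.seed(8)
  g <- rbinom(200, 2, 0.5)
  pop <- factor(rep(letters[1:4], each = 50))
  y <- g + rnorm(200)
  fit0 <- lmm_random_intercept(y, g, pop)
  expect_lt(fit0$random_intercept_sd, 0.2)
  expect_equal(fit0$genotype_wald$df, 1)

  # agreement with the car-style Wald chi-square on the same fit
  co <- simulate_cohort(seed = 123)
  y2 <- co$host[, 1]; g2 <- co$genotypes$geno[, 1]
  pop2 <- co$metadata$population
  mine <- lmm_random_intercept(y2, g2, pop2)
  ref <- car::Anova(lme4::lmer(y2 ~ g2 + (1 | pop2), REML = TRUE),
                    type = 2, test.statistic = "Chisq")
  expect_equal(mine$genotype_wald$statistic, ref[["Chisq"]][1],
               tolerance = 1e-6)
  expect_equal(mine$genotype_wald$p_value, ref[["Pr(>Chisq)"]][1],
               tolerance = 1e-6)
})

test_that("Pearson correlation matches cor.test and rejects constants", {
  set.seed(6)
  x <- rnorm(25); y <- x + rnorm(25)
  res <- pearson(x, y)
  ref <- cor.test(x, y)
  expect_equal(res$estimate, unname(ref$estimate))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(pearson(x, x)$estimate, 1)
  expect_error(pearson(rep(1, 10), rnorm(10)), "constant")
})

test_that("population-adjusted correlation equals the projection-matrix oracle", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(20:40, 1)
    pop <- factor(sample(c("p1", "p2", "p3"), n, replace = TRUE))
    if (nlevels(droplevels(pop)) < 2) next
    x <- rnorm(n) + 2 * as.numeric(pop)
    y <- rnorm(n) - as.numeric(pop)
    res <- partial_pearson(x, y, pop)
    X <- model.matrix(~pop)
    P <- diag(n) - X %*% solve(crossprod(X)) %*% t(X)
    r_oracle <- as.numeric((t(x) %*% P %*% y) /
                             sqrt((t(x) %*% P %*% x) * (t(y) %*% P %*% y)))
    expect_equal(res$estimate, r_oracle, tolerance = 1e-10)
    k <- nlevels(droplevels(pop))
    expect_equal(res$df, n - 2 - (k - 1))
  }
})

test_that("population adjustment removes a pure between-population confound", {
  set.seed(9)
  pop <- factor(rep(c("p1", "p2"), each = 30))
  x <- rnorm(60) + 100 * (pop == "p2")
  y <- rnorm(60)
  plain <- pearson(x, y)
  adj <- partial_pearson(x, y, pop)
  expect_lt(abs(adj$estimate), 0.3)
  # single population reduces to the plain correlation
  one <- partial_pearson(x[1:30], y[1:30], pop[1:30, drop = TRUE])
  ref <- pearson(x[1:30], y[1:30])
  expect_equal(one$estimate, ref$estimate, tolerance = 1e-12)
  expect_equal(one$df, ref$df)
})

test_that("statistics are invariant to permuting sample order", {
  co <- simulate_cohort(seed = 21)
  y <- co$host[, 1]; g <- co$genotypes$geno[, 1]
  pop <- co$metadata$population
  set.seed(1); perm <- sample(length(y))
  a1 <- ancova_type2(y, g, pop)
  a2 <- ancova_type2(y[perm], g[perm], pop[perm])
  expect_equal(a1$genotype$statistic, a2$genotype$statistic,
               tolerance = 1e-10)
  expect_equal(partial_pearson(y, g, pop)$estimate,
               partial_pearson(y[perm], g[perm], pop[perm])$estimate,
               tolerance = 1e-10)
  expect_equal(slr_ftest(y, g)$p_value, slr_ftest(y[perm], g[perm])$p_value,
               tolerance = 1e-10)
})
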