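#' @title Association-model toolkit
#' @description Statistical primitives used throughout the eQTL analyses:
#'   SLR F-test, one-way ANOVA, type II ANCOVA, Welch t-test,
#'   random-intercept mixed model, plain and population-adjusted Pearson
#'   correlation. Genotype is always modeled additively (0/1/2). All
#'   functions use pairwise-complete deletion and record the n actually
#'   analyzed.
#' @name assoc-models
NULL

# drop cases with any NA across the supplied parallel vectors
complete_cases_of <- function(...) {
  args <- list(...)
  keep <- Reduce(`&`, lapply(args, function(v) !is.na(v)))
  lapply(args, function(v) v[keep])
}

#' Simple linear regression F-test of expression on genotype
#'
#' Fits `y ~ g` with genotype coded additively and returns the F-test of the
#' genotype slope (F on 1 and n-2 df), equivalent to testing Pearson's
#' correlation between y and g.
#'
#' @param y numeric expression vector.
#' @param g numeric genotype vector (0/1/2 allele counts).
#' @return A test result with `statistic` (F), `df` (1, n-2), `p_value`,
#'   and `estimate` (the slope).
#' @export
slr_ftest <- function(y, g) {
  v <- complete_cases_of(as.numeric(y), as.numeric(g))
  y <- v[[1]]; g <- v[[2]]
  n <- length(y)
  if (n < 3) stop("slr_ftest needs at least 3 complete samples")
  if (stats::var(g) == 0) stop("degenerate input: genotype is constant")
  if (stats::var(y) == 0) stop("degenerate input: response is constant")
  fit <- stats::lm(y ~ g)
  slope <- unname(stats::coef(fit)[2])
  rss <- sum(stats::resid(fit)^2)
  mss <- sum((stats::fitted(fit) - mean(y))^2)
  if (rss <= 0) {
    # perfect fit: F diverges
    p <- if (mss > 0) 0 else 1
    return(test_result(Inf, c(1, n - 2), p, slope, n, "SLR F-test"))
  }
  f <- (mss / 1) / (rss / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  test_result(f, c(1, n - 2), p, slope, n, "SLR F-test")
}

#' One-way ANOVA
#'
#' Standard between/within F-test of a numeric response across groups
#' (used with the population variable alone).
#'
#' @param y numeric vector.
#' @param group categorical vector (coerced to factor).
#' @return A test result with F on (k-1, n-k) df.
#' @export
anova_oneway <- function(y, group) {
  v <- complete_cases_of(as.numeric(y), as.character(group))
  y <- v[[1]]; group <- factor(v[[2]])
  k <- nlevels(group)
  if (k < 2) stop("anova_oneway needs at least 2 groups")
  n <- length(y)
  if (n - k < 1) stop("anova_oneway needs positive residual df")
  tab <- stats::anova(stats::lm(y ~ group))
  test_result(tab$`F value`[1], c(k - 1, n - k), tab$`Pr(>F)`[1],
              NA_real_, n, "one-way ANOVA")
}

#' ANCOVA with type II sums of squares
#'
#' Linear model of expression on additive genotype (numeric) and population
#' (categorical), optionally with their interaction. F-tests for all terms
#' use type II sums of squares, i.e. marginality-respecting model
#' comparisons: each main effect is tested against the main-effects model
#' without it (the interaction excluded from both comparison models), the
#' interaction against the main-effects model; the denominator is the
#' residual mean square of the largest fitted model.
#'
#' @param y numeric expression vector.
#' @param g numeric genotype vector (0/1/2).
#' @param pop categorical population vector.
#' @param with_interaction include a genotype x population interaction term.
#' @return A list of class `ancova_result` with elements `genotype`,
#'   `population`, (optionally) `interaction` — each a test result — plus
#'   `residual_df` and `n`. The genotype estimate is the main-effects slope.
#' @export
ancova_type2 <- function(y, g, pop, with_interaction = FALSE) {
  v <- complete_cases_of(as.numeric(y), as.numeric(g), as.character(pop))
  y <- v[[1]]; g <- v[[2]]; pop <- factor(v[[3]])
  n <- length(y)
  if (nlevels(pop) < 2) stop("ancova_type2 needs >= 2 population levels")
  if (stats::var(g) == 0) stop("singular design: genotype is constant")
  # genotype constant within every population level makes it collinear with
  # the population indicators
  full <- if (with_interaction) stats::lm(y ~ g * pop) else stats::lm(y ~ g + pop)
  if (any(is.na(stats::coef(full)))) stop("singular design: rank-deficient model matrix")
  p_model_cols <- length(stats::coef(full))
  if (n <= p_model_cols) stop("ancova_type2 needs n greater than the number of model columns")
  a2 <- car::Anova(full, type = 2)
  rows <- rownames(a2)
  res_df <- a2[rows == "Residuals", "Df"]
  pick <- function(term) {
    i <- match(term, rows)
    test_result(a2$`F value`[i], c(a2$Df[i], res_df), a2$`Pr(>F)`[i],
                NA_real_, n, sprintf("type II F (%s)", term))
  }
  slope <- unname(stats::coef(stats::lm(y ~ g + pop))["g"])
  out <- list(genotype = pick("g"), population = pick("pop"),
              residual_df = res_df, n = n)
  out$genotype$estimate <- slope
  if (with_interaction) out$interaction <- pick("g:pop")
  structure(out, class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("type II ANCOVA (n =", x$n, ")\n")
  cat(sprintf("  genotype:   F = %.4g, p = %.4g (slope %.4g)\n",
              x$genotype$statistic, x$genotype$p_value, x$genotype$estimate))
  cat(sprintf("  population: F = %.4g, p = %.4g\n",
              x$population$statistic, x$population$p_value))
  if (!is.null(x$interaction))
    cat(sprintf("  interaction: F = %.4g, p = %.4g\n",
                x$interaction$statistic, x$interaction$p_value))
  invisible(x)
}

#' Two-sample two-tailed Welch t-test
#'
#' @param a,b numeric vectors (each with >= 2 values and nonzero variance
#'   in at least one of them).
#' @return A test result; `estimate` is mean(a) - mean(b), `df` the
#'   Satterthwaite degrees of freedom.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("welch_t needs >= 2 samples per group")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("welch_t: both groups have zero variance")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              mean(a) - mean(b), length(a) + length(b), "Welch t-test")
}

#' Random-intercept linear mixed model for the genotype effect
#'
#' Fits `y ~ g + (1 | pop)` by REML (population as random intercept) and
#' assesses the genotype fixed effect by a type II Wald chi-square test on
#' 1 df, `(slope / SE)^2`, against the asymptotic chi-square distribution
#' (no small-sample df correction).
#'
#' @param y numeric expression vector.
#' @param g numeric genotype vector (0/1/2).
#' @param pop categorical population vector.
#' @return A list of class `lmm_result` with `genotype_wald` (test result,
#'   chi-square on 1 df), `fixed_slope`, `random_intercept_sd`,
#'   `residual_sd`, `converged`, `n`.
#' @export
lmm_random_intercept <- function(y, g, pop) {
  v <- complete_cases_of(as.numeric(y), as.numeric(g), as.character(pop))
  y <- v[[1]]; g <- v[[2]]; pop <- factor(v[[3]])
  n <- length(y)
  if (n < 4) stop("lmm_random_intercept needs n >= 4")
  if (nlevels(pop) < 2) stop("lmm_random_intercept needs >= 2 populations")
  fit <- tryCatch(
    suppressMessages(lme4::lmer(y ~ g + (1 | pop), REML = TRUE,
                                control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(genotype_wald = test_result(NA_real_, 1, NA_real_, NA_real_, n, "Wald chi-square"),
                          fixed_slope = NA_real_, random_intercept_sd = NA_real_,
                          residual_sd = NA_real_, converged = FALSE, n = n),
                     class = "lmm_result"))
  }
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  beta <- lme4::fixef(fit)["g"]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["g"]]
  wald <- unname((beta / se)^2)
  p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    genotype_wald = test_result(wald, 1, p, unname(beta), n, "Wald chi-square"),
    fixed_slope = unname(beta),
    random_intercept_sd = vc$sdcor[vc$grp == "pop"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    converged = conv, n = n), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("random-intercept LMM (REML, n = %d, converged = %s)\n",
              x$n, x$converged))
  cat(sprintf("  genotype slope %.4g, Wald chi2 = %.4g (1 df), p = %.4g\n",
              x$fixed_slope, x$genotype_wald$statistic, x$genotype_wald$p_value))
  cat(sprintf("  sd(population intercept) = %.4g, sd(residual) = %.4g\n",
              x$random_intercept_sd, x$residual_sd))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors (n >= 3, both nonconstant after
#'   pairwise-complete deletion).
#' @return A test result; `estimate` = r, `statistic` = t on n-2 df,
#'   two-tailed p.
#' @export
pearson <- function(x, y) {
  v <- complete_cases_of(as.numeric(x), as.numeric(y))
  x <- v[[1]]; y <- v[[2]]
  n <- length(x)
  if (n < 3) stop("pearson needs >= 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("pearson: constant input")
  ht <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              unname(ht$estimate), n, "Pearson correlation")
}

#' Population-adjusted (partial) Pearson correlation
#'
#' Residualizes `x` and `y` on population indicator columns (with
#' intercept) by least squares and returns the Pearson correlation of the
#' residuals. The t-test degrees of freedom are reduced by the number of
#' population levels minus one: df = n - 2 - (levels - 1).
#'
#' @param x,y numeric vectors.
#' @param pop categorical population vector.
#' @return A test result; `estimate` = partial r.
#' @export
partial_pearson <- function(x, y, pop) {
  v <- complete_cases_of(as.numeric(x), as.numeric(y), as.character(pop))
  x <- v[[1]]; y <- v[[2]]; pop <- factor(v[[3]])
  n <- length(x)
  k <- nlevels(pop)
  if (n < k + 2) stop("partial_pearson needs n >= number of populations + 2")
  if (any(tabulate(pop) == 1L))
    warning("population level(s) with a single sample contribute zero residuals")
  if (k == 1L) {
    # adjustment on the intercept only: plain centered correlation
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    rx <- stats::resid(stats::lm(x ~ pop))
    ry <- stats::resid(stats::lm(y ~ pop))
  }
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("partial_pearson: all-constant residuals after population adjustment")
  r <- stats::cor(rx, ry)
  df <- n - 2 - (k - 1)
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  test_result(tt, df, p, r, n, "population-adjusted Pearson correlation")
}
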