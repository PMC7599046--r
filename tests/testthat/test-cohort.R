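test_that("read-depth outliers are removed once, by z-score", {
  set.seed(200)
  cohort <- data.frame(total_reads = c(rnorm(100, 1e4, 500), 1e7))
  out <- remove_read_outliers(cohort)
  expect_equal(nrow(out), 100)
  expect_equal(attr(out, "removed"), 101L)
  flat <- data.frame(total_reads = rep(5000, 10))
  expect_warning(out2 <- remove_read_outliers(flat), "zero variance")
  expect_equal(nrow(out2), 10)
  # threshold monotonicity: z > 3 removals contain z > 4 removals
  r3 <- attr(remove_read_outliers(cohort, 3), "removed")
  r4 <- attr(remove_read_outliers(cohort, 4), "removed")
  expect_true(all(r4 %in% r3))
})

test_that("within-dataset standardization gives mean 0, sd 1 per dataset", {
  set.seed(201)
  v <- c(rnorm(50, 100, 10), rnorm(60, 5, 0.1))
  g <- rep(c("a", "b"), c(50, 60))
  z <- standardize_within_dataset(v, g)
  for (gg in c("a", "b")) {
    expect_equal(mean(z[g == gg]), 0, tolerance = 1e-12)
    expect_equal(sd(z[g == gg]), 1, tolerance = 1e-12)
  }
  expect_equal(standardize_within_dataset(z, g), z, tolerance = 1e-12)
  expect_error(standardize_within_dataset(c(1, 2, 3), c("a", "a", "b")),
               "single subject")
  expect_error(standardize_within_dataset(c(1, 1, 2, 3), c("a", "a", "b", "b")),
               "constant")
})

test_that("covariate adjustment is exact OLS residualization", {
  set.seed(202)
  x <- rnorm(80)
  y <- 2 + 3 * x
  expect_equal(adjust_for_covariates(y, cbind(x)), rep(0, 80),
               tolerance = 1e-10)
  y2 <- rnorm(80)
  res <- adjust_for_covariates(y2, cbind(x))
  expect_equal(mean(res), 0, tolerance = 1e-10)
  expect_lt(abs(sum(res * x)), 1e-9)
  expect_error(adjust_for_covariates(y, cbind(x, 2 * x)), "rank deficient")
})

test_that("natural spline basis is C2 with linear tails and deterministic", {
  age <- seq(1, 100, by = 0.25)
  B <- natural_spline_basis(age, df = 3)
  expect_equal(ncol(B), 3)
  B2 <- natural_spline_basis(age, df = 3)
  expect_identical(unclass(B), unclass(B2))
  # second differences (~ second derivative) continuous across interior knots
  h <- 0.25
  for (j in 1:3) {
    d2 <- diff(B[, j], differences = 2) / h^2
    expect_lt(max(abs(diff(d2))), 1.5)   # piecewise-linear f'' has bounded steps
  }
  # linear beyond boundary knots: third differences vanish at the edges
  for (j in 1:3) {
    d3 <- diff(B[, j], differences = 3)
    expect_lt(max(abs(head(d3, 8))), 1e-5)
    expect_lt(max(abs(tail(d3, 8))), 1e-5)
  }
  expect_error(natural_spline_basis(c(1, 2, 3), df = 3), "distinct ages")
})

test_that("age-trend deviations sum to zero and duplication leaves estimates unchanged", {
  # noiseless cohort, identical effect in every dataset
  set.seed(204)
  n <- 300
  age <- rep(seq(20, 90, length.out = 100), 3)
  cohort <- data.frame(
    age = age,
    sex = rep(c(0, 1), length.out = n),
    dataset = rep(c("d1", "d2", "d3"), each = 100),
    total_reads = rep(1e4, n))
  # outcome exactly in the span of the spline basis, so the fit is exact
  # and grand-mean estimates cannot depend on dataset weights
  Bc <- natural_spline_basis(cohort$age, df = 3)
  cohort$idx <- standardize_within_dataset(
    as.numeric(2 * Bc[, 1] - Bc[, 2] + 3 * Bc[, 3]), cohort$dataset)
  fit <- suppressWarnings(fit_age_trend(cohort, "idx", standardize = FALSE))
  # per-term deviation estimates sum to zero across datasets
  for (tm in unique(fit$deviations$term)) {
    expect_equal(sum(fit$deviations$estimate[fit$deviations$term == tm]), 0,
                 tolerance = 1e-8)
  }
  # replicating one dataset 3x must not move the grand-mean coefficients
  cohort_dup <- rbind(cohort, cohort[cohort$dataset == "d2", ],
                      cohort[cohort$dataset == "d2", ])
  fit_dup <- suppressWarnings(fit_age_trend(cohort_dup, "idx",
                                            standardize = FALSE))
  expect_equal(fit$global[, "estimate"], fit_dup$global[, "estimate"],
               tolerance = 1e-6)
})

test_that("spline df selection prefers parsimony for linear signals", {
  set.seed(205)
  n <- 240
  cohort <- data.frame(
    age = rep(seq(20, 90, length.out = 80), 3),
    sex = rbinom(n, 1, 0.5),
    dataset = rep(c("d1", "d2", "d3"), each = 80),
    total_reads = round(rlnorm(n, log(1e4), 0.2)))
  cohort$idx <- 0.03 * cohort$age + rnorm(n, 0, 0.3)
  sel <- select_spline_df(cohort, "idx", df_grid = c(1, 3, 5))
  expect_equal(sel$chosen_df, 1)
  sel1 <- select_spline_df(cohort, "idx", df_grid = 4)
  expect_equal(sel1$chosen_df, 4)
  expect_equal(nrow(sel$criteria), 3)
})

test_that("pairwise Mann-Whitney tests match exact enumeration and rank invariance", {
  # {1,2,3} vs {101,102,103}: U = 0, exact two-sided p = 0.1
  p <- pairwise_group_test(c(1, 2, 3, 101, 102, 103),
                           rep(c("a", "b"), each = 3))
  expect_equal(p$p, 0.1, tolerance = 1e-12)
  # identical groups: p ~ 1
  p2 <- pairwise_group_test(c(1, 2, 3, 4, 1, 2, 3, 4),
                            rep(c("a", "b"), each = 4))
  expect_gte(p2$p, 0.99)
  # invariance under strictly monotone transforms
  set.seed(206)
  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), 10)
  p_raw <- pairwise_group_test(v, g)
  p_tr <- pairwise_group_test(exp(2 * v) + 5, g)
  expect_equal(p_raw$p, p_tr$p, tolerance = 1e-12)
  expect_equal(nrow(p_raw), 3)
  expect_error(pairwise_group_test(c(1, 2), c("a", "b")), "at least 2 subjects")
})
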