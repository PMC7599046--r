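test_that("acceptance test reproduces the worked per-bin examples exactly", {
  # identical histograms: zero distance, accept
  r0 <- acceptance_test(c(5, 3, 1), c(5, 3, 1), tolerance_base = "per-bin")
  expect_equal(r0$chi2, 0)
  expect_equal(r0$cdf, 0)
  expect_true(r0$accept)
  # |14 - 10| = 4 > 3 = 0.30 * 10: rejected by condition 1
  r1 <- acceptance_test(c(10, 5), c(14, 5), tolerance_base = "per-bin")
  expect_false(r1$accept)
  # condition 1 passes; chi2 = 4/18 + 1/11, df = 2, CDF = 1 - exp(-chi2/2)
  r2 <- acceptance_test(c(10, 5), c(8, 6), tolerance_base = "per-bin")
  expect_equal(r2$chi2, 4 / 18 + 1 / 11, tolerance = 1e-14)
  expect_equal(r2$df, 2)
  expect_equal(r2$cdf, 1 - exp(-r2$chi2 / 2), tolerance = 1e-12)
  expect_true(r2$accept)
  # shorter histogram is zero-padded
  r3 <- acceptance_test(c(10, 5), c(10, 5, 2), tolerance_base = "per-bin")
  expect_equal(r3$df, 3)
  expect_error(acceptance_test(integer(0), integer(0)), "empty")
})

test_that("total-count tolerance only rejects gross bin deviations", {
  # allowance 0.3 * 15 = 4.5 covers the |4| deviation that per-bin rejects
  rt <- acceptance_test(c(10, 5), c(14, 5), tolerance_base = "total")
  expect_true(rt$accept)
  rt2 <- acceptance_test(c(10, 5), c(15, 5), tolerance_base = "total")
  expect_false(rt2$accept)  # |5| > 4.5
})

test_that("proposals respect parameter domains and are seed-deterministic", {
  for (par in c("ratios", "rates")) {
    pr <- uninformative_priors(2, parametrization = par)
    pm <- with_seed(41, nichenb:::propose_matrix(pr, 500))
    expect_true(all(pm$b < pm$d))
    expect_true(all(pm$x > 0 & pm$x < 1))
    expect_true(all(pm$r > 0))
    expect_true(all(abs(rowSums(pm$w) - 1) < 1e-12))
    pm2 <- with_seed(41, nichenb:::propose_matrix(pr, 500))
    expect_identical(pm, pm2)
  }
  m <- with_seed(1, propose_models(uninformative_priors(1)))
  expect_s3_class(m, "mixture_model")
})

test_that("beta(1,1) weight prior yields uniform weights", {
  pr <- uninformative_priors(2)
  pm <- with_seed(8, nichenb:::propose_matrix(pr, 1e4))
  ks <- suppressWarnings(ks.test(pm$w[, 1], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("vectorized engine equals the straight-line reference loop draw for draw", {
  m <- geom_model()
  av <- sample_community(m, 50, seed = 70)
  cfg <- abc_config(n_sims = 1000, seed = 71)
  post <- abc_rejection(av, 1, config = cfg)
  ref <- reference_abc_loop(av, 1, uninformative_priors(1), cfg)
  expect_gt(post$n_accepted, 0)
  expect_identical(post$draws$proposal, which(ref$accept))
  expect_equal(post$draws$chi2, ref$chi2[ref$accept], tolerance = 1e-12)
  # and for a 2-niche model
  av2 <- sample_community(two_niche_model(), 50, seed = 72)
  cfg2 <- abc_config(n_sims = 1000, seed = 73)
  post2 <- abc_rejection(av2, 2, config = cfg2)
  ref2 <- reference_abc_loop(av2, 2, uninformative_priors(2), cfg2)
  expect_identical(post2$draws$proposal, which(ref2$accept))
})

test_that("ABC runs are reproducible and a vacuous run is flagged", {
  av <- sample_community(geom_model(), 60, seed = 80)
  cfg <- abc_config(n_sims = 2000, seed = 81)
  p1 <- abc_rejection(av, 1, config = cfg)
  p2 <- abc_rejection(av, 1, config = cfg)
  expect_identical(p1$draws, p2$draws)
  p0 <- abc_rejection(av, 1, config = abc_config(n_sims = 0, seed = 1))
  expect_equal(p0$n_accepted, 0L)
  expect_equal(p0$acceptance_rate, 0)
  expect_true("none-accepted" %in% p0$flags)
})

test_that("a matched point prior is accepted far more often than a mismatched one", {
  av <- sample_community(geom_model(), 100, seed = 90)
  tight <- function(v) list(family = "gamma", pars = c(2500, v / 2500))
  pr_match <- prior_spec(1, list(list(b = tight(1), d = tight(2), s = tight(1))))
  pr_wrong <- prior_spec(1, list(list(b = tight(0.05), d = tight(2), s = tight(8))))
  cfg <- abc_config(n_sims = 1e4, seed = 91)
  rate_match <- abc_rejection(av, 1, pr_match, cfg)$acceptance_rate
  rate_wrong <- abc_rejection(av, 1, pr_wrong, cfg)$acceptance_rate
  expect_gt(rate_match, 10 * max(rate_wrong, 1e-4))
})

test_that("tightening the bin tolerance never enlarges the accepted set", {
  av <- sample_community(geom_model(), 60, seed = 85)
  cfg_loose <- abc_config(n_sims = 3000, seed = 86, bin_tolerance = 0.3)
  cfg_tight <- abc_config(n_sims = 3000, seed = 86, bin_tolerance = 0.15)
  acc_loose <- abc_rejection(av, 1, config = cfg_loose)$draws$proposal
  acc_tight <- abc_rejection(av, 1, config = cfg_tight)$draws$proposal
  expect_true(all(acc_tight %in% acc_loose))
})

test_that("cap_draws keeps at most k draws with deterministic selection", {
  av <- sample_community(geom_model(), 60, seed = 95)
  post <- abc_rejection(av, 1, config = abc_config(n_sims = 5000, seed = 96))
  expect_gt(post$n_accepted, 5)
  kept <- cap_draws(post, 5, rule = "best-chi2")
  expect_equal(nrow(kept), 5)
  expect_true(all(kept$chi2 <= sort(post$draws$chi2)[5] + 1e-12))
  small <- post
  small$draws <- post$draws[1:3, ]
  expect_equal(nrow(cap_draws(small, 5)), 3)
  # equal chi2: first k in acceptance order
  tied <- post
  tied$draws$chi2 <- 1
  expect_equal(cap_draws(tied, 5)$proposal, head(tied$draws$proposal, 5))
  r1 <- cap_draws(post, 5, rule = "random", seed = 5)
  r2 <- cap_draws(post, 5, rule = "random", seed = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 5)
})

test_that("hyperprior fitting recovers generating hyperparameters from large pools", {
  set.seed(101)
  k <- 2
  n <- 500
  pool <- data.frame(b_rare = rgamma(n, shape = 2, scale = 3),
                     d_rare = rgamma(n, shape = 4, scale = 2),
                     s_rare = rgamma(n, shape = 2, scale = 1),
                     b_abundant = rgamma(n, shape = 3, scale = 1),
                     d_abundant = rgamma(n, shape = 5, scale = 1),
                     s_abundant = rgamma(n, shape = 2, scale = 2),
                     w_rare = rbeta(n, 2, 5))
  hp <- fit_hyperpriors(pool, k, parametrization = "rates")
  expect_equal(hp$rate_priors[[1]]$b$pars[1], 2, tolerance = 0.2)
  expect_equal(hp$rate_priors[[1]]$b$pars[2], 3, tolerance = 0.2)
  wfit <- hp$weight_priors[[1]]$pars
  expect_equal(wfit[1], 2, tolerance = 0.25)
  expect_equal(wfit[2], 5, tolerance = 0.25)
  # degenerate constant pool: variance floor, no error
  cpool <- pool
  cpool$b_rare <- 2
  expect_silent(fit_hyperpriors(cpool, k, parametrization = "rates"))
  expect_error(fit_hyperpriors(pool[1, ], k), "at least 2")
})

test_that("point estimates are medians after rare/abundant relabelling", {
  av <- sample_community(two_niche_model(), 100, seed = 110)
  post <- abc_rejection(av, 2, config = abc_config(n_sims = 5000, seed = 111))
  expect_gt(post$n_accepted, 0)
  pe <- point_estimates(post)
  expect_named(pe$theta, c("theta_rare", "theta_abundant"))
  # single accepted draw: medians equal that draw exactly
  one <- post
  one$draws <- post$draws[1, ]
  one$n_accepted <- 1L
  pe1 <- point_estimates(one)
  d <- one$draws
  means <- c(ztnb_mean(d$b1 / d$d1, d$s1 / d$b1),
             ztnb_mean(d$b2 / d$d2, d$s2 / d$b2))
  rare <- which.min(means)
  expect_equal(unname(pe1$medians["b_rare"]), d[[paste0("b", rare)]])
  # permuting niche order leaves the result unchanged
  sw <- one
  sw$draws <- transform(one$draws, b1 = d$b2, d1 = d$d2, s1 = d$s2,
                        b2 = d$b1, d2 = d$d1, s2 = d$s1, w1 = 1 - d$w1)
  pe_sw <- point_estimates(sw)
  expect_equal(pe_sw$theta, pe1$theta, tolerance = 1e-12)
  expect_equal(pe_sw$medians, pe1$medians, tolerance = 1e-12)
  # empty posterior: flagged, no theta
  p0 <- abc_rejection(av, 2, config = abc_config(n_sims = 0, seed = 1))
  pe0 <- point_estimates(p0)
  expect_true("none-accepted" %in% pe0$flags)
  expect_null(pe0$theta)
})

test_that("two-step fitting runs on a single sample and is reproducible", {
  av <- sample_community(geom_model(), 60, seed = 120)
  cfg <- abc_config(n_sims = 3000, seed = 121)
  f1 <- two_step_fit(av, 1, cfg)
  f2 <- two_step_fit(av, 1, cfg)
  expect_identical(f1$results, f2$results)
  expect_equal(nrow(f1$results), 1)
  expect_true(is.finite(f1$results$theta_single))
})

test_that("the dataset prior sharpens step-2 acceptance", {
  m <- geom_model()
  avs <- lapply(1:3, function(j) {
    av <- sample_community(m, 100, seed = 130 + j)
    av$sample_id <- paste0("s", j)
    av
  })
  cfg <- abc_config(n_sims = 1e4, seed = 140)
  fit <- two_step_fit(avs, 1, cfg)
  r1 <- vapply(fit$step1, `[[`, numeric(1), "acceptance_rate")
  r2 <- vapply(fit$step2, `[[`, numeric(1), "acceptance_rate")
  expect_gte(median(r2), median(r1))
})

test_that("model posteriors and log Bayes factors follow the acceptance-rate rule", {
  expect_equal(model_posterior(2000, 1e7), 2e-4)
  expect_equal(model_posterior(0, 1e7), 0)
  expect_equal(log_bayes_factor(1e-4, 1e-4), 0)
  expect_equal(log_bayes_factor(0, 0), 0)
  expect_equal(log_bayes_factor(2e-4, 1e-4), log(2.001e-4 / 1.001e-4),
               tolerance = 1e-12)
  expect_equal(log_bayes_factor(2e-4, 1e-4), 0.692647555268513,
               tolerance = 1e-10)
  expect_gt(log_bayes_factor(1e-3, 0), 0)
  expect_true(is.finite(log_bayes_factor(1e-3, 0)))
})
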