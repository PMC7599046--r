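test_that("ZTNB pmf reduces to a geometric law at r = 1 and normalizes", {
  # r = 1: pmf(n) = x^(n-1) (1-x) on n >= 1
  expect_equal(dztnb(1, 0.5, 1), 0.5, tolerance = 1e-14)
  n <- 1:30
  expect_equal(dztnb(n, 0.3, 1), 0.3^(n - 1) * 0.7, tolerance = 1e-13)
  for (x in c(0.1, 0.5, 0.9, 0.95)) {
    for (r in c(0.01, 0.1, 1, 10)) {
      nmax <- max(1000, qnbinom(1 - 1e-13, size = r, prob = 1 - x))
      expect_equal(sum(dztnb(seq_len(nmax), x, r)), 1, tolerance = 1e-9)
    }
  }
})

test_that("ZTNB pmf matches an independent closed-form evaluation", {
  expect_equal(dztnb(3, 0.9, 0.5), ztnb_pmf_oracle(3, 0.9, 0.5),
               tolerance = 1e-12)
  expect_equal(dztnb(3, 0.9, 0.5), 0.105357653273012, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:30) {
    x <- runif(1, 0.05, 0.95); r <- exp(runif(1, log(0.01), log(50)))
    n <- sample(1:200, 1)
    expect_equal(dztnb(n, x, r), ztnb_pmf_oracle(n, x, r),
                 tolerance = 1e-10)
  }
  expect_error(dztnb(0, 0.5, 1), "positive")
  expect_error(dztnb(1, 1.2, 1), "0, 1")
  expect_error(dztnb(1, 0.5, -1), "> 0")
})

test_that("ZTNB mean has its closed form and the support bound >= 1", {
  expect_equal(ztnb_mean(0.5, 1), 2)
  set.seed(4)
  for (i in 1:50) {
    x <- runif(1, 0.05, 0.95); r <- exp(runif(1, log(0.01), log(100)))
    expect_gte(ztnb_mean(x, r), 1)
    # mean agrees with pmf summation
    nmax <- max(2000, qnbinom(1 - 1e-12, size = r, prob = 1 - x))
    n <- seq_len(nmax)
    expect_equal(ztnb_mean(x, r), sum(n * dztnb(n, x, r)), tolerance = 1e-8)
  }
})

test_that("sampler mean agrees with the analytic mean within Monte Carlo error", {
  m <- mixture_model(niche_ratios(0.8, 2))
  av <- sample_community(m, 1e5, seed = 21)
  mu <- ztnb_mean(0.8, 2)
  se <- sd(av$counts) / sqrt(av$n_obs)
  expect_lt(abs(mean(av$counts) - mu), 3 * se)
  # geometric case
  av2 <- sample_community(geom_model(), 1000, seed = 22)
  expect_lt(abs(mean(av2$counts) - 2), 3 * sd(av2$counts) / sqrt(1000))
})

test_that("mixture pmf collapses correctly and normalizes", {
  n1 <- niche_ratios(0.4, 0.5); n2 <- niche_ratios(0.9, 2)
  m10 <- mixture_model(list(n1, n2), c(1, 0))
  n <- 1:50
  expect_equal(mixture_pmf(n, m10), dztnb(n, 0.4, 0.5), tolerance = 1e-14)
  msame <- mixture_model(list(n1, n1), c(0.3, 0.7))
  expect_equal(mixture_pmf(n, msame), dztnb(n, 0.4, 0.5), tolerance = 1e-14)
  set.seed(5)
  for (i in 1:10) {
    m <- mixture_model(list(niche_ratios(runif(1, .1, .9), exp(runif(1, -2, 2))),
                            niche_ratios(runif(1, .1, .9), exp(runif(1, -2, 2)))),
                       { a <- runif(1); c(a, 1 - a) })
    expect_equal(sum(mixture_pmf(1:200000, m)), 1, tolerance = 1e-9)
  }
})

test_that("expected SAD conserves richness, is linear in n_obs, and has the geometric value", {
  m <- geom_model()
  n <- 1:5000
  expect_equal(sum(expected_sad(n, m, 100)), 100, tolerance = 1e-6)
  expect_equal(expected_sad(n, m, 200), 2 * expected_sad(n, m, 100))
  # x = 0.5, r = 1: pmf(2) = 0.25, so 500 species give 125 expected
  expect_equal(expected_sad(2, m, 500), 125, tolerance = 1e-12)
})

test_that("Hubbell theta has its closed forms and algebraic inverse", {
  expect_equal(theta_hubbell(0.5, 1, 100), 100, tolerance = 1e-12)
  expect_equal(theta_hubbell(0.9, 0.5, 500), 500 / ((sqrt(10) - 1) * sqrt(pi)),
               tolerance = 1e-12)
  expect_equal(theta_hubbell(0.9, 0.5, 500), 130.461872205585, tolerance = 1e-10)
  set.seed(6)
  for (i in 1:50) {
    x <- runif(1, 0.05, 0.95); r <- exp(runif(1, log(0.01), log(100)))
    th <- theta_hubbell(x, r, 500)
    expect_equal(th * gamma(r) * ((1 - x)^(-r) - 1), 500, tolerance = 1e-6)
  }
  # large r stays finite through log-space evaluation
  expect_true(is.finite(theta_hubbell(0.5, 1000, 500)))
  # scale equivariance
  expect_equal(theta_hubbell(0.7, 2, 300), 3 * theta_hubbell(0.7, 2, 100),
               tolerance = 1e-15)
})

test_that("niches are labelled rare/abundant by expected abundance", {
  m <- two_niche_model()  # means 1.5 and 50
  lab <- label_niches(m)
  expect_equal(lab$labels, c("rare", "abundant"))
  # swapping list order keeps labels attached to the same parameters
  m_swapped <- mixture_model(rev(m$niches), rev(m$weights))
  lab2 <- label_niches(m_swapped)
  expect_equal(lab2$labels, c("abundant", "rare"))
  expect_equal(sort(lab$means), sort(lab2$means))
  # identical niches: tie broken by position, flagged
  mt <- mixture_model(list(niche_ratios(0.5, 1), niche_ratios(0.5, 1)),
                      c(0.5, 0.5))
  labt <- label_niches(mt)
  expect_true(labt$degenerate)
  expect_equal(labt$labels, c("rare", "abundant"))
  est <- theta_estimate(m, 500)
  expect_equal(unname(est$theta["rare"]), 1000, tolerance = 1e-10)
  expect_equal(unname(est$theta["abundant"]), 500 / 49, tolerance = 1e-10)
})

test_that("community sampling is seed-deterministic and distributionally exact", {
  m <- two_niche_model()
  a1 <- sample_community(m, 500, seed = 77)
  a2 <- sample_community(m, 500, seed = 77)
  expect_identical(a1$counts, a2$counts)
  expect_equal(a1$n_obs, 500)
  expect_true(all(a1$counts >= 1))
  # degenerate weights reproduce the single-niche distribution (chi-squared
  # against the analytic pmf, pooled tail)
  m10 <- mixture_model(list(niche_ratios(0.5, 1), niche_ratios(0.9, 5)),
                       c(1, 0))
  av <- sample_community(m10, 2e4, seed = 33)
  tab <- tabulate(av$counts, nbins = 30)
  p <- dztnb(1:30, 0.5, 1)
  keep <- 1:12
  obs <- c(tab[keep], av$n_obs - sum(tab[keep]))
  pr <- c(p[keep], 1 - sum(p[keep]))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr))$p.value, 0.01)
})
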