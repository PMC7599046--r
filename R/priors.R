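#' Prior specification for the ABC fitter
#'
#' A `prior_spec` holds one distribution family per model parameter: the
#' rates b, d, s of each niche and the free mixture weights (one for K = 2,
#' two for K = 3). Supported families are `log-uniform(lo, hi)`,
#' `uniform(lo, hi)`, `gamma(shape, scale)` and `beta(a, b)`.
#'
#' @param k number of niches (1-3).
#' @param rate_priors list of `k` lists, each with elements `b`, `d`, `s`,
#'   every element a `list(family =, pars =)`.
#' @param weight_priors list of `max(k - 1, 0)` weight families.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(k, rate_priors, weight_priors = list()) {
  stopifnot(k %in% 1:3, length(rate_priors) == k,
            length(weight_priors) == max(k - 1, 0))
  structure(list(k = k, rate_priors = rate_priors,
                 weight_priors = weight_priors),
            class = "prior_spec")
}

#' Uninformative step-one priors
#'
#' The RSA depends on the rates only through x = b/d and r = s/b, so the
#' default (`parametrization = "ratios"`) places the prior directly on the
#' identifiable scale: x uniform on (0, 1), r log-uniform on
#' `[r_lo, r_hi]`, with the unidentifiable death-rate scale d log-uniform
#' on `[d_lo, d_hi]` (b = x d and s = r b follow, and b < d holds by
#' construction). The alternative `"rates"` parametrization draws b, d and
#' s each log-uniform on `[rate_lo, rate_hi]` and resamples draws with
#' b >= d; it concentrates x near the stationarity boundary and spreads r
#' over `rate_hi / rate_lo` squared, which starves a rejection sampler of
#' acceptances at practical proposal counts. Mixture weights are uniform
#' on `[0, 1]` (beta(1, 1)) in both cases.
#'
#' @param k number of niches.
#' @param parametrization `"ratios"` (default) or `"rates"`.
#' @param r_lo,r_hi bounds of the log-uniform prior on r = s/b.
#' @param d_lo,d_hi bounds of the log-uniform prior on the nuisance scale d.
#' @param rate_lo,rate_hi bounds of the log-uniform rate priors under
#'   `"rates"`.
#' @return a [prior_spec].
#' @export
uninformative_priors <- function(k, parametrization = c("ratios", "rates"),
                                 r_lo = 1e-2, r_hi = 1e2,
                                 d_lo = 0.1, d_hi = 10,
                                 rate_lo = 1e-3, rate_hi = 1e3) {
  parametrization <- match.arg(parametrization)
  wp <- replicate(max(k - 1, 0), list(family = "beta", pars = c(1, 1)),
                  simplify = FALSE)
  if (parametrization == "rates") {
    lu <- list(family = "log-uniform", pars = c(rate_lo, rate_hi))
    rp <- replicate(k, list(b = lu, d = lu, s = lu), simplify = FALSE)
  } else {
    rp <- replicate(k, list(
      x = list(family = "uniform", pars = c(0, 1)),
      d = list(family = "log-uniform", pars = c(d_lo, d_hi)),
      r = list(family = "log-uniform", pars = c(r_lo, r_hi))),
      simplify = FALSE)
  }
  prior_spec(k, rp, wp)
}

# draw n values from one prior family
rfamily <- function(fam, n) {
  switch(fam$family,
    "log-uniform" = exp(runif(n, log(fam$pars[1]), log(fam$pars[2]))),
    "uniform"     = runif(n, fam$pars[1], fam$pars[2]),
    "gamma"       = rgamma(n, shape = fam$pars[1], scale = fam$pars[2]),
    "beta"        = rbeta(n, fam$pars[1], fam$pars[2]),
    stop_input("unknown prior family '%s'", fam$family))
}

# Vectorized proposal draw. Consumption order is fixed (per niche: b, d, s;
# then weights), and rows with b >= d (or weight sums > 1 for K = 3) are
# redrawn until valid, with an attempt cap.
propose_matrix <- function(priors, n, resample_cap = 1e4) {
  stopifnot(inherits(priors, "prior_spec"))
  k <- priors$k
  b <- d <- s <- matrix(0, n, k)
  for (i in seq_len(k)) {
    rp <- priors$rate_priors[[i]]
    if (!is.null(rp$x)) {
      # ratio parametrization: x, d, r drawn; b and s derived (b < d holds)
      xv <- rfamily(rp$x, n)
      bad <- which(xv <= 0 | xv >= 1)
      while (length(bad)) {
        xv[bad] <- rfamily(rp$x, length(bad))
        bad <- bad[xv[bad] <= 0 | xv[bad] >= 1]
      }
      d[, i] <- rfamily(rp$d, n)
      b[, i] <- xv * d[, i]
      s[, i] <- rfamily(rp$r, n) * b[, i]
    } else {
      b[, i] <- rfamily(rp$b, n)
      d[, i] <- rfamily(rp$d, n)
      s[, i] <- rfamily(rp$s, n)
      bad <- which(b[, i] >= d[, i])
      tries <- 0
      while (length(bad)) {
        tries <- tries + 1
        if (tries > resample_cap)
          stop_input("resample cap exceeded enforcing b < d for niche %d prior", i)
        b[bad, i] <- rfamily(rp$b, length(bad))
        d[bad, i] <- rfamily(rp$d, length(bad))
        bad <- bad[b[bad, i] >= d[bad, i]]
      }
    }
  }
  w <- matrix(1, n, k)
  if (k == 2) {
    w1 <- rfamily(priors$weight_priors[[1]], n)
    w <- cbind(w1, 1 - w1)
  } else if (k == 3) {
    w1 <- rfamily(priors$weight_priors[[1]], n)
    w2 <- rfamily(priors$weight_priors[[2]], n)
    bad <- which(w1 + w2 > 1)
    tries <- 0
    while (length(bad)) {
      tries <- tries + 1
      if (tries > resample_cap)
        stop_input("resample cap exceeded enforcing weight simplex")
      w1[bad] <- rfamily(priors$weight_priors[[1]], length(bad))
      w2[bad] <- rfamily(priors$weight_priors[[2]], length(bad))
      bad <- bad[w1[bad] + w2[bad] > 1]
    }
    w <- cbind(w1, w2, 1 - w1 - w2)
  }
  list(b = b, d = d, s = s, x = b / d, r = s / b, w = w, k = k, n = n)
}

#' Draw mixture models from a prior specification
#'
#' Samples `n` parameter sets from the priors, resampling any draw that
#' violates b < d (or, for three niches, a weight sum above one).
#'
#' @param priors a [prior_spec].
#' @param n number of models to draw.
#' @param resample_cap maximum resampling attempts before erroring.
#' @return a list of `n` [mixture_model] objects (a single model for
#'   `n = 1`).
#' @export
propose_models <- function(priors, n = 1, resample_cap = 1e4) {
  pm <- propose_matrix(priors, n, resample_cap)
  models <- lapply(seq_len(n), function(i) {
    niches <- lapply(seq_len(pm$k), function(j)
      niche_rates(pm$b[i, j], pm$d[i, j], pm$s[i, j]))
    mixture_model(niches, pm$w[i, ])
  })
  if (n == 1) models[[1]] else models
}

# parameter column names for accepted-draw tables, by niche label
draw_colnames <- function(k) {
  labs <- switch(k, "single", c("rare", "abundant"), c("rare", "middle", "abundant"))
  rates <- as.vector(outer(c("b", "d", "s"), labs, paste, sep = "_"))
  wts <- if (k >= 2) paste0("w_", labs[-k]) else character(0)
  c(rates, wts)
}

# Relabel raw draws (columns b1,d1,s1,...,w1,...) so that niches are ordered
# by increasing ZTNB mean: rare (, middle), abundant. Prevents
# label-switching artifacts before pooling or summarising.
relabel_draws <- function(draws, k) {
  n <- nrow(draws)
  means <- sapply(seq_len(k), function(j)
    ztnb_mean(draws[[paste0("b", j)]] / draws[[paste0("d", j)]],
              draws[[paste0("s", j)]] / draws[[paste0("b", j)]]))
  means <- matrix(means, nrow = n)
  ord <- t(apply(means, 1, order))            # per-row permutation, rare first
  if (k == 1) ord <- matrix(1L, n, 1)
  wfull <- matrix(1, n, k)
  if (k >= 2) {
    wcols <- sapply(seq_len(k - 1), function(j) draws[[paste0("w", j)]])
    wcols <- matrix(wcols, nrow = n)
    wfull <- cbind(wcols, 1 - rowSums(wcols))
  }
  out <- data.frame(matrix(NA_real_, n, length(draw_colnames(k))))
  names(out) <- draw_colnames(k)
  labs <- switch(k, "single", c("rare", "abundant"),
                 c("rare", "middle", "abundant"))
  for (pos in seq_len(k)) {
    src <- ord[, pos]
    idx <- cbind(seq_len(n), src)
    bmat <- matrix(sapply(seq_len(k), function(j) draws[[paste0("b", j)]]), nrow = n)
    dmat <- matrix(sapply(seq_len(k), function(j) draws[[paste0("d", j)]]), nrow = n)
    smat <- matrix(sapply(seq_len(k), function(j) draws[[paste0("s", j)]]), nrow = n)
    out[[paste0("b_", labs[pos])]] <- bmat[idx]
    out[[paste0("d_", labs[pos])]] <- dmat[idx]
    out[[paste0("s_", labs[pos])]] <- smat[idx]
    if (pos < k) out[[paste0("w_", labs[pos])]] <- wfull[idx]
  }
  out
}

# method-of-moments gamma fit with variance floor
gamma_mme <- function(v) {
  m <- mean(v); va <- var(v)
  if (!is.finite(va) || va < (1e-8 * max(m, 1e-12))^2)
    va <- (0.1 * max(m, 1e-12))^2          # variance floor for degenerate pools
  list(shape = m^2 / va, scale = va / m, degenerate = va == (0.1 * max(m, 1e-12))^2)
}

beta_mme <- function(v) {
  v <- pmin(pmax(v, 1e-6), 1 - 1e-6)
  m <- mean(v); va <- var(v)
  if (!is.finite(va) || va < 1e-12) va <- 1e-4   # variance floor
  c0 <- m * (1 - m) / va - 1
  if (c0 <= 0) c0 <- 1e-2
  list(a = m * c0, b = (1 - m) * c0)
}

#' Fit dataset-level hyperpriors from pooled accepted draws
#'
#' Implements the hierarchical refit between the two ABC steps: the accepted
#' draws of all samples in a dataset (relabelled rare/abundant first) are
#' pooled and refitted with parametric families, which then serve as the
#' dataset-specific step-2 prior. Mixture coefficients always get a Beta
#' distribution. Under the default `"ratios"` parametrization the refit is
#' done on the identifiable scale — Beta for x = b/d (support (0, 1)),
#' Gamma for r = s/b and for the nuisance scale d — which preserves the
#' b-d coupling the acceptance region lives on; under `"rates"` each of b,
#' d, s is fitted with a Gamma distribution directly. Maximum likelihood is
#' used with a method-of-moments fallback on non-convergence; a variance
#' floor is applied to degenerate (near-constant) pools. Because step-1
#' pools are typically tiny (a handful of draws per sample), the fitted
#' variance is conservatively inflated by `1 + 8 / n_pooled`: a small pool
#' must not produce an overconfident step-2 prior, and the step-2
#' acceptance test re-filters a broader prior at the cost of compute only.
#'
#' @param pooled data.frame of relabelled draws (columns as produced by the
#'   two-step fitter: `b_rare`, `d_rare`, ..., `w_rare`).
#' @param k number of niches.
#' @param parametrization `"ratios"` (default) or `"rates"`, normally
#'   matching the step-1 prior.
#' @return a [prior_spec] with fitted niche and weight priors; attribute
#'   `n_pooled` records the pool size.
#' @export
fit_hyperpriors <- function(pooled, k,
                            parametrization = c("ratios", "rates")) {
  parametrization <- match.arg(parametrization)
  if (nrow(pooled) < 2)
    stop_input("at least 2 pooled draws are required to fit hyperpriors; fall back to step-1 priors")
  labs <- switch(k, "single", c("rare", "abundant"),
                 c("rare", "middle", "abundant"))
  n_pool <- nrow(pooled)
  inflate <- 1 + 8 / n_pool
  fit_gamma <- function(v) {
    if (n_pool < 30) {
      # moment fit with small-pool variance inflation; ML on a handful of
      # points is noise dressed up as certainty
      m <- mean(v)
      va <- var(v) * inflate
      if (!is.finite(va) || va < (0.1 * max(m, 1e-12))^2)
        va <- (0.1 * max(m, 1e-12))^2
      return(list(family = "gamma", pars = c(m^2 / va, va / m)))
    }
    mme <- gamma_mme(v)
    if (var(v) == 0) return(list(family = "gamma", pars = c(mme$shape, mme$scale)))
    ml <- tryCatch({
      f <- suppressWarnings(fitdistrplus::fitdist(v, "gamma", method = "mle"))
      list(family = "gamma",
           pars = c(unname(f$estimate["shape"]), 1 / unname(f$estimate["rate"])))
    }, error = function(e) NULL)
    ml %||% list(family = "gamma", pars = c(mme$shape, mme$scale))
  }
  fit_beta <- function(v) {
    vc <- pmin(pmax(v, 1e-6), 1 - 1e-6)
    if (n_pool < 30) {
      m <- mean(vc)
      va <- var(vc) * inflate
      vmax <- m * (1 - m)
      if (!is.finite(va) || va < 1e-4) va <- 1e-4
      if (va >= vmax) va <- 0.9 * vmax
      c0 <- vmax / va - 1
      return(list(family = "beta", pars = c(m * c0, (1 - m) * c0)))
    }
    ml <- if (var(vc) > 0) tryCatch({
      f <- suppressWarnings(fitdistrplus::fitdist(vc, "beta", method = "mle"))
      list(family = "beta",
           pars = c(unname(f$estimate["shape1"]), unname(f$estimate["shape2"])))
    }, error = function(e) NULL) else NULL
    if (is.null(ml)) {
      mm <- beta_mme(v)
      ml <- list(family = "beta", pars = c(mm$a, mm$b))
    }
    ml
  }
  rp <- if (parametrization == "rates") {
    lapply(labs, function(lb) list(
      b = fit_gamma(pooled[[paste0("b_", lb)]]),
      d = fit_gamma(pooled[[paste0("d_", lb)]]),
      s = fit_gamma(pooled[[paste0("s_", lb)]])))
  } else {
    lapply(labs, function(lb) {
      b <- pooled[[paste0("b_", lb)]]
      d <- pooled[[paste0("d_", lb)]]
      s <- pooled[[paste0("s_", lb)]]
      list(x = fit_beta(b / d), d = fit_gamma(d), r = fit_gamma(s / b))
    })
  }
  wp <- if (k >= 2) lapply(labs[-k], function(lb)
    fit_beta(pooled[[paste0("w_", lb)]])) else list()
  out <- prior_spec(k, rp, wp)
  attr(out, "n_pooled") <- nrow(pooled)
  out
}
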