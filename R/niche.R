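#' Niche rates: birth, death and immigration
#'
#' The per-capita birth rate b, death rate d and immigration influx s of one
#' neutral niche. The stationary RSA of the underlying birth-death-
#' immigration process exists only for b < d, and zero-truncation requires
#' s > 0. All distributional quantities depend on the rates only through the
#' ratios x = b/d and r = s/b (see [niche_ratios]).
#'
#' @param b per-capita birth rate (> 0).
#' @param d per-capita death rate (> b).
#' @param s immigration influx (> 0).
#' @return an object of class `niche_rates`.
#' @export
niche_rates <- function(b, d, s) {
  if (!is.finite(b) || b <= 0) stop_input("birth rate b must be > 0")
  if (!is.finite(d) || d <= 0) stop_input("death rate d must be > 0")
  if (b >= d) stop_input("stationarity requires b < d (got b = %g, d = %g)", b, d)
  if (!is.finite(s) || s <= 0) stop_input("immigration s must be > 0")
  structure(list(b = b, d = d, s = s), class = "niche_rates")
}

#' Niche ratios x = b/d and r = s/b
#'
#' The identifiable parametrization of a niche: the zero-truncated Negative
#' Binomial RSA depends on the rates only through x = b/d in (0, 1) and
#' r = s/b > 0.
#'
#' @param x ratio b/d, in (0, 1).
#' @param r ratio s/b, > 0.
#' @return an object of class `niche_ratios`.
#' @export
niche_ratios <- function(x, r) {
  if (!is.finite(x) || x <= 0 || x >= 1) stop_input("x = b/d must lie in (0, 1)")
  if (!is.finite(r) || r <= 0) stop_input("r = s/b must be > 0")
  structure(list(x = x, r = r), class = "niche_ratios")
}

#' @rdname niche_ratios
#' @param rates a [niche_rates] object.
#' @export
as_niche_ratios <- function(rates) {
  if (inherits(rates, "niche_ratios")) return(rates)
  stopifnot(inherits(rates, "niche_rates"))
  niche_ratios(rates$b / rates$d, rates$s / rates$b)
}

#' Mixture of neutral niches
#'
#' A community model with K in {1, 2, 3} non-interacting neutral niches and
#' mixture weights summing to one. Each species belongs to one niche with
#' probability given by the weights, and its abundance follows that niche's
#' zero-truncated Negative Binomial.
#'
#' @param niches a list of 1-3 [niche_rates] or [niche_ratios] objects.
#' @param weights numeric vector of the same length, non-negative, summing
#'   to 1 (a single niche may omit it).
#' @return an object of class `mixture_model` with elements `niches`
#'   (as `niche_ratios`), `rates` (the original rates, when supplied),
#'   `weights` and `k`.
#' @export
mixture_model <- function(niches, weights = NULL) {
  if (inherits(niches, "niche_rates") || inherits(niches, "niche_ratios"))
    niches <- list(niches)
  k <- length(niches)
  if (k < 1 || k > 3) stop_input("a mixture must have 1 to 3 niches (got %d)", k)
  if (is.null(weights)) {
    if (k != 1) stop_input("weights are required for K > 1")
    weights <- 1
  }
  if (length(weights) != k) stop_input("need one weight per niche")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop_input("weights must be non-negative and sum to 1")
  rates <- lapply(niches, function(n) if (inherits(n, "niche_rates")) n else NULL)
  structure(list(niches = lapply(niches, as_niche_ratios),
                 rates = rates,
                 weights = as.numeric(weights),
                 k = k),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model with %d niche(s):\n", x$k))
  for (i in seq_len(x$k)) {
    cat(sprintf("  niche %d: x = %.4g, r = %.4g, weight = %.3f (mean abundance %.3g)\n",
                i, x$niches[[i]]$x, x$niches[[i]]$r, x$weights[i],
                ztnb_mean(x$niches[[i]]$x, x$niches[[i]]$r)))
  }
  invisible(x)
}

#' Zero-truncated Negative Binomial probability mass function
#'
#' The stationary RSA of one neutral niche:
#' `P(n) = x^n Gamma(n + r) / (n! Gamma(r) ((1 - x)^(-r) - 1))` for
#' n >= 1, with x = b/d and r = s/b. Evaluated in log space through the
#' untruncated Negative Binomial density, so large r and extreme x are
#' handled without overflow.
#'
#' @param n vector of positive integer abundances.
#' @param x ratio b/d in (0, 1); a [niche_ratios] may be given instead, in
#'   which case `r` is ignored.
#' @param r ratio s/b > 0.
#' @param log return log-probabilities.
#' @return numeric vector of probabilities.
#' @export
dztnb <- function(n, x, r = NULL, log = FALSE) {
  if (inherits(x, "niche_ratios")) { r <- x$r; x <- x$x }
  if (!is.numeric(x) || any(x <= 0 | x >= 1)) stop_input("x must lie in (0, 1)")
  if (!is.numeric(r) || any(r <= 0)) stop_input("r must be > 0")
  if (any(n < 1 | n != round(n))) stop_input("n must be a positive integer")
  # log P(X = 0) = r * log(1 - x); normalize by log(1 - (1-x)^r)
  log_p0 <- r * log1p(-x)
  lp <- dnbinom(n, size = r, prob = 1 - x, log = TRUE) - log1p(-exp(log_p0))
  if (log) lp else exp(lp)
}

#' Mean of the zero-truncated Negative Binomial
#'
#' Closed form `r x / ((1 - x) (1 - (1 - x)^r))`; used to order niches into
#' rare and abundant.
#'
#' @inheritParams dztnb
#' @return the expected abundance (always >= 1).
#' @export
ztnb_mean <- function(x, r = NULL) {
  if (inherits(x, "niche_ratios")) { r <- x$r; x <- x$x }
  if (any(x <= 0 | x >= 1) || any(r <= 0)) stop_input("invalid (x, r)")
  r * x / ((1 - x) * -expm1(r * log1p(-x)))
}

#' Mixture RSA probability mass function
#'
#' Weighted sum of the component zero-truncated Negative Binomials.
#'
#' @param n vector of positive integer abundances.
#' @param model a [mixture_model].
#' @return numeric vector of probabilities.
#' @export
mixture_pmf <- function(n, model) {
  stopifnot(inherits(model, "mixture_model"))
  out <- 0
  for (i in seq_len(model$k)) {
    out <- out + model$weights[i] * dztnb(n, model$niches[[i]])
  }
  out
}

#' Expected species-abundance distribution
#'
#' Expected number of species with exactly `n` individuals under a mixture
#' model for a community of `n_obs` observed species:
#' `n_obs * mixture_pmf(n, model)`.
#'
#' @inheritParams mixture_pmf
#' @param n_obs observed species richness (>= 1).
#' @return numeric vector of expected species counts.
#' @export
expected_sad <- function(n, model, n_obs) {
  if (n_obs < 1) stop_input("n_obs must be >= 1")
  n_obs * mixture_pmf(n, model)
}

#' Hubbell biodiversity number of one niche
#'
#' `theta = n_obs / (((1 - x)^(-r) - 1) * Gamma(r))`, evaluated in log
#' space. This is the fundamental biodiversity number of neutral theory,
#' computed from the fitted niche ratios and the observed richness; in a
#' two-niche model the rare and abundant niches yield theta_rare and
#' theta_abundant.
#'
#' @inheritParams dztnb
#' @param n_obs observed species richness (>= 1).
#' @return the biodiversity number (> 0).
#' @export
theta_hubbell <- function(x, r = NULL, n_obs) {
  if (inherits(x, "niche_ratios")) { r <- x$r; x <- x$x }
  if (any(x <= 0 | x >= 1) || any(r <= 0)) stop_input("invalid (x, r)")
  if (any(n_obs < 1)) stop_input("n_obs must be >= 1")
  a <- -r * log1p(-x)                      # a = -r log(1-x) > 0
  log_denom <- a + log1p(-exp(-a))         # log((1-x)^(-r) - 1)
  exp(log(n_obs) - log_denom - lgamma(r))
}

#' Order the niches of a mixture into rare / abundant
#'
#' Niches are ranked by their expected abundance ([ztnb_mean]): the smallest
#' mean is labelled `rare`, the largest `abundant`, and for K = 3 the
#' remaining one `middle` (K = 1 gets `single`). Exact ties are broken by
#' list position and flagged degenerate.
#'
#' @param model a [mixture_model].
#' @return a list with `order` (permutation of niche indices, rare first),
#'   `labels` (per original niche), `means`, and `degenerate` flag.
#' @export
label_niches <- function(model) {
  stopifnot(inherits(model, "mixture_model"))
  means <- vapply(model$niches, function(nr) ztnb_mean(nr$x, nr$r), numeric(1))
  ord <- order(means)  # ties broken by list position (stable)
  labels <- character(model$k)
  if (model$k == 1) {
    labels <- "single"
  } else if (model$k == 2) {
    labels[ord] <- c("rare", "abundant")
  } else {
    labels[ord] <- c("rare", "middle", "abundant")
  }
  list(order = ord, labels = labels, means = means,
       degenerate = anyDuplicated(means) > 0)
}

#' Biodiversity numbers of every niche of a mixture
#'
#' Computes [theta_hubbell] for each niche and attaches the rare / abundant
#' labels of [label_niches].
#'
#' @param model a [mixture_model].
#' @param n_obs observed species richness.
#' @return a list with `theta` (named by label, in rare-to-abundant order),
#'   `labels`, `means` and `degenerate`.
#' @export
theta_estimate <- function(model, n_obs) {
  lab <- label_niches(model)
  th <- vapply(model$niches, function(nr) theta_hubbell(nr$x, nr$r, n_obs),
               numeric(1))
  list(theta = setNames(th[lab$order], lab$labels[lab$order]),
       labels = lab$labels, means = lab$means, degenerate = lab$degenerate)
}

#' Sample a community from a niche mixture
#'
#' Draws `n_obs` species abundances: each species is assigned to a niche by
#' the mixture weights and its abundance is drawn from that niche's
#' zero-truncated Negative Binomial. Zero truncation uses rejection of zero
#' draws when zeros are rare and CDF inversion when they are not, so
#' pathological parameter sets cannot stall the sampler; a single abundance
#' above 1e9 aborts the draw (near-critical x).
#'
#' @param model a [mixture_model].
#' @param n_obs number of species to draw (>= 1).
#' @param seed optional integer seed; when given, the caller's RNG state is
#'   left untouched and the same seed always reproduces the same community.
#' @return an [abundance_vector].
#' @export
sample_community <- function(model, n_obs, seed = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  if (n_obs < 1) stop_input("n_obs must be >= 1")
  x <- vapply(model$niches, `[[`, numeric(1), "x")
  r <- vapply(model$niches, `[[`, numeric(1), "r")
  counts <- with_seed(seed,
    cpp_sample_community(as.integer(n_obs), x, r, model$weights))
  names(counts) <- paste0("OTU_", seq_along(counts))
  structure(list(sample_id = "simulated",
                 counts = counts,
                 n_obs = length(counts),
                 total_reads = sum(as.numeric(counts))),
            class = "abundance_vector")
}
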