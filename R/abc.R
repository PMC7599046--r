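#' Configuration of the ABC rejection fitter
#'
#' @param n_sims number of prior proposals per ABC run (use 1e7 for
#'   full-scale fits; 1e4-1e5 is a practical desk scale).
#' @param bin_tolerance condition-1 tolerance: the allowed absolute
#'   deviation per Preston bin, as a fraction of the reference count set by
#'   `tolerance_base`.
#' @param chi2_cdf_cutoff accept when the chi-squared CDF at the Skellam
#'   statistic is below this value.
#' @param tolerance_base what the condition-1 allowance is 30% of:
#'   `"total"` (the sample's total bin count, so only gross per-bin
#'   deviations violate condition 1 and the chi-squared criterion is the
#'   operative filter — the behaviour consistent with acceptance rates
#'   reported for this method) or `"per-bin"` (each bin's own data count,
#'   a much stricter variant that forces small tail bins to match almost
#'   exactly).
#' @param max_accept_pooling per-sample cap on accepted draws carried into
#'   the hyperprior pool.
#' @param pseudo_count floor added to model posterior probabilities before
#'   taking log Bayes factors.
#' @param seed root seed; per-sample, per-step and per-proposal streams are
#'   derived from it so results do not depend on evaluation order.
#' @param df_mode degrees of freedom of the chi-squared test: `"union"`
#'   counts bins non-zero in either histogram (the summands of the
#'   statistic), `"data"` only data-positive bins.
#' @param cap_rule which draws survive the per-sample cap: `"best-chi2"`
#'   (smallest statistic, ties by acceptance order) or `"random"`.
#' @return an object of class `abc_config`.
#' @export
abc_config <- function(n_sims = 1e5, bin_tolerance = 0.3,
                       chi2_cdf_cutoff = 0.5, max_accept_pooling = 5,
                       pseudo_count = 1e-7, seed = NULL,
                       tolerance_base = c("total", "per-bin"),
                       df_mode = c("union", "data"),
                       cap_rule = c("best-chi2", "random")) {
  stopifnot(n_sims >= 0, bin_tolerance > 0, bin_tolerance < 1,
            chi2_cdf_cutoff > 0, chi2_cdf_cutoff < 1, max_accept_pooling >= 1)
  structure(list(n_sims = as.integer(n_sims), bin_tolerance = bin_tolerance,
                 chi2_cdf_cutoff = chi2_cdf_cutoff,
                 max_accept_pooling = as.integer(max_accept_pooling),
                 pseudo_count = pseudo_count, seed = seed,
                 tolerance_base = match.arg(tolerance_base),
                 df_mode = match.arg(df_mode),
                 cap_rule = match.arg(cap_rule)),
            class = "abc_config")
}

#' Preston-plot acceptance test
#'
#' Compares an observed and a simulated Preston histogram (the shorter is
#' zero-padded) with the two ABC acceptance conditions: (1) per bin, the
#' absolute difference between simulation and data counts is at most
#' `bin_tolerance` times the reference count — the sample total under
#' `tolerance_base = "total"` (default), or the bin's own data count under
#' `"per-bin"`, in which case only data-positive bins are constrained;
#' (2) the Skellam-motivated statistic
#' `chi2 = sum (d_i - s_i)^2 / (d_i + s_i)` over bins with `d_i + s_i > 0`,
#' on `df` such bins, has chi-squared CDF below `chi2_cdf_cutoff`.
#'
#' @param data_bins,sim_bins [preston_histogram] objects or integer
#'   vectors of octave counts.
#' @param config an [abc_config] (or leave default and set the two
#'   thresholds directly).
#' @param bin_tolerance,chi2_cdf_cutoff,tolerance_base,df_mode overrides
#'   of the corresponding `config` fields.
#' @return a list with `accept`, `chi2`, `df` and `cdf`.
#' @export
acceptance_test <- function(data_bins, sim_bins, config = abc_config(),
                            bin_tolerance = config$bin_tolerance,
                            chi2_cdf_cutoff = config$chi2_cdf_cutoff,
                            tolerance_base = config$tolerance_base,
                            df_mode = config$df_mode) {
  d <- if (inherits(data_bins, "preston_histogram")) data_bins$bin_counts else as.numeric(data_bins)
  s <- if (inherits(sim_bins, "preston_histogram")) sim_bins$bin_counts else as.numeric(sim_bins)
  if (sum(d) == 0 && sum(s) == 0) stop_input("both histograms are empty")
  nb <- max(length(d), length(s))
  d <- c(d, numeric(nb - length(d)))
  s <- c(s, numeric(nb - length(s)))
  pos <- d > 0
  cond1 <- if (tolerance_base == "per-bin") {
    all(abs(s[pos] - d[pos]) <= bin_tolerance * d[pos] + 1e-9)
  } else {
    all(abs(s - d) <= bin_tolerance * sum(d) + 1e-9)
  }
  use <- (d + s) > 0
  chi2 <- sum((d[use] - s[use])^2 / (d[use] + s[use]))
  df <- if (df_mode == "union") sum(use) else sum(pos)
  cdf <- if (df > 0) pchisq(chi2, df) else 0
  list(accept = cond1 && (cdf < chi2_cdf_cutoff), chi2 = chi2,
       df = df, cdf = cdf)
}

#' ABC rejection fit of one sample
#'
#' Draws `n_sims` parameter sets from the priors, simulates a community with
#' the sample's observed richness for each, and keeps the draws whose
#' Preston histogram passes [acceptance_test] against the data. Every
#' proposal's community is generated under its own seed derived from the
#' root, so the accepted set does not depend on proposal order and an
#' equivalent straight-line loop reproduces it draw for draw.
#'
#' @param av an [abundance_vector].
#' @param model_kind number of niches (1, 2 or 3).
#' @param priors a [prior_spec]; defaults to [uninformative_priors].
#' @param config an [abc_config].
#' @return an object of class `sample_posterior`: accepted draws (raw
#'   parameter columns `b1, d1, s1, ...` plus `chi2`, `df` and the proposal
#'   index), proposal counts, acceptance rate and flags. Zero accepted
#'   draws is a valid, flagged outcome.
#' @export
abc_rejection <- function(av, model_kind = 2,
                          priors = uninformative_priors(model_kind),
                          config = abc_config()) {
  stopifnot(inherits(av, "abundance_vector"), model_kind %in% 1:3,
            priors$k == model_kind)
  data_bins <- preston_histogram(av)$bin_counts
  n <- config$n_sims
  root <- config$seed %||% sample.int(2147483646L, 1)
  empty <- data.frame(matrix(numeric(0), 0,
                             3 * model_kind + max(model_kind - 1, 0)))
  names(empty) <- c(paste0(rep(c("b", "d", "s"), model_kind),
                           rep(seq_len(model_kind), each = 3)),
                    if (model_kind >= 2) paste0("w", seq_len(model_kind - 1)))
  if (n == 0) {
    return(structure(list(sample_id = av$sample_id, model_kind = model_kind,
                          draws = cbind(empty, chi2 = numeric(0),
                                        df = integer(0), proposal = integer(0)),
                          n_proposals = 0L, n_accepted = 0L,
                          acceptance_rate = 0, n_aborted = 0L,
                          flags = "none-accepted", n_obs = av$n_obs,
                          seed = root),
                     class = "sample_posterior"))
  }
  prop <- with_seed(derive_seed(root, "proposals"),
                    propose_matrix(priors, n))
  seeds <- derive_seed_vec(derive_seed(root, "communities"), seq_len(n))
  res <- cpp_abc_loop(as.integer(data_bins), as.integer(av$n_obs),
                      prop$x, prop$r, prop$w, seeds,
                      config$bin_tolerance, config$chi2_cdf_cutoff,
                      config$df_mode == "union",
                      config$tolerance_base == "total")
  acc <- which(res$accept)
  draws <- data.frame(matrix(NA_real_, length(acc), ncol(empty)))
  names(draws) <- names(empty)
  for (j in seq_len(model_kind)) {
    draws[[paste0("b", j)]] <- prop$b[acc, j]
    draws[[paste0("d", j)]] <- prop$d[acc, j]
    draws[[paste0("s", j)]] <- prop$s[acc, j]
    if (j <= model_kind - 1) draws[[paste0("w", j)]] <- prop$w[acc, j]
  }
  draws$chi2 <- res$chi2[acc]
  draws$df <- res$df[acc]
  draws$proposal <- acc
  rate <- length(acc) / n
  flags <- character(0)
  if (length(acc) == 0) flags <- c(flags, "none-accepted")
  else if (rate < 1e-4) flags <- c(flags, "low-acceptance")
  structure(list(sample_id = av$sample_id, model_kind = model_kind,
                 draws = draws, n_proposals = n,
                 n_accepted = length(acc), acceptance_rate = rate,
                 n_aborted = sum(res$status == 3L),
                 flags = flags, n_obs = av$n_obs, seed = root),
            class = "sample_posterior")
}

# vectorized one-token derive_seed, consistent with derive_seed(root, i)
derive_seed_vec <- function(root, idx) {
  m <- 2147483647
  h <- ((as.numeric(root) %% m) * 69069 + as.numeric(idx) + 1) %% m
  as.integer(h %% (m - 2) + 1)
}

#' @export
print.sample_posterior <- function(x, ...) {
  cat(sprintf("sample_posterior '%s' (%dNB): %d / %s accepted (rate %.3g)%s\n",
              x$sample_id, x$model_kind, x$n_accepted,
              format(x$n_proposals, big.mark = ","), x$acceptance_rate,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Cap the accepted draws of one sample
#'
#' Limits the number of accepted parameter sets carried forward per sample
#' (default 5), preventing samples with thousands of acceptances from
#' dominating the hyperprior pool. The default keeps the draws with the
#' smallest chi-squared statistic, ties broken by acceptance order; rule
#' `"random"` keeps a uniform random subset (seeded).
#'
#' @param posterior a `sample_posterior`.
#' @param k cap (default 5).
#' @param rule `"best-chi2"` or `"random"`.
#' @param seed seed for the random rule.
#' @return a data.frame of at most `k` accepted draws.
#' @export
cap_draws <- function(posterior, k = 5, rule = c("best-chi2", "random"),
                      seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(k >= 1)
  dr <- posterior$draws
  if (nrow(dr) <= k) return(dr)
  keep <- if (rule == "best-chi2") {
    order(dr$chi2, dr$proposal)[seq_len(k)]
  } else {
    sort(with_seed(seed, sample.int(nrow(dr), k)))
  }
  dr[keep, , drop = FALSE]
}

#' Point estimates and biodiversity numbers from a posterior
#'
#' Relabels every accepted draw into rare / abundant niches (by expected
#' abundance), computes the Hubbell number of each niche via
#' [theta_hubbell], and reports the component-wise medians across draws:
#' `theta_rare` and `theta_abundant` (for two niches) and the parameter
#' medians after relabelling. An empty posterior yields a flagged result
#' with no theta.
#'
#' @param posterior a `sample_posterior`.
#' @param n_obs observed richness; defaults to the richness stored in the
#'   posterior.
#' @return an object of class `fit_result`.
#' @export
point_estimates <- function(posterior, n_obs = posterior$n_obs) {
  k <- posterior$model_kind
  dr <- posterior$draws
  base <- list(sample_id = posterior$sample_id, model_kind = k,
               n_accepted = posterior$n_accepted,
               acceptance_rate = posterior$acceptance_rate)
  if (nrow(dr) == 0) {
    return(structure(c(base, list(theta = NULL, medians = NULL,
                                  flags = "none-accepted")),
                     class = "fit_result"))
  }
  rel <- relabel_draws(dr, k)
  labs <- switch(k, "single", c("rare", "abundant"),
                 c("rare", "middle", "abundant"))
  th <- sapply(labs, function(lb) {
    x <- rel[[paste0("b_", lb)]] / rel[[paste0("d_", lb)]]
    r <- rel[[paste0("s_", lb)]] / rel[[paste0("b_", lb)]]
    theta_hubbell(x, r, n_obs)
  })
  th <- matrix(th, nrow = nrow(rel))
  theta <- setNames(apply(th, 2, median), paste0("theta_", labs))
  medians <- vapply(rel, median, numeric(1))
  flags <- posterior$flags
  structure(c(base, list(theta = theta, medians = medians, flags = flags,
                         draws_relabelled = rel)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result '%s' (%dNB): %d accepted", x$sample_id,
              x$model_kind, x$n_accepted))
  if (!is.null(x$theta))
    cat(";", paste(sprintf("%s = %.4g", names(x$theta), x$theta),
                   collapse = ", "))
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Two-step hierarchical ABC fit of a dataset
#'
#' Step 1 fits every sample under uninformative priors, caps each sample's
#' accepted draws (default 5), pools them across the dataset (after
#' rare/abundant relabelling) and fits Gamma/Beta hyperpriors. Step 2 refits
#' every sample under the dataset-level prior, so the population informs
#' each individual estimate, and reports per-sample point estimates.
#'
#' @param avs a list of [abundance_vector]s (or an [otu_table], whose
#'   samples are all fitted).
#' @param model_kind number of niches.
#' @param config an [abc_config]; `config$seed` is the root seed from which
#'   each sample and step derives its own stream.
#' @param priors step-1 priors (default uninformative).
#' @return an object of class `two_step_fit`: a `results` data.frame (one
#'   row per sample with theta and diagnostics), the fitted `hyperprior`,
#'   and the per-sample `step1` / `step2` posteriors.
#' @export
two_step_fit <- function(avs, model_kind = 2, config = abc_config(),
                         priors = uninformative_priors(model_kind)) {
  if (inherits(avs, "otu_table"))
    avs <- lapply(avs$sample_ids, function(s) abundance_vector(avs, s))
  if (inherits(avs, "abundance_vector")) avs <- list(avs)
  stopifnot(length(avs) >= 1)
  root <- config$seed %||% sample.int(2147483646L, 1)
  run_step <- function(step, pr) {
    lapply(seq_along(avs), function(i) {
      cfg <- config
      cfg$seed <- derive_seed(root, step, i)
      abc_rejection(avs[[i]], model_kind, pr, cfg)
    })
  }
  step1 <- run_step("step1", priors)
  capped <- lapply(step1, cap_draws, k = config$max_accept_pooling,
                   rule = config$cap_rule, seed = derive_seed(root, "cap"))
  pool_raw <- do.call(rbind, capped)
  if (is.null(pool_raw) || nrow(pool_raw) == 0)
    stop_input("step-1 pool is empty: no sample accepted any parameter set; increase n_sims or loosen the acceptance thresholds")
  pool <- relabel_draws(pool_raw, model_kind)
  if (nrow(pool) < 2)
    stop_input("step-1 pool has a single draw; at least 2 are needed to fit hyperpriors")
  par_kind <- if (!is.null(priors$rate_priors[[1]]$x)) "ratios" else "rates"
  hyper <- fit_hyperpriors(pool, model_kind, parametrization = par_kind)
  step2 <- run_step("step2", hyper)
  fits <- lapply(step2, point_estimates)
  results <- do.call(rbind, lapply(fits, function(f) {
    row <- data.frame(sample_id = f$sample_id, model_kind = f$model_kind,
                      n_accepted = f$n_accepted,
                      acceptance_rate = f$acceptance_rate,
                      flags = paste(f$flags, collapse = ";"))
    th <- f$theta
    labs <- switch(model_kind, "single", c("rare", "abundant"),
                   c("rare", "middle", "abundant"))
    for (lb in paste0("theta_", labs))
      row[[lb]] <- if (!is.null(th)) unname(th[lb]) else NA_real_
    row
  }))
  structure(list(results = results, hyperprior = hyper, pool = pool,
                 step1 = step1, step2 = step2, fits = fits,
                 seed = root, config = config),
            class = "two_step_fit")
}

#' @export
print.two_step_fit <- function(x, ...) {
  cat(sprintf("two_step_fit: %d sample(s), %dNB model\n",
              nrow(x$results), x$results$model_kind[1]))
  print(x$results)
  invisible(x)
}

#' Posterior probability of a model from its acceptance rate
#'
#' The ABC model posterior is approximated by the acceptance rate: accepted
#' draws over proposals, unnormalized across models.
#'
#' @param x a `sample_posterior`, or a count of accepted draws.
#' @param n_sims number of proposals (required when `x` is a count).
#' @return the acceptance-rate posterior probability.
#' @export
model_posterior <- function(x, n_sims = NULL) {
  if (inherits(x, "sample_posterior")) return(x$acceptance_rate)
  if (is.null(n_sims)) stop_input("n_sims is required for a raw count")
  x / n_sims
}

#' Approximate log Bayes factor between two models
#'
#' Natural log of the ratio of the two acceptance-rate posterior
#' probabilities, each floored by a pseudo-count so that zero acceptance
#' cannot produce an infinite ratio. Positive values favour model a.
#'
#' @param p_a,p_b model posterior probabilities (>= 0).
#' @param pseudo_count additive floor (default 1e-7).
#' @return the log ratio.
#' @export
log_bayes_factor <- function(p_a, p_b, pseudo_count = 1e-7) {
  stopifnot(all(p_a >= 0), all(p_b >= 0))
  log((p_a + pseudo_count) / (p_b + pseudo_count))
}
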