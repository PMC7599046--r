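# shared fixtures, built in code

# small OTU table: 3 samples x 4 OTUs
tiny_table <- function() {
  m <- matrix(c(0, 3, 1, 0,
                5, 0, 2, 1,
                1, 1, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("OTU_", 1:4)))
  otu_table(m)
}

# single-niche geometric-like community model (x = 0.5, r = 1, mean 2)
geom_model <- function() mixture_model(niche_ratios(0.5, 1))

# well-separated 2-niche model used across ABC tests (the recovery model)
two_niche_model <- function() default_recovery_model()

# independent ZTNB pmf oracle: direct closed-form log-gamma arithmetic,
# not via dnbinom (the implementation's path)
ztnb_pmf_oracle <- function(n, x, r) {
  exp(n * log(x) + lgamma(n + r) - lgamma(n + 1) - lgamma(r) -
        log((1 - x)^(-r) - 1))
}

# independent trapezoidal ROC AUC
auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!labels] >= t), numeric(1))
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  # ties produce diagonal segments; trapezoid handles them
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# straight-line reference ABC loop: full simulation of every proposal under
# the engine's per-proposal seeds, then the R-level acceptance test
reference_abc_loop <- function(av, model_kind, priors, config) {
  data_bins <- preston_histogram(av)$bin_counts
  n <- config$n_sims
  root <- config$seed
  prop <- with_seed(derive_seed(root, "proposals"),
                    nichenb:::propose_matrix(priors, n))
  seeds <- nichenb:::derive_seed_vec(derive_seed(root, "communities"),
                                     seq_len(n))
  out <- lapply(seq_len(n), function(i) {
    counts <- tryCatch(
      with_seed(seeds[i],
                nichenb:::cpp_sample_community(as.integer(av$n_obs),
                                               prop$x[i, ], prop$r[i, ],
                                               prop$w[i, ])),
      error = function(e) NULL)
    if (is.null(counts)) return(list(accept = FALSE, chi2 = NA_real_))
    r <- acceptance_test(data_bins, preston_histogram(counts),
                         bin_tolerance = config$bin_tolerance,
                         chi2_cdf_cutoff = config$chi2_cdf_cutoff,
                         tolerance_base = config$tolerance_base,
                         df_mode = config$df_mode)
    list(accept = r$accept, chi2 = r$chi2)
  })
  list(accept = vapply(out, `[[`, logical(1), "accept"),
       chi2 = vapply(out, `[[`, numeric(1), "chi2"))
}
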