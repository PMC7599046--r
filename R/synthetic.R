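#' Default two-niche recovery model
#'
#' The reference synthetic community used throughout validation: two well
#' separated niches with expected abundances of about 1.5 (rare, weight
#' 0.7) and 50 (abundant, weight 0.3) reads per species.
#'
#' @return a [mixture_model].
#' @export
default_recovery_model <- function() {
  mixture_model(list(niche_rates(b = 1, d = 3, s = 1),        # x = 1/3, r = 1, mean 1.5
                     niche_rates(b = 0.98, d = 1, s = 0.98)), # x = 0.98, r = 1, mean 50
                weights = c(0.7, 0.3))
}

#' Simulate one community with its generating truth
#'
#' Wraps [sample_community] and records everything a recovery test needs:
#' the generating ratios and the Hubbell numbers implied by them at the
#' simulated richness.
#'
#' @param model a [mixture_model].
#' @param n_obs number of species (default 500, the standard recovery
#'   fixture size).
#' @param seed integer seed.
#' @return a list with `otu` (a one-sample [otu_table]), `av` (the
#'   [abundance_vector]) and `truth` (model, labelled theta values, niche
#'   means).
#' @export
make_community <- function(model, n_obs = 500, seed = NULL) {
  av <- sample_community(model, n_obs, seed = seed)
  est <- theta_estimate(model, n_obs)
  otu <- otu_table(matrix(as.integer(av$counts), nrow = 1,
                          dimnames = list("sample_1", names(av$counts))))
  av$sample_id <- "sample_1"
  list(otu = otu, av = av,
       truth = list(model = model, theta = est$theta,
                    means = est$means, n_obs = n_obs))
}

#' Specification of a synthetic cohort
#'
#' Defines the statistical structure of a simulated study population: ages,
#' sex, pseudo-dataset membership, read depth, the age trajectories of the
#' niche parameters (through which biodiversity depends on age), and the
#' noise models for the observed diversity values and elderly health
#' scores.
#'
#' @param n_subjects number of subjects.
#' @param age_range sampled uniformly.
#' @param n_datasets number of balanced pseudo-datasets.
#' @param x_rare,x_abundant birth/death ratio of each niche (constant with
#'   age).
#' @param r_rare,r_abundant functions of age returning the
#'   immigration/birth ratio of each niche; defaults give a mild increase
#'   of biodiversity with age. Note the direction theta moves with r
#'   depends on x: at small r, theta increases with r iff
#'   `log(1/(1-x)) < 0.5772` (x below ~0.44), so the rare niche default
#'   increases r with age while the abundant niche (x = 0.98) decreases
#'   it.
#' @param weight_rare mixture weight of the rare niche.
#' @param n_obs species richness of every simulated community.
#' @param subject_r_sdlog subject-level lognormal jitter on both r
#'   trajectories (inter-individual variability beyond age).
#' @param read_meanlog,read_sdlog lognormal read-depth law (metadata only:
#'   the community is not resampled unless `resample_reads`).
#' @param resample_reads if TRUE, counts are multinomially resampled to the
#'   drawn read depth.
#' @param p_female probability of sex = 1.
#' @param index_noise_sd sd of Gaussian observation noise added to the true
#'   theta values, in units of their cohort sd (absolute 1 if the truth is
#'   constant).
#' @param score_slope strength of the linear dependence of elderly health
#'   scores on standardized theta_rare.
#' @param score_noise_sd sd of the health-score noise, in units of each
#'   score's slope scale; 0 makes scores and residence deterministic.
#' @param seed root seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 200,
                        age_range = c(20, 90),
                        n_datasets = 3,
                        x_rare = 1 / 3,
                        x_abundant = 0.98,
                        r_rare = function(age) 0.05 + 0.002 * age,
                        r_abundant = function(age) 0.2 - 0.0012 * age,
                        weight_rare = 0.7,
                        n_obs = 200,
                        subject_r_sdlog = 0,
                        read_meanlog = log(2e4),
                        read_sdlog = 0.4,
                        resample_reads = FALSE,
                        p_female = 0.5,
                        index_noise_sd = 0.3,
                        score_slope = 2,
                        score_noise_sd = 0.5,
                        seed = NULL) {
  stopifnot(n_subjects >= 2, n_datasets >= 1, is.function(r_rare),
            is.function(r_abundant), x_rare > 0, x_rare < 1,
            x_abundant > 0, x_abundant < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

# evaluate and validate the niche trajectories at each subject's age
eval_trajectory <- function(fn, age, x, what) {
  r <- fn(age)
  r <- rep_len(r, length(age))
  bad <- which(!is.finite(r) | r <= 0)
  if (length(bad))
    stop_input("%s trajectory leaves the valid domain at age %.3g", what, age[bad[1]])
  r
}

#' Generate a synthetic cohort with known biodiversity truth
#'
#' Draws ages, sex, dataset labels and read depths per the spec,
#' instantiates a two-niche model for every subject from the age
#' trajectories, samples a community per subject, and records the true
#' Hubbell numbers alongside noisy observed versions and the classical
#' diversity indices of the sampled communities.
#'
#' @param spec a [cohort_spec].
#' @return a list with `otu` (an [otu_table], one row per subject),
#'   `cohort` (metadata + observed diversity) and `truth` (per-subject
#'   generating parameters and exact theta values).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  root <- spec$seed %||% sample.int(2147483646L, 1)
  meta <- with_seed(derive_seed(root, "meta"), {
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- rbinom(n, 1, spec$p_female)
    dataset <- sample(rep_len(paste0("dataset_", seq_len(spec$n_datasets)), n))
    reads <- round(rlnorm(n, spec$read_meanlog, spec$read_sdlog))
    jit_r <- if (spec$subject_r_sdlog > 0) rlnorm(n, 0, spec$subject_r_sdlog) else rep(1, n)
    jit_a <- if (spec$subject_r_sdlog > 0) rlnorm(n, 0, spec$subject_r_sdlog) else rep(1, n)
    list(age = age, sex = sex, dataset = dataset, reads = reads,
         jit_r = jit_r, jit_a = jit_a)
  })
  r_rare <- eval_trajectory(spec$r_rare, meta$age, spec$x_rare, "rare-niche r") * meta$jit_r
  r_ab <- eval_trajectory(spec$r_abundant, meta$age, spec$x_abundant, "abundant-niche r") * meta$jit_a
  theta_rare_true <- theta_hubbell(spec$x_rare, r_rare, spec$n_obs)
  theta_ab_true <- theta_hubbell(spec$x_abundant, r_ab, spec$n_obs)

  counts <- matrix(0L, n, spec$n_obs,
                   dimnames = list(paste0("subject_", seq_len(n)),
                                   paste0("OTU_", seq_len(spec$n_obs))))
  div <- vector("list", n)
  for (i in seq_len(n)) {
    model <- mixture_model(list(niche_ratios(spec$x_rare, r_rare[i]),
                                niche_ratios(spec$x_abundant, r_ab[i])),
                           c(spec$weight_rare, 1 - spec$weight_rare))
    av <- sample_community(model, spec$n_obs,
                           seed = derive_seed(root, "community", i))
    cts <- as.numeric(av$counts)
    if (spec$resample_reads) {
      cts <- with_seed(derive_seed(root, "resample", i),
                       as.numeric(stats::rmultinom(1, meta$reads[i],
                                                   cts / sum(cts))))
      cts <- pmax(cts, 0)
      keep_pos <- cts > 0
      if (!any(keep_pos)) cts[1] <- 1
    }
    counts[i, seq_along(cts)] <- as.integer(cts)
    div[[i]] <- diversity_profile(cts[cts > 0])
  }
  noise_scale <- function(v) spec$index_noise_sd * (if (sd(v) > 0) sd(v) else 1)
  obs_noise <- with_seed(derive_seed(root, "obsnoise"), {
    list(r = rnorm(n, 0, noise_scale(theta_rare_true)),
         a = rnorm(n, 0, noise_scale(theta_ab_true)))
  })
  cohort <- data.frame(sample_id = rownames(counts),
                       age = meta$age, sex = meta$sex, dataset = meta$dataset,
                       total_reads = meta$reads,
                       theta_rare = theta_rare_true + obs_noise$r,
                       theta_abundant = theta_ab_true + obs_noise$a,
                       do.call(rbind, div))
  truth <- data.frame(sample_id = rownames(counts),
                      age = meta$age,
                      r_rare = r_rare, r_abundant = r_ab,
                      x_rare = spec$x_rare, x_abundant = spec$x_abundant,
                      theta_rare_true = theta_rare_true,
                      theta_abundant_true = theta_ab_true)
  list(otu = otu_table(counts), cohort = cohort, truth = truth, seed = root)
}

#' Generate a synthetic elderly cohort with health scores
#'
#' Builds on [make_cohort] (ages restricted to old age by default) and adds
#' Barthel, MMSE and FIM scores as linear functions of the standardized
#' true theta_rare plus Gaussian noise, clipped into their clinical ranges
#' (Barthel 0-20, MMSE 0-30, FIM 18-126), and a residence setting whose
#' odds of being Community increase with biodiversity. With
#' `score_noise_sd = 0` scores and residence are deterministic functions of
#' the truth. True health labels follow [classify_health] on the generated
#' scores.
#'
#' @param spec a [cohort_spec]; the default age range is overridden to
#'   65-100 unless `age_range` was set explicitly above 60.
#' @return the [make_cohort] list with the cohort extended by `barthel`,
#'   `mmse`, `fim`, `residence`, `label` and `pc_score` columns.
#' @export
make_elderly_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$age_range[1] < 60) spec$age_range <- c(65, 100)
  out <- make_cohort(spec)
  n <- spec$n_subjects
  root <- out$seed
  z <- out$truth$theta_rare_true
  z <- if (sd(z) > 0) (z - mean(z)) / sd(z) else rep(0, n)
  ns <- spec$score_noise_sd
  noise <- with_seed(derive_seed(root, "scores"), {
    list(b = rnorm(n), m = rnorm(n), f = rnorm(n),
         res = stats::rlogis(n))
  })
  sl <- spec$score_slope
  # threshold crossings staggered in z so labels split around z = 0
  barthel <- pmin(pmax(15 + sl * 2 * (z + 0.5) + ns * 2 * noise$b, 0), 20)
  mmse <- pmin(pmax(24 + sl * 3 * (z + 0.2) + ns * 3 * noise$m, 0), 30)
  fim <- pmin(pmax(100 + sl * 10 * (z - 0.2) + ns * 10 * noise$f, 18), 126)
  eta <- sl * z + ns * noise$res
  residence <- ifelse(eta >= 0, "Community", "Long-stay")
  hl <- classify_health(barthel, mmse, fim, residence)
  out$cohort$barthel <- barthel
  out$cohort$mmse <- mmse
  out$cohort$fim <- fim
  out$cohort$residence <- residence
  out$cohort$label <- hl$label
  res_bin <- as.integer(residence %in% c("Community", "Day-Hospital"))
  if (sd(barthel) > 0 && sd(mmse) > 0 && sd(fim) > 0 && sd(res_bin) > 0) {
    pc <- health_pc_score(cbind(barthel = barthel, mmse = mmse, fim = fim,
                                residence = res_bin))
    out$cohort$pc_score <- pc$score
    out$pc <- pc
  }
  out$truth$health_z <- z
  out
}
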