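#' Remove subjects with outlier sequencing depth
#'
#' Drops subjects whose total read count has an absolute z-score above the
#' threshold. The z-scores are computed once on the input; removal is not
#' iterated.
#'
#' @param cohort data.frame with a `total_reads` column.
#' @param z_threshold z-score cutoff (default 4).
#' @return the filtered cohort; attribute `removed` holds the dropped row
#'   indices.
#' @export
remove_read_outliers <- function(cohort, z_threshold = 4) {
  stopifnot(is.data.frame(cohort), "total_reads" %in% names(cohort),
            nrow(cohort) >= 2)
  reads <- cohort$total_reads
  s <- sd(reads)
  if (s == 0) {
    warning("total_reads has zero variance; no outliers removed")
    out <- cohort
    attr(out, "removed") <- integer(0)
    return(out)
  }
  z <- abs(reads - mean(reads)) / s
  drop <- which(z > z_threshold)
  out <- if (length(drop)) cohort[-drop, , drop = FALSE] else cohort
  attr(out, "removed") <- drop
  out
}

#' Standardize values within each dataset
#'
#' Centers and scales to unit variance separately per dataset label, the
#' normalization applied to each diversity index before pooling datasets in
#' the age-trend model.
#'
#' @param values numeric vector.
#' @param dataset_labels factor or character vector of the same length.
#' @return the standardized vector.
#' @export
standardize_within_dataset <- function(values, dataset_labels) {
  stopifnot(length(values) == length(dataset_labels))
  out <- numeric(length(values))
  for (g in unique(dataset_labels)) {
    i <- which(dataset_labels == g)
    if (length(i) < 2) stop_input("dataset '%s' has a single subject; cannot standardize", g)
    s <- sd(values[i])
    if (s == 0) stop_input("dataset '%s' has constant values; cannot standardize", g)
    out[i] <- (values[i] - mean(values[i])) / s
  }
  out
}

#' Adjust a response for covariates by OLS residualization
#'
#' Regresses `y` on the covariates (plus intercept) and returns the
#' residuals, the adjustment applied to biodiversity values before group
#' hypothesis tests.
#'
#' @param y numeric response.
#' @param covariates numeric matrix or data.frame of covariates.
#' @return residual vector (mean zero).
#' @export
adjust_for_covariates <- function(y, covariates) {
  X <- as.matrix(covariates)
  stopifnot(length(y) == nrow(X))
  Xi <- cbind(`(Intercept)` = 1, X)
  q <- qr(Xi)
  if (q$rank < ncol(Xi)) {
    bad <- colnames(Xi)[setdiff(seq_len(ncol(Xi)), q$pivot[seq_len(q$rank)])]
    stop_input("covariate matrix is rank deficient (collinear: %s)",
               paste(bad, collapse = ", "))
  }
  as.numeric(qr.resid(q, y))
}

#' Natural cubic spline basis for age
#'
#' A natural cubic spline basis with `df` degrees of freedom: piecewise
#' cubic, continuous up to the second derivative, and linear beyond the
#' boundary knots. Boundary knots sit at the age range, interior knots at
#' equally spaced age quantiles (the `splines::ns` convention).
#'
#' @param age numeric vector of ages.
#' @param df degrees of freedom (default 3).
#' @param knots optional explicit interior knots.
#' @param boundary_knots optional boundary knots (used to evaluate the same
#'   basis on new data).
#' @return a basis matrix with `df` columns; knots are attached as
#'   attributes.
#' @export
natural_spline_basis <- function(age, df = 3, knots = NULL,
                                 boundary_knots = range(age)) {
  if (length(unique(age)) < df + 2)
    stop_input("need at least df + 2 = %d distinct ages (got %d)",
               df + 2, length(unique(age)))
  if (is.null(knots)) {
    n_interior <- df - 1
    probs <- seq(0, 1, length.out = n_interior + 2)[-c(1, n_interior + 2)]
    knots <- if (length(probs)) quantile(age, probs, names = FALSE) else NULL
  }
  B <- splines::ns(age, knots = knots, Boundary.knots = boundary_knots)
  colnames(B) <- paste0("spline", seq_len(ncol(B)))
  B
}

#' Age-trend spline regression with per-dataset deviations
#'
#' Fits the standardized diversity index on a natural cubic spline of age
#' (df = 3), a sum-to-zero (deviation) coded dataset factor, its
#' interactions with the spline columns, and the sex and standardized-reads
#' covariates. With deviation coding the uncontrasted spline terms estimate
#' the grand mean of the per-dataset effects, so the global trend is not
#' driven by the sample size of any one dataset; the interaction terms are
#' each dataset's deviation from that trend.
#'
#' @param cohort data.frame with columns `age`, `sex` (0/1), `dataset`,
#'   `total_reads` and the index column.
#' @param index_name column to analyse.
#' @param df spline degrees of freedom (default 3).
#' @param standardize standardize the index within dataset first (default
#'   TRUE; set FALSE if already standardized).
#' @return an object of class `spline_fit`: `global` (intercept and spline
#'   coefficients with t-test p-values), `deviations` (per dataset x term),
#'   `covariates` (sex, standardized reads), the underlying `lm` fit and
#'   the basis attributes.
#' @export
fit_age_trend <- function(cohort, index_name, df = 3, standardize = TRUE) {
  stopifnot(all(c("age", "sex", "dataset", "total_reads", index_name)
                %in% names(cohort)))
  ds <- factor(cohort$dataset)
  if (nlevels(ds) < 2) stop_input("need at least 2 datasets")
  y <- cohort[[index_name]]
  if (standardize) y <- standardize_within_dataset(y, ds)
  B <- natural_spline_basis(cohort$age, df = df)
  reads_std <- if (sd(cohort$total_reads) > 0)
    as.numeric(scale(cohort$total_reads)) else NULL
  sex_col <- if (sd(cohort$sex) > 0) cohort$sex else NULL
  if (is.null(reads_std))
    warning("total_reads is constant; reads covariate dropped")
  if (is.null(sex_col))
    warning("sex is constant; sex covariate dropped")
  L <- nlevels(ds)
  C <- contr.sum(L)                     # L x (L-1) deviation contrasts
  D <- C[as.integer(ds), , drop = FALSE]
  colnames(D) <- paste0("ds", seq_len(L - 1))
  inter <- do.call(cbind, lapply(seq_len(df), function(j) {
    M <- D * B[, j]
    colnames(M) <- paste0("ds", seq_len(L - 1), "_spline", j)
    M
  }))
  X <- cbind(B, D, inter)
  if (!is.null(sex_col)) X <- cbind(X, sex = sex_col)
  if (!is.null(reads_std)) X <- cbind(X, reads = reads_std)
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- lm(y ~ ., data = dat)
  cf <- coef(fit)
  if (anyNA(cf)) {
    warning("rank-deficient design: some deviation terms dropped")
    keep <- !is.na(cf)
    dat2 <- dat[, c(TRUE, keep[-1]), drop = FALSE]
    fit <- lm(y ~ ., data = dat2)
    cf <- coef(fit)
  }
  V <- vcov(fit)
  rdf <- fit$df.residual
  est_tab <- function(contrast) {
    # contrast is a named vector over the coefficient names
    v <- setNames(numeric(length(cf)), names(cf))
    v[names(contrast)] <- contrast
    est <- sum(v * cf)
    se <- sqrt(drop(t(v) %*% V %*% v))
    t <- est / se
    c(estimate = est, se = se, t = t, p = 2 * pt(-abs(t), rdf))
  }
  gl_terms <- c("(Intercept)", paste0("spline", seq_len(df)))
  global <- t(sapply(gl_terms, function(tm) est_tab(setNames(1, tm))))
  # per-dataset deviations: for level l < L the contrast is the unit vector
  # on dsl (and dsl:splinej); for level L it is minus the sum of the others
  dev_rows <- list()
  terms_of <- function(l, j) {
    if (j == 0) paste0("ds", l) else paste0("ds", l, "_spline", j)
  }
  for (l in seq_len(L)) {
    for (j in 0:df) {
      if (l < L) {
        ctr <- setNames(1, terms_of(l, j))
      } else {
        nms <- vapply(seq_len(L - 1), terms_of, character(1), j = j)
        ctr <- setNames(rep(-1, L - 1), nms)
      }
      ctr <- ctr[names(ctr) %in% names(cf)]
      if (!length(ctr)) next
      row <- est_tab(ctr)
      dev_rows[[length(dev_rows) + 1]] <-
        data.frame(dataset = levels(ds)[l],
                   term = if (j == 0) "(Intercept)" else paste0("spline", j),
                   estimate = row["estimate"], se = row["se"],
                   t = row["t"], p = row["p"], row.names = NULL)
    }
  }
  deviations <- do.call(rbind, dev_rows)
  cov_terms <- intersect(c("sex", "reads"), names(cf))
  covariates <- if (length(cov_terms))
    t(sapply(cov_terms, function(tm) est_tab(setNames(1, tm)))) else NULL
  structure(list(global = global, deviations = deviations,
                 covariates = covariates, fit = fit,
                 index = index_name, df = df,
                 knots = attr(B, "knots"),
                 boundary_knots = attr(B, "Boundary.knots")),
            class = "spline_fit")
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf("spline_fit of '%s' (df = %d)\nGlobal model:\n", x$index, x$df))
  print(round(x$global, 4))
  cat("Covariates:\n")
  print(round(x$covariates, 4))
  invisible(x)
}

#' Choose the spline degrees of freedom by information criteria
#'
#' Fits the age-trend model over a grid of spline degrees of freedom and
#' reports AIC and BIC for each; the chosen df minimizes AIC, with BIC as
#' tie-break.
#'
#' @inheritParams fit_age_trend
#' @param df_grid candidate degrees of freedom.
#' @return a list with `chosen_df` and the `criteria` table.
#' @export
select_spline_df <- function(cohort, index_name, df_grid = 1:6,
                             standardize = TRUE) {
  stopifnot(length(df_grid) >= 1)
  crit <- t(sapply(df_grid, function(d) {
    f <- fit_age_trend(cohort, index_name, df = d, standardize = standardize)
    c(df = d, AIC = AIC(f$fit), BIC = BIC(f$fit))
  }))
  crit <- as.data.frame(crit)
  best <- order(crit$AIC, crit$BIC)[1]
  list(chosen_df = df_grid[best], criteria = crit)
}

#' Pairwise Mann-Whitney group comparisons
#'
#' Two-sided Mann-Whitney U tests for every unordered pair of groups,
#' applied to covariate-adjusted values. The exact null distribution is
#' used when the smaller group has at most 8 subjects and there are no
#' ties; otherwise the normal approximation with tie (midrank) correction.
#'
#' @param values numeric vector (typically residuals from
#'   [adjust_for_covariates]).
#' @param group_labels factor or character vector.
#' @return a data.frame with columns `group1`, `group2`, `p`.
#' @export
pairwise_group_test <- function(values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) < 2) stop_input("need at least 2 groups")
  split_vals <- split(values, g)
  sizes <- lengths(split_vals)
  if (any(sizes < 2)) stop_input("every group needs at least 2 subjects")
  pairs <- utils::combn(levels(g), 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- split_vals[[pr[1]]]; b <- split_vals[[pr[2]]]
    has_ties <- anyDuplicated(c(a, b)) > 0
    use_exact <- min(length(a), length(b)) <= 8 && !has_ties
    p <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                  correct = TRUE)$p.value)
    data.frame(group1 = pr[1], group2 = pr[2], p = p)
  })
  do.call(rbind, rows)
}
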