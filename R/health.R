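#' Classify elderly health status from clinical scores
#'
#' One point is awarded for each of: Barthel score >= 15, MMSE score >= 24,
#' FIM score >= 100, and residence in Community or Day-Hospital. A subject
#' is healthy when the total is at least 3.
#'
#' @param barthel,mmse,fim numeric clinical scores (vectors recycle
#'   together).
#' @param residence character: one of `"Community"`, `"Day-Hospital"`,
#'   `"Rehabilitation"`, `"Long-stay"` (only the Community / Day-Hospital
#'   dichotomy matters).
#' @return a data.frame with the four binary `point_*` columns, `total`
#'   (0-4) and `label` (`"healthy"` / `"unhealthy"`).
#' @export
classify_health <- function(barthel, mmse, fim, residence) {
  n <- max(length(barthel), length(mmse), length(fim), length(residence))
  barthel <- rep_len(barthel, n); mmse <- rep_len(mmse, n)
  fim <- rep_len(fim, n); residence <- rep_len(residence, n)
  if (anyNA(barthel) || anyNA(mmse) || anyNA(fim) || anyNA(residence))
    stop_input("all four health fields are required (no missing values)")
  pts <- cbind(point_barthel = as.integer(barthel >= 15),
               point_mmse = as.integer(mmse >= 24),
               point_fim = as.integer(fim >= 100),
               point_residence = as.integer(residence %in%
                                              c("Community", "Day-Hospital")))
  total <- rowSums(pts)
  data.frame(pts, total = total,
             label = ifelse(total >= 3, "healthy", "unhealthy"))
}

#' First-principal-component health score
#'
#' Standardizes the health-score matrix (Barthel, MMSE, FIM and a binary
#' residence indicator: 1 for Community or Day-Hospital) and projects the
#' subjects on the first principal axis. The sign is fixed so that a higher
#' score means healthier (positive loading on the first column, Barthel).
#'
#' @param score_matrix numeric matrix or data.frame, subjects x scores,
#'   Barthel first.
#' @return a list with `score` (per-subject PC1 projection),
#'   `variance_explained` (fraction per component) and `loadings`.
#' @export
health_pc_score <- function(score_matrix) {
  X <- as.matrix(score_matrix)
  stopifnot(nrow(X) >= 2)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop_input("constant column(s) in the score matrix: %s",
               paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (pc$rotation[1, 1] < 0) {
    score <- -score
    pc$rotation <- -pc$rotation
  }
  list(score = as.numeric(score),
       variance_explained = pc$sdev^2 / sum(pc$sdev^2),
       loadings = pc$rotation)
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' `AUC = (sum of positive-class midranks - n1 (n1 + 1) / 2) / (n1 n0)`,
#' identical to trapezoidal integration of the ROC curve.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels logical or 0/1 vector of true classes.
#' @return the AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop_input("both classes must be present")
  r <- rank(scores)             # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out health prediction from biodiversity
#'
#' For each subject an ordinary least-squares model of the first-PC health
#' score on the chosen predictors is fitted on the remaining subjects and
#' used to predict the held-out score. Predictions are dichotomized at the
#' midpoint of the true healthy / unhealthy class means of the PC score,
#' and the AUC of the continuous predictions against the true labels is
#' computed by the rank formulation.
#'
#' @param cohort data.frame containing the predictors, the clinical fields
#'   (`barthel`, `mmse`, `fim`, `residence`) or a precomputed `pc_score`
#'   and `label`.
#' @param predictor_names character vector of predictor columns.
#' @return an object of class `loo_prediction`: per-subject `predicted`
#'   scores, `true_score`, `true_label`, `predicted_label`, `threshold`
#'   and `auc`.
#' @export
loo_predict_health <- function(cohort, predictor_names) {
  stopifnot(all(predictor_names %in% names(cohort)))
  n <- nrow(cohort)
  if (n < 3) stop_input("need at least 3 subjects")
  if (!"pc_score" %in% names(cohort)) {
    res_bin <- as.integer(cohort$residence %in% c("Community", "Day-Hospital"))
    pc <- health_pc_score(cbind(barthel = cohort$barthel, mmse = cohort$mmse,
                                fim = cohort$fim, residence = res_bin))
    cohort$pc_score <- pc$score
  }
  if (!"label" %in% names(cohort)) {
    cohort$label <- classify_health(cohort$barthel, cohort$mmse, cohort$fim,
                                    cohort$residence)$label
  }
  X <- as.matrix(cohort[, predictor_names, drop = FALSE])
  y <- cohort$pc_score
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- cbind(1, X[-i, , drop = FALSE])
    if (qr(Xi)$rank < ncol(Xi))
      stop_input("rank-deficient predictors in the fold holding out subject %d", i)
    beta <- qr.coef(qr(Xi), y[-i])
    pred[i] <- sum(c(1, X[i, ]) * beta)
  }
  healthy <- cohort$label == "healthy"
  if (!any(healthy) || all(healthy))
    stop_input("both health classes must be present")
  threshold <- (mean(y[healthy]) + mean(y[!healthy])) / 2
  structure(list(predicted = pred, true_score = y,
                 true_label = cohort$label,
                 predicted_label = ifelse(pred >= threshold,
                                          "healthy", "unhealthy"),
                 threshold = threshold,
                 auc = auc_rank(pred, healthy)),
            class = "loo_prediction")
}

#' @export
print.loo_prediction <- function(x, ...) {
  cat(sprintf("loo_prediction: %d subjects, AUC = %.3f\n",
              length(x$predicted), x$auc))
  invisible(x)
}
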