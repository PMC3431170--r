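#' Stepwise selection configuration
#'
#' Defaults follow the published thresholds: a candidate feature enters when
#' its partial-F p-value is below 0.10 and an included feature is removed
#' when its p-value rises above 0.15. `p_enter < p_remove` is enforced to
#' prevent enter/remove cycling.
#'
#' @param p_enter Entry critical probability.
#' @param p_remove Removal critical probability.
#' @param feature_pool Which feature family to consider: `"all"`,
#'   `"morphology"` (p1..p8 columns) or `"texture"` (the 13 GLCM columns).
#' @param max_steps Safety cap on stepwise iterations.
#' @return A list of class `stepwise_config`.
#' @export
stepwise_config <- function(p_enter = 0.10, p_remove = 0.15,
                            feature_pool = c("all", "morphology", "texture"),
                            max_steps = 50L) {
  stopifnot(p_enter > 0, p_remove < 1, p_enter < p_remove)
  structure(list(p_enter = p_enter, p_remove = p_remove,
                 feature_pool = match.arg(feature_pool),
                 max_steps = as.integer(max_steps)),
            class = "stepwise_config")
}

texture_feature_names <- function() {
  c("angular_second_moment", "contrast", "correlation",
    "inverse_difference_moment", "sum_average", "sum_variance",
    "sum_entropy", "entropy", "difference_average", "difference_variance",
    "difference_entropy", "info_measure_corr_1", "info_measure_corr_2")
}
morphology_feature_names <- function() {
  c("p1_compactness", "p2_spiculation", "p3_extent", "p4_elongation",
    "p5_solidity", "p6_circularity", "p7_radial_entropy", "p8_eccentricity")
}

pool_columns <- function(table, pool) {
  cols <- switch(pool,
                 all = c(texture_feature_names(), morphology_feature_names()),
                 texture = texture_feature_names(),
                 morphology = morphology_feature_names())
  intersect(cols, names(table))
}

check_cohort <- function(table, label_col = "label") {
  stopifnot(is.data.frame(table), label_col %in% names(table))
  lab <- table[[label_col]]
  if (length(unique(lab)) != 2L)
    stop("cohort must contain exactly two classes", call. = FALSE)
  if (min(table(lab)) < 2L)
    stop("each class needs at least two lesions", call. = FALSE)
  if (anyNA(table)) stop("cohort contains missing values", call. = FALSE)
  invisible(table)
}

## Wilks' lambda of a feature subset for a two-group design:
## det(W)/det(T) over the within-group and total SSCP matrices.
wilks_lambda <- function(X, g) {
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  W <- matrix(0, ncol(X), ncol(X))
  for (lv in unique(g)) {
    Xi <- X[g == lv, , drop = FALSE]
    W <- W + crossprod(scale(Xi, center = TRUE, scale = FALSE))
  }
  dT <- det(Tm)
  if (!is.finite(dT) || dT <= 0) return(NA_real_)
  lam <- det(W) / dT
  if (!is.finite(lam) || lam <= 0) return(NA_real_)
  lam
}

## Partial-F p-value for adding feature `cand` to set `sel` (two groups):
## F = (n - 2 - q) * (Lambda_q / Lambda_{q+1} - 1), df (1, n - 2 - q).
partial_f_p <- function(table, sel, cand, lambda_sel) {
  n <- nrow(table)
  q <- length(sel)
  df2 <- n - 2 - q
  if (df2 < 1) return(NA_real_)
  lam_new <- wilks_lambda(as.matrix(table[, c(sel, cand), drop = FALSE]),
                          table$label)
  if (is.na(lam_new) || lam_new > lambda_sel + 1e-12) return(NA_real_)
  Fv <- df2 * (lambda_sel / lam_new - 1)
  if (!is.finite(Fv) || Fv < 0) return(NA_real_)
  stats::pf(Fv, 1, df2, lower.tail = FALSE)
}

#' Stepwise feature selection by Wilks' lambda partial F
#'
#' Classic forward-entry/backward-removal discriminant selection for two
#' groups. At each step the candidate with the smallest partial-F p-value
#' enters if p < `p_enter`; included features are then retested and removed
#' when their p-value given the rest of the set exceeds `p_remove`. Ties
#' break by column order, so the procedure is deterministic and invariant
#' to row order. A feature whose addition leaves Wilks' lambda unchanged
#' (e.g. a duplicated column) has partial F of 0 and can never enter.
#'
#' @param table Data frame with feature columns and a `label` column with
#'   two classes.
#' @param config A [stepwise_config()].
#' @return Character vector of selected feature names, in entry order.
#' @export
stepwise_select <- function(table, config = stepwise_config()) {
  check_cohort(table)
  pool <- pool_columns(table, config$feature_pool)
  if (!length(pool)) stop("empty feature pool", call. = FALSE)
  sel <- character(0)
  for (step in seq_len(config$max_steps)) {
    changed <- FALSE
    lambda_sel <- if (length(sel))
      wilks_lambda(as.matrix(table[, sel, drop = FALSE]), table$label) else 1
    if (is.na(lambda_sel))
      stop(sprintf("singular within-group covariance for features: %s",
                   paste(sel, collapse = ", ")), call. = FALSE)
    cands <- setdiff(pool, sel)
    if (length(cands)) {
      pv <- vapply(cands, function(cd) partial_f_p(table, sel, cd, lambda_sel),
                   0)
      ok <- which(!is.na(pv) & pv < config$p_enter)
      if (length(ok)) {
        sel <- c(sel, cands[ok[which.min(pv[ok])]])
        changed <- TRUE
      }
    }
    # removal pass
    repeat {
      if (length(sel) < 2L) break
      pv_out <- vapply(sel, function(s) {
        rest <- setdiff(sel, s)
        lam_rest <- wilks_lambda(as.matrix(table[, rest, drop = FALSE]),
                                 table$label)
        partial_f_p(table, rest, s, lam_rest)
      }, 0)
      worst <- which.max(pv_out)
      if (!is.na(pv_out[worst]) && pv_out[worst] > config$p_remove) {
        sel <- setdiff(sel, sel[worst])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sel
}

#' Fit a two-class Fisher linear discriminant
#'
#' Computes the Fisher discriminant direction
#' \eqn{w = \Sigma_{pooled}^{-1} (\mu_{mal} - \mu_{ben})} over the given
#' features, with the intercept placing the decision boundary at the
#' midpoint of the projected class means (equal priors). Scores are
#' \eqn{w \cdot x + c}; positive scores favor the malignant class.
#'
#' @param table Cohort data frame with a two-level `label` column; the
#'   level `"malignant"` (or, failing that, the second sorted level) is the
#'   positive class.
#' @param features Character vector of feature columns (non-empty).
#' @return An object of class `lesion_lda` with elements
#'   `features`, `weights`, `intercept`, `class_means`,
#'   `pooled_covariance`, `positive_class`.
#' @export
fit_lda <- function(table, features) {
  check_cohort(table)
  stopifnot(length(features) >= 1, all(features %in% names(table)))
  lv <- sort(unique(as.character(table$label)))
  pos <- if ("malignant" %in% lv) "malignant" else lv[2]
  neg <- setdiff(lv, pos)
  X <- as.matrix(table[, features, drop = FALSE])
  Xp <- X[table$label == pos, , drop = FALSE]
  Xn <- X[table$label == neg, , drop = FALSE]
  mu_p <- colMeans(Xp); mu_n <- colMeans(Xn)
  Sp <- (crossprod(scale(Xp, scale = FALSE)) + crossprod(scale(Xn, scale = FALSE))) /
    (nrow(X) - 2)
  w <- tryCatch(solve(Sp, mu_p - mu_n),
                error = function(e) stop("singular pooled covariance", call. = FALSE))
  intercept <- -sum(w * (mu_p + mu_n) / 2)
  structure(list(features = features, weights = w, intercept = intercept,
                 class_means = rbind(positive = mu_p, negative = mu_n),
                 pooled_covariance = Sp, positive_class = pos,
                 negative_class = neg),
            class = "lesion_lda")
}

#' @export
predict.lesion_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  as.numeric(X %*% object$weights + object$intercept)
}

#' Leave-one-out cross-validated discriminant scores
#'
#' For each lesion, removes it, runs stepwise selection and the
#' discriminant fit on the remainder, and scores the held-out lesion.
#' Feature selection inside each fold (`selection = "per_fold"`, the
#' default) keeps selection from leaking the held-out label; with
#' `selection = "full_data"` the subset is selected once on the whole
#' cohort and only the discriminant fit is cross-validated. A fold whose
#' selection is empty scores the held-out lesion 0 (an uninformative tie).
#'
#' @param table Cohort data frame with feature columns and `label`.
#' @param config A [stepwise_config()].
#' @param selection Where stepwise selection runs: `"per_fold"` or
#'   `"full_data"`.
#' @return A tibble with one row per lesion: `id`, `label`, `score`,
#'   `n_selected`.
#' @export
loocv_scores <- function(table, config = stepwise_config(),
                         selection = c("per_fold", "full_data")) {
  check_cohort(table)
  selection <- match.arg(selection)
  n <- nrow(table)
  stopifnot(n >= 4)
  full_sel <- if (selection == "full_data") stepwise_select(table, config)
  rows <- purrr::map(seq_len(n), function(i) {
    train <- table[-i, , drop = FALSE]
    if (length(unique(train$label)) < 2L)
      stop("a fold has a single-class training set", call. = FALSE)
    sel <- if (selection == "per_fold") stepwise_select(train, config) else full_sel
    score <- if (length(sel)) {
      fit <- fit_lda(train, sel)
      predict(fit, table[i, , drop = FALSE])
    } else 0
    tibble::tibble(id = i, label = as.character(table$label[i]),
                   score = score, n_selected = length(sel))
  })
  dplyr::bind_rows(rows)
}
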