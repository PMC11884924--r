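#' Label clinical outcomes from CRS-R scores
#'
#' A subject is labelled improved iff the follow-up CRS-R exceeds baseline by
#' at least 3 points (boundary inclusive). Scores must lie on the 0-23
#' scale.
#'
#' @param crs_r data frame with columns `subject`, `crs_r_baseline`,
#'   `crs_r_followup`.
#' @return The input with an added/replaced logical `improved` column.
#' @export
label_outcomes <- function(crs_r) {
  b <- crs_r$crs_r_baseline; f <- crs_r$crs_r_followup
  if (anyNA(b) || anyNA(f)) stop("both CRS-R scores must be present")
  if (any(b < 0 | b > 23 | f < 0 | f > 23))
    stop("CRS-R scores must lie in [0, 23]")
  crs_r$improved <- (f - b) >= 3
  crs_r
}

#' Train a linear support-vector classifier
#'
#' L2-regularized hinge-loss (soft-margin) linear SVM solved by dual
#' coordinate descent with a fixed sweep order, so the fit is deterministic
#' given the data and `C`. The bias is handled through an augmented constant
#' feature (and therefore lightly regularized, the usual choice for this
#' solver). The decision function is the affine score `w . x + b`.
#'
#' @param features numeric matrix (subjects x features).
#' @param labels logical or two-level vector; `TRUE`/second level is the
#'   positive class.
#' @param C soft-margin cost (default 1).
#' @param max_sweeps,tol solver controls.
#' @return An object of class `linear_svm` with `w`, `b`, `levels`.
#' @export
train_svm <- function(features, labels, C = 1, max_sweeps = 2000, tol = 1e-8) {
  X <- as.matrix(features)
  y <- if (is.logical(labels)) labels else labels == sort(unique(labels))[2]
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  if (min(table(y)) < 2L) stop("need at least 2 subjects per class")
  yy <- ifelse(y, 1, -1)
  Xa <- cbind(X, bias = 1)
  n <- nrow(Xa); d <- ncol(Xa)
  qii <- rowSums(Xa^2)
  alpha <- numeric(n)
  w <- numeric(d)
  for (s in seq_len(max_sweeps)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      g <- yy[i] * sum(w * Xa[i, ]) - 1
      a_new <- min(max(alpha[i] - g / qii[i], 0), C)
      da <- a_new - alpha[i]
      if (abs(da) > 0) {
        w <- w + da * yy[i] * Xa[i, ]
        alpha[i] <- a_new
        delta_max <- max(delta_max, abs(da))
      }
    }
    if (delta_max < tol) break
  }
  structure(list(w = w[-d], b = w[d], C = C), class = "linear_svm")
}

#' Decision scores of a linear SVM
#' @param object a `linear_svm`.
#' @param newdata numeric matrix of features.
#' @param ... unused.
#' @return Numeric vector of affine decision scores.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$w + object$b)
}

#' AUC by the rank (Mann-Whitney) formula
#'
#' `AUC = (R_pos - n_pos (n_pos + 1)/2) / (n_pos n_neg)` with mid-ranks for
#' tied scores; identical to trapezoidal integration of the ROC curve.
#'
#' @param scores numeric decision scores.
#' @param labels logical vector, `TRUE` = positive.
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
auc_rank <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(labels, k) {
  n <- length(labels)
  fold <- integer(n)
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

#' Cross-validated AUC of the linear SVM
#'
#' Stratified random k-fold assignment (both classes spread across folds, so
#' training folds keep both classes wherever arithmetically possible).
#' Per-feature standardization (mean 0, SD 1) is fit on the training folds
#' only and applied to the validation fold — validation statistics never
#' enter the scaler. Validation-fold AUC uses the rank formula on the pooled
#' decision scores of that fold; folds whose validation part holds a single
#' class yield a missing AUC, reported as such.
#'
#' @param features numeric matrix (subjects x features).
#' @param labels logical vector.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param C SVM cost.
#' @return A list of class `cv_result`: `fold_auc`, `mean_auc`, `sd_auc`,
#'   `folds`, `seed`.
#' @export
cross_validated_auc <- function(features, labels, k = 5, seed = 1, C = 1) {
  X <- as.matrix(features)
  y <- as.logical(labels)
  n <- nrow(X)
  if (n < k) stop("need at least k subjects")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (min(sum(y), sum(!y)) < k)
    warning("fewer subjects in the minority class than folds: ",
            "some validation folds will hold a single class (AUC missing)")
  set.seed(seed)
  fold <- stratified_folds(y, k)
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || min(table(y[tr])) < 2L) next
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Zva <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- train_svm(Ztr, y[tr], C = C)
    fold_auc[f] <- auc_rank(predict(fit, Zva), y[!tr])
  }
  ok <- !is.na(fold_auc)
  structure(list(fold_auc = fold_auc,
                 mean_auc = if (any(ok)) mean(fold_auc[ok]) else NA_real_,
                 sd_auc = if (sum(ok) >= 2L) stats::sd(fold_auc[ok]) else NA_real_,
                 folds = fold, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> AUC = %.3f +/- %.3f over %d/%d informative folds\n",
              x$mean_auc, x$sd_auc, sum(!is.na(x$fold_auc)),
              length(x$fold_auc)))
  invisible(x)
}

#' Exact Shapley feature attributions
#'
#' Exact Shapley values of a model's decision function under background-mean
#' masking: a feature absent from a coalition is replaced by its background
#' mean. All `2^d` coalitions are enumerated (capped at d = 15), so the
#' attribution satisfies the Shapley axioms exactly — in particular
#' efficiency: `sum_j phi_j(x) = f(x) - f(background mean)` for every
#' subject.
#'
#' @param model object with a `predict` method returning decision scores.
#' @param features numeric matrix of the subjects to explain.
#' @param background numeric matrix used for the masking means (defaults to
#'   `features`).
#' @return A list of class `shapley_attribution`: `phi` (subjects x
#'   features), `baseline`, `ranking` (feature names by decreasing mean
#'   |phi|).
#' @export
shapley_attributions <- function(model, features, background = features) {
  X <- as.matrix(features)
  d <- ncol(X)
  if (d > 15L)
    stop("more than 15 features: exact enumeration infeasible; ",
         "use a sampling approximation (not implemented)")
  bg <- colMeans(as.matrix(background))
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
  colnames(masks) <- colnames(X)
  sizes <- rowSums(masks)
  lfac <- lgamma(seq_len(d + 1))   # lfac[k+1] = log(k!)
  # model output for every coalition and subject
  f_of <- function(mask) {
    Z <- matrix(bg, nrow(X), d, byrow = TRUE)
    Z[, mask] <- X[, mask, drop = FALSE]
    predict(model, Z)
  }
  vals <- apply(masks, 1, f_of)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)  # single subject
  # vals: subjects x coalitions
  phi <- matrix(0, nrow(X), d, dimnames = list(rownames(X), colnames(X)))
  key <- masks %*% (2^(seq_len(d) - 1))
  for (j in seq_len(d)) {
    without <- which(!masks[, j])
    with_j <- match(key[without] + 2^(j - 1), key)
    s <- sizes[without]
    wgt <- exp(lfac[s + 1] + lfac[d - s] - lfac[d + 1])  # |S|! (d-|S|-1)! / d!
    phi[, j] <- (vals[, with_j, drop = FALSE] -
                   vals[, without, drop = FALSE]) %*% wgt
  }
  baseline <- vals[1, match(0, key)]
  ranking <- colnames(X)[order(colMeans(abs(phi)), decreasing = TRUE)]
  structure(list(phi = phi, baseline = baseline, ranking = ranking),
            class = "shapley_attribution")
}

#' Compare full against top-k feature sets
#'
#' Trains an SVM on all features (standardized on the full sample) to rank
#' features by mean absolute Shapley value, then runs two cross-validations
#' with identical folds and seed: one on all features, one on the top `k`.
#'
#' The ranking fit is deliberately much more strongly regularized
#' (`C_rank`) than the classifiers under cross-validation: with a handful
#' of subjects and exactly collinear indices (TP = LF + HF by
#' construction), a soft-margin fit at `C = 1` spreads weight onto noise
#' dimensions and splits it arbitrarily within the collinear block, making
#' the attribution unstable. As `C` tends to 0 the linear SVM converges to
#' the standardized class-mean-difference (nearest-centroid) direction, so
#' the Shapley ranking of the `C_rank` fit tracks each feature's actual
#' standardized group separation — which is what a feature-importance
#' ranking is meant to measure.
#'
#' @param features numeric matrix (subjects x features).
#' @param labels logical vector.
#' @param top_k number of features kept (default 3).
#' @param seed RNG seed shared by both CV runs.
#' @param k number of CV folds.
#' @param C SVM cost used for the cross-validated classifiers.
#' @param C_rank SVM cost used for the attribution fit; the default
#'   `0.2 / n` guarantees the near-centroid regime at any sample size.
#' @return A list with `all` and `top` (`cv_result`s), `ranking`,
#'   `selected`.
#' @export
compare_feature_sets <- function(features, labels, top_k = 3, seed = 1,
                                 k = 5, C = 1, C_rank = NULL) {
  X <- as.matrix(features)
  if (is.null(C_rank)) C_rank <- 0.2 / nrow(X)
  if (top_k > ncol(X)) stop("top_k exceeds the number of features")
  mu <- colMeans(X); sg <- apply(X, 2, stats::sd); sg[sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  fit <- train_svm(Z, labels, C = C_rank)
  shap <- shapley_attributions(fit, Z)
  selected <- shap$ranking[seq_len(top_k)]
  list(all = cross_validated_auc(X, labels, k = k, seed = seed, C = C),
       top = cross_validated_auc(X[, selected, drop = FALSE], labels,
                                 k = k, seed = seed, C = C),
       ranking = shap$ranking, selected = selected)
}
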