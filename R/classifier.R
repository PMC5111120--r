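# RBF-SVM model construction and evaluation: grid search over (C, gamma),
# stratified 10-fold cross-validation, confusion-based metrics
# (Acc/Sen/Spe/Pre/Mcc) and trapezoidal ROC / precision-recall areas from
# pooled out-of-fold decision values.

#' The (C, gamma) grid for RBF-SVM optimisation
#'
#' C = 2^-5, 2^-3, ..., 2^15 (11 values) crossed with
#' gamma = 2^3, 2^1, ..., 2^-15 (10 values): 110 pairs.
#'
#' @return data.frame with columns `C` and `gamma` (110 rows).
#' @export
svm_grid <- function() {
  expand.grid(C = 2^seq(-5, 15, by = 2),
              gamma = 2^seq(3, -15, by = -2))
}

#' Fit a min-max feature scaler on training data
#'
#' Columns are mapped linearly so the training min/max land on -1/+1
#' (constant columns map to 0); the same affine map is applied to new data,
#' whose values may therefore fall outside [-1, 1].
#'
#' @param train Numeric training matrix.
#' @return Object of class `feature_scaler`.
#' @export
fit_scaler <- function(train) {
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  structure(list(lo = lo, hi = hi), class = "feature_scaler")
}

#' Apply a fitted scaler
#' @param scaler A `feature_scaler`.
#' @param X Matrix with the same columns as the training data.
#' @return Scaled matrix.
#' @export
apply_scaler <- function(scaler, X) {
  rng <- scaler$hi - scaler$lo
  mid <- (scaler$hi + scaler$lo) / 2
  out <- sweep(X, 2, mid, `-`)
  ok <- rng > 0
  out[, ok] <- sweep(out[, ok, drop = FALSE], 2, rng[ok] / 2, `/`)
  out[, !ok] <- 0
  out
}

#' Scale train/test matrices to [-1, 1] from the training range
#'
#' @param train Training matrix.
#' @param apply_to Matrix to transform with the training map (default the
#'   training matrix itself).
#' @return List with `train` and `applied` scaled matrices and the `scaler`.
#' @export
scale_features <- function(train, apply_to = train) {
  sc <- fit_scaler(train)
  list(train = apply_scaler(sc, train),
       applied = apply_scaler(sc, apply_to),
       scaler = sc)
}

#' Stratified cross-validation folds
#'
#' @param y Label vector (two classes).
#' @param k Number of folds.
#' @param seed RNG seed (local; the global RNG state is restored).
#' @return List of `k` integer index vectors (test sets).
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  if (any(table(y) < k))
    stop("cannot stratify: a class has fewer members than folds")
  with_seed(seed, {
    out <- vector("list", k)
    for (cl in unique(y)) {
      members <- sample(which(y == cl))
      fold_of <- rep_len(seq_len(k), length(members))
      for (f in seq_len(k)) out[[f]] <- c(out[[f]], members[fold_of == f])
    }
    out
  })
}

# evaluate code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Binary classification metrics from confusion counts
#'
#' Acc, Sen (recall), Spe, Pre and Matthews correlation coefficient. Any
#' metric whose denominator vanishes is 0 by convention.
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @return Named numeric vector `Acc`, `Sen`, `Spe`, `Pre`, `Mcc`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  div <- function(num, den) if (den > 0) num / den else 0
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(Acc = div(tp + tn, tp + tn + fp + fn),
    Sen = div(tp, tp + fn),
    Spe = div(tn, tn + fp),
    Pre = div(tp, tp + fp),
    Mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0)
}

#' Area under the ROC curve (trapezoidal)
#'
#' @param scores Decision values (larger = more positive).
#' @param labels Vector with positives coded `1` (anything else negative).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse score ties to a single operating point
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, tp[keep] / sum(pos))
  fpr <- c(0, fp[keep] / sum(!pos))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (trapezoidal)
#'
#' @inheritParams roc_auc
#' @return AUC-PR in [0, 1].
#' @export
pr_auc <- function(scores, labels) {
  pos <- labels == 1
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  n_seen <- seq_along(ord)
  keep <- c(diff(scores[ord]) != 0, TRUE)
  recall <- tp[keep] / sum(pos)
  precision <- tp[keep] / n_seen[keep]
  r <- c(0, recall); p <- c(precision[1], precision)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

# fit one RBF SVM and return decision values oriented so that larger = class 1
.svm_decision <- function(Xtr, ytr, Xte, C, gamma) {
  fit <- e1071::svm(Xtr, factor(ytr, levels = c(-1, 1)), scale = FALSE,
                    kernel = "radial", cost = C, gamma = gamma)
  pred <- stats::predict(fit, Xte, decision.values = TRUE)
  dec <- drop(attr(pred, "decision.values"))
  if (grepl("^-1/", colnames(attr(pred, "decision.values"))[1])) dec <- -dec
  list(pred = as.numeric(as.character(pred)), dec = dec, fit = fit)
}

#' Grid-searched RBF-SVM evaluation under stratified k-fold CV
#'
#' For every (C, gamma) pair the stratified k-fold cross-validated accuracy is
#' computed; the best pair (ties: smaller C, then larger gamma) is reported
#' with the pooled out-of-fold confusion metrics and trapezoidal ROC/PR areas
#' of its decision values. Feature scaling — and, when `n_features` is given,
#' mRMR selection — are fitted inside each training fold only.
#'
#' @param X Numeric feature matrix.
#' @param y Labels in {-1, +1}.
#' @param grid data.frame of `C`, `gamma` pairs (default [svm_grid()]).
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold split.
#' @param n_features If non-NULL, each training fold is mRMR-ranked and only
#'   the top `n_features` columns are used for that fold (nested selection).
#' @return Object of class `evaluation_report`: metrics, confusion counts,
#'   AUCR/AUCP, chosen `(C, gamma)`, subset size, seed, pooled out-of-fold
#'   decision values and predictions.
#' @export
cv_evaluate <- function(X, y, grid = svm_grid(), folds = 10L, seed = 1L,
                        n_features = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  fold_idx <- stratified_folds(y, k = folds, seed = seed)
  n <- length(y)
  npair <- nrow(grid)
  pred_mat <- matrix(NA_real_, n, npair)
  dec_mat <- matrix(NA_real_, n, npair)
  for (f in seq_len(folds)) {
    te <- fold_idx[[f]]
    tr <- setdiff(seq_len(n), te)
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (!is.null(n_features) && n_features < ncol(X)) {
      rk <- mrmr_rank(discretize_features(Xtr), y[tr], n_max = n_features)
      cols <- match(rk$feature, colnames(X))
      Xtr <- Xtr[, cols, drop = FALSE]
      Xte <- Xte[, cols, drop = FALSE]
    }
    sc <- scale_features(Xtr, Xte)
    for (g in seq_len(npair)) {
      res <- .svm_decision(sc$train, y[tr], sc$applied,
                           grid$C[g], grid$gamma[g])
      pred_mat[te, g] <- res$pred
      dec_mat[te, g] <- res$dec
    }
  }
  acc <- colMeans(pred_mat == y)
  best_acc <- max(acc)
  cand <- which(acc == best_acc)
  cand <- cand[order(grid$C[cand], -grid$gamma[cand])]
  best <- cand[1]
  pred <- pred_mat[, best]
  dec <- dec_mat[, best]
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == -1 & y == -1)
  fp <- sum(pred == 1 & y == -1); fn <- sum(pred == -1 & y == 1)
  metrics <- classification_metrics(tp, tn, fp, fn)
  structure(list(metrics = metrics,
                 counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
                 AUCR = roc_auc(dec, y),
                 AUCP = pr_auc(dec, y),
                 C = grid$C[best], gamma = grid$gamma[best],
                 subset_size = if (is.null(n_features)) ncol(X)
                               else min(n_features, ncol(X)),
                 folds = folds, seed = seed,
                 grid_accuracy = acc,
                 decision_values = dec, predictions = pred, labels = y),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "RBF-SVM %d-fold CV (C = %g, gamma = %g, %d features)\n",
    x$folds, x$C, x$gamma, x$subset_size))
  cat(sprintf(
    "  Acc %.4f  Sen %.4f  Spe %.4f  Pre %.4f  Mcc %.4f\n",
    m["Acc"], m["Sen"], m["Spe"], m["Pre"], m["Mcc"]))
  cat(sprintf("  AUC-ROC %.4f  AUC-PR %.4f\n", x$AUCR, x$AUCP))
  invisible(x)
}

#' Pick the accuracy-optimal feature subset
#'
#' Evaluates each subset of a sweep with [cv_evaluate()] (fixed columns; no
#' nested re-selection, since the subsets themselves are the ranking under
#' test) and returns the subset maximising CV accuracy; ties go to the
#' smaller subset.
#'
#' @param subsets Named list of feature-name vectors (see [subset_sweep()]).
#' @param X,y,grid,folds,seed As in [cv_evaluate()].
#' @return List with `size`, `features` and the winning `report`; all
#'   per-subset reports in `all_reports`.
#' @export
select_optimal_subset <- function(subsets, X, y, grid = svm_grid(),
                                  folds = 10L, seed = 1L) {
  stopifnot(length(subsets) >= 1L)
  reports <- lapply(subsets, function(f)
    cv_evaluate(X[, f, drop = FALSE], y, grid = grid, folds = folds,
                seed = seed))
  accs <- vapply(reports, function(r) unname(r$metrics["Acc"]), numeric(1))
  sizes <- lengths(subsets)
  best <- order(-accs, sizes)[1]
  list(size = sizes[[best]], features = subsets[[best]],
       report = reports[[best]], all_reports = reports)
}
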