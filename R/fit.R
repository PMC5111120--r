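# The user-facing model: term_classifier() assembles the whole pipeline for
# one GO term — benchmark construction, term-conditional topology
# featurisation, nested mRMR selection inside stratified 10-fold CV, RBF-SVM
# grid search — and returns a fitted classed object with predict/summary/
# plot/coef methods.

#' Fit a GO-term protein-function classifier
#'
#' Builds the balanced benchmark for `term` from the positive (`go`) and
#' negative (`nogo`) annotation tables, computes the term-conditional
#' topology features of every benchmark protein on the weighted network,
#' evaluates an RBF-SVM over the (C, gamma) grid under stratified k-fold
#' cross-validation (mRMR selection nested in each training fold by
#' default), and refits a final model on the full benchmark for prediction.
#'
#' @param net A `ppi_network` with node-weight descriptors (typically the
#'   LCC; see [largest_connected_component()], [set_node_weights()]).
#' @param go Positive annotations: data.frame (`protein`, `term`) or named
#'   list of protein sets.
#' @param nogo Negative annotations in the same form (may be `NULL`).
#' @param term GO term ID to model.
#' @param n_features Number of mRMR-selected features (default 50);
#'   `NULL` uses all features.
#' @param nested_selection If `TRUE` (default), mRMR runs inside each
#'   training fold; if `FALSE`, one ranking on the full benchmark is used
#'   for every fold (optimistic, but mirrors ranking-then-sweeping designs).
#' @param degree_matched Use degree-matched negative sampling (default
#'   `FALSE`).
#' @param grid `(C, gamma)` search grid (default [svm_grid()]).
#' @param folds CV folds (default 10).
#' @param max_L Maximum BFS depth for the topology features (default 10).
#' @param min_positives Minimum positive-sample count (default 50).
#' @param seed Seed driving sampling and fold assignment.
#' @param paths Optional precomputed [all_pairs_paths()] for `net`.
#' @param features Optional precomputed feature matrix covering the
#'   benchmark proteins (rows = protein IDs), e.g. from [featurize_all()].
#' @return Object of class `term_classifier`.
#' @export
term_classifier <- function(net, go, nogo = NULL, term,
                            n_features = 50L, nested_selection = TRUE,
                            degree_matched = FALSE,
                            grid = svm_grid(), folds = 10L,
                            max_L = MAX_L, min_positives = 50L, seed = 1L,
                            paths = NULL, features = NULL) {
  cl <- match.call()
  part <- partition_term(term, go, nogo, net)
  dataset <- if (degree_matched)
    build_degree_matched(part, net, seed = seed, min_positives = min_positives)
  else
    build_benchmark(part, seed = seed, min_positives = min_positives)
  prot <- dataset$samples$protein
  y <- dataset$samples$label
  members <- part$positives

  if (is.null(features)) {
    if (is.null(paths)) paths <- all_pairs_paths(net)
    X <- featurize_all(net, members, queries = prot, max_L = max_L,
                       paths = paths)
  } else {
    missing <- setdiff(prot, rownames(features))
    if (length(missing)) stop("feature matrix missing benchmark proteins")
    X <- features[prot, , drop = FALSE]
  }

  report <- if (nested_selection || is.null(n_features)) {
    cv_evaluate(X, y, grid = grid, folds = folds, seed = seed,
                n_features = n_features)
  } else {
    rk <- mrmr_rank(discretize_features(X), y, n_max = n_features)
    cv_evaluate(X[, rk$feature, drop = FALSE], y, grid = grid,
                folds = folds, seed = seed)
  }

  # final refit on the full benchmark for predict(): rank once on all data
  final_cols <- if (is.null(n_features) || n_features >= ncol(X)) {
    colnames(X)
  } else {
    mrmr_rank(discretize_features(X), y, n_max = n_features)$feature
  }
  Xf <- X[, final_cols, drop = FALSE]
  scaler <- fit_scaler(Xf)
  svm_fit <- e1071::svm(apply_scaler(scaler, Xf),
                        factor(y, levels = c(-1, 1)), scale = FALSE,
                        kernel = "radial", cost = report$C,
                        gamma = report$gamma)
  structure(list(call = cl, term = term, net = net, members = members,
                 partition = part, dataset = dataset,
                 features = final_cols, report = report,
                 scaler = scaler, svm = svm_fit,
                 max_L = max_L, n_features = n_features, seed = seed),
            class = "term_classifier")
}

#' Predict term membership for proteins
#'
#' Featurises `newdata` proteins against the model's term on the stored
#' network (or accepts a ready feature matrix), applies the training scaler
#' and the final SVM.
#'
#' @param object A `term_classifier`.
#' @param newdata Character vector of protein IDs in the network, or a
#'   numeric feature matrix with the model's feature columns.
#' @param ... Unused.
#' @return data.frame with `protein`, `label` (-1/+1) and `decision` (signed
#'   distance to the margin; larger favours the term).
#' @export
predict.term_classifier <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    X <- featurize_all(object$net, object$members, queries = newdata,
                       max_L = object$max_L)
  } else {
    X <- as.matrix(newdata)
  }
  X <- X[, object$features, drop = FALSE]
  Xs <- apply_scaler(object$scaler, X)
  pred <- stats::predict(object$svm, Xs, decision.values = TRUE)
  dec <- drop(attr(pred, "decision.values"))
  if (grepl("^-1/", colnames(attr(pred, "decision.values"))[1])) dec <- -dec
  data.frame(protein = rownames(X),
             label = as.integer(as.character(pred)),
             decision = as.numeric(dec),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.term_classifier <- function(x, ...) {
  cat(sprintf("term_classifier for %s\n", x$term))
  cat(sprintf("  benchmark: %d samples (%d positives), seed %d\n",
              nrow(x$dataset$samples), length(x$partition$positives), x$seed))
  cat(sprintf("  features: %d of %s topology features (mRMR)\n",
              length(x$features),
              format(1767L * x$max_L + 6L * x$max_L + (x$max_L - 1L),
                     big.mark = ",")))
  print(x$report)
  invisible(x)
}

#' @export
summary.term_classifier <- function(object, ...) {
  r <- object$report
  out <- list(term = object$term,
              n_samples = nrow(object$dataset$samples),
              n_positives = length(object$partition$positives),
              metrics = c(r$metrics, AUCR = r$AUCR, AUCP = r$AUCP),
              counts = r$counts, C = r$C, gamma = r$gamma,
              subset_size = r$subset_size, seed = object$seed)
  class(out) <- "summary.term_classifier"
  out
}

#' @export
print.summary.term_classifier <- function(x, ...) {
  cat(sprintf("GO term %s: %d samples (%d positives)\n",
              x$term, x$n_samples, x$n_positives))
  cat(sprintf("  chosen (C, gamma) = (%g, %g), %d features\n",
              x$C, x$gamma, x$subset_size))
  print(round(x$metrics, 4))
  invisible(x)
}

#' Top-ranked features of the final model
#'
#' @param object A `term_classifier`.
#' @param ... Unused.
#' @return Character vector of the selected feature names, in mRMR order.
#' @export
coef.term_classifier <- function(object, ...) object$features

#' ROC and precision-recall curves of the cross-validated model
#'
#' Plots the pooled out-of-fold ROC (left) and precision-recall (right)
#' curves of the selected model.
#'
#' @param x A `term_classifier`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.term_classifier <- function(x, ...) {
  r <- x$report
  y <- r$labels; s <- r$decision_values
  ord <- order(s, decreasing = TRUE)
  pos <- y[ord] == 1
  tp <- cumsum(pos); fp <- cumsum(!pos)
  tpr <- c(0, tp / sum(pos)); fpr <- c(0, fp / sum(!pos))
  rec <- tp / sum(pos); prec <- tp / seq_along(tp)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(fpr, tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", r$AUCR), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::plot(rec, prec, type = "l", xlab = "Recall", ylab = "Precision",
                 ylim = c(0, 1), main = sprintf("PR (AUC = %.3f)", r$AUCP),
                 ...)
  invisible(x)
}
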