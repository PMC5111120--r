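# Minimum-redundancy maximum-relevance feature ranking (greedy MID scheme,
# Peng's difference criterion): first pick argmax I(f;y), then repeatedly pick
#   argmax_f [ I(f;y) - mean_{s in S} I(f;s) ]
# over features f not yet selected.  Mutual information is estimated in bits
# from empirical joint frequencies after a 3-bin discretization (z-score, cut
# at +/- 1 SD).  Ties break deterministically by ascending column index.

#' Discretize a feature matrix for mutual-information estimation
#'
#' Each column is z-scored with its own mean/SD and cut into 3 bins at
#' thresholds -1 and +1 (at or below -1; strictly within; at or above +1).
#' Zero-SD columns map entirely to the middle bin.
#'
#' @param X Numeric matrix (samples x features).
#' @return Integer matrix of the same shape with values in 1..3.
#' @export
discretize_features <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  Z <- sweep(X, 2, mu, `-`)
  ok <- sd > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, sd[ok], `/`)
  Z[, !ok] <- 0
  D <- matrix(2L, nrow(X), ncol(X), dimnames = dimnames(X))
  D[Z <= -1] <- 1L
  D[Z >= 1] <- 3L
  D
}

# MI (bits) between two discrete vectors from their contingency table.
.mi_pair <- function(x, y) {
  J <- table(x, y) / length(x)
  px <- rowSums(J); py <- colSums(J)
  E <- outer(px, py)
  nz <- J > 0
  sum(J[nz] * log2(J[nz] / E[nz]))
}

# MI (bits) between one discrete vector z and every column of the
# discretized matrix Xd (values 1..3), vectorised via indicator crossprods.
.mi_all <- function(Xd, z, ind = NULL) {
  n <- nrow(Xd)
  lv <- sort(unique(z))
  Cz <- outer(z, lv, `==`) + 0                 # n x K indicator
  pz <- colSums(Cz) / n
  if (is.null(ind)) ind <- lapply(1:3, function(b) (Xd == b) + 0)
  mi <- numeric(ncol(Xd))
  pb <- lapply(ind, function(M) colSums(M) / n)
  for (b in 1:3) {
    if (all(pb[[b]] == 0)) next
    Jb <- crossprod(Cz, ind[[b]]) / n           # K x p joint freqs
    Eb <- outer(pz, pb[[b]])
    term <- Jb * log2(Jb / Eb)
    term[Jb == 0 | Eb == 0] <- 0
    mi <- mi + colSums(term)
  }
  names(mi) <- colnames(Xd)
  mi
}

#' mRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance ranking under the
#' mutual-information-difference (MID) criterion.
#'
#' @param Xd Discrete feature matrix from [discretize_features()] (or any
#'   integer matrix with values in 1..3).
#' @param y Class labels (two classes; any coding).
#' @param n_max Number of features to rank (must not exceed `ncol(Xd)`).
#' @return data.frame with columns `rank`, `feature`, `relevance` (I(f;y),
#'   bits) and `score` (the MID objective at selection time), of class
#'   `mrmr_ranking`.
#' @export
mrmr_rank <- function(Xd, y, n_max = ncol(Xd)) {
  stopifnot(nrow(Xd) == length(y))
  if (n_max > ncol(Xd))
    stop("n_max exceeds the number of features")
  p <- ncol(Xd)
  feat_names <- colnames(Xd)
  if (is.null(feat_names)) feat_names <- paste0("f", seq_len(p))
  ind <- lapply(1:3, function(b) (Xd == b) + 0)
  relevance <- .mi_all(Xd, y, ind = ind)
  selected <- integer(0)
  score <- numeric(0)
  redundancy <- numeric(p)           # running sum of I(f; s) over selected s
  remaining <- rep(TRUE, p)
  for (step in seq_len(n_max)) {
    obj <- relevance - if (step == 1) 0 else redundancy / length(selected)
    obj[!remaining] <- -Inf
    pick <- which.max(obj)           # which.max takes the first tie: column order
    selected <- c(selected, pick)
    score <- c(score, obj[pick])
    remaining[pick] <- FALSE
    if (step < n_max)
      redundancy <- redundancy + .mi_all(Xd, Xd[, pick], ind = ind)
  }
  structure(data.frame(rank = seq_along(selected),
                       feature = feat_names[selected],
                       relevance = as.numeric(relevance[selected]),
                       score = as.numeric(score),
                       stringsAsFactors = FALSE),
            class = c("mrmr_ranking", "data.frame"))
}

#' Nested feature subsets from an mRMR ranking
#'
#' Prefixes of the ranking with sizes `step, 2*step, ...` up to `max_size`
#' (the benchmark sweep uses 5, 10, ..., 1000, i.e. 200 subsets). If fewer
#' features are ranked, the sweep truncates at the largest available multiple
#' of `step`, with a warning.
#'
#' @param ranked An `mrmr_ranking` (or character vector of feature names).
#' @param step Size increment (default 5).
#' @param max_size Largest subset size (default 1000).
#' @return Named list of character vectors (names `"5"`, `"10"`, ...).
#' @export
subset_sweep <- function(ranked, step = 5L, max_size = 1000L) {
  feats <- if (inherits(ranked, "mrmr_ranking")) ranked$feature else ranked
  top <- min(max_size, length(feats))
  sizes <- seq(step, top, by = step)
  if (top < max_size)
    warning(sprintf("only %d ranked features; sweep truncated to %d subsets",
                    length(feats), length(sizes)))
  out <- lapply(sizes, function(k) feats[seq_len(k)])
  names(out) <- as.character(sizes)
  out
}

#' Write an mRMR ranking as TSV
#' @param ranked An `mrmr_ranking`.
#' @param path Output file.
#' @export
write_ranking <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
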