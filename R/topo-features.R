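# GO-term-conditional topology features of a query protein, computed from BFS
# shortest-path structure on the weighted network.  At each hop distance
# L = 1..10 let N be the vertices at distance L from the query, N^F its
# intersection with the function set F, sigma(v) the number of shortest
# query->v paths and wsum(v) their confidence-product sum; then
#   APVW_j(L)  = sum_{v in N^F} sigma(v) v_v(j) / NP,  NP = sum_{v in N} sigma(v)
#   PWPFP(L)   = WP_F / WP_all          (wsum totals over N^F vs N)
#   APWPF(L)   = WP_F / |F|
#   PINPFP(L)  = E_{N^F} / E_N          (edge counts within the level sets)
#   ADPF(L)    = mean degree over N^F
#   ADPWPF(L)  = mean deg(v) wsum(v) over N^F
#   PP(L)      = |N^F| / |N|
#   PPL(L)     = (shortest F-F paths of length L through the query) /
#                (all shortest F-F paths of length L),  L = 2..10.
# Every empty-denominator case yields 0, so the vector is always dense with
# 17,670 + 6x10 + 9 = 17,739 entries.  The query protein is removed from F
# before computation so positive-set membership is never trivially encoded.

MAX_L <- 10L

#' Term feature vector of one protein
#'
#' Computes the eight topology-feature families of `query` with respect to the
#' function set `members`, concatenated in fixed order (APVW for L = 1..10,
#' then PWPFP, APWPF, PINPFP, ADPF, ADPWPF, PP at L = 1..10, then PPL at
#' L = 2..10); total length `1767 * max_L + 6 * max_L + (max_L - 1)`.
#'
#' @param net A `ppi_network` with node-weight descriptors attached.
#' @param members Character vector of protein IDs annotated with the term
#'   (the query itself is excluded automatically).
#' @param query Protein ID to featurise.
#' @param max_L Maximum hop distance (default 10).
#' @param paths Optional precomputed [all_pairs_paths()] result (reused across
#'   queries by [featurize_all()]); computed on the fly when `NULL`.
#' @return Named numeric feature vector.
#' @export
featurize <- function(net, members, query, max_L = MAX_L, paths = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.null(net$descriptors))
    stop("network has no node-weight descriptors; see set_node_weights()")
  qi <- match(query, net$vertices)
  if (is.na(qi)) stop("unknown query vertex: ", query)
  members <- setdiff(intersect(members, net$vertices), query)
  fi <- match(members, net$vertices)
  n <- length(net$vertices)
  deg <- lengths(net$adj)
  D <- net$descriptors
  p <- ncol(D)

  if (is.null(paths)) {
    bq <- bfs_paths(net, query)
    # PPL needs shortest-path structure between function proteins: BFS from
    # each member (distances/counts are symmetric on an undirected graph)
    bf <- lapply(members, function(v) bfs_paths(net, v))
    dist_ff <- do.call(rbind, lapply(bf, function(b) b$dist[fi]))
    sigma_ff <- do.call(rbind, lapply(bf, function(b) b$sigma[fi]))
    dist_qf <- bq$dist[fi]
    sigma_qf <- bq$sigma[fi]
  } else {
    bq <- paths$per_source[[query]]
    dist_ff <- paths$dist[fi, fi, drop = FALSE]
    sigma_ff <- paths$sigma[fi, fi, drop = FALSE]
    dist_qf <- paths$dist[qi, fi]
    sigma_qf <- paths$sigma[qi, fi]
  }

  inF <- logical(n); inF[fi] <- TRUE
  ia <- net$edge_i[, 1]; ib <- net$edge_i[, 2]
  descnames <- colnames(D)
  if (is.null(descnames)) descnames <- paste0("d", seq_len(p))

  apvw <- matrix(0, nrow = p, ncol = max_L)
  scal <- matrix(0, nrow = 6, ncol = max_L,
                 dimnames = list(c("pwpfp", "apwpf", "pinpfp",
                                   "adpf", "adpwpf", "pp"), NULL))
  nF <- length(fi)
  for (L in seq_len(max_L)) {
    lv <- which(!is.na(bq$dist) & bq$dist == L)
    if (!length(lv)) next
    nf <- lv[inF[lv]]
    NP <- sum(bq$sigma[lv])
    WP_all <- sum(bq$wsum[lv])
    WP_F <- sum(bq$wsum[nf])
    if (length(nf) && NP > 0)
      apvw[, L] <- as.vector(crossprod(D[nf, , drop = FALSE],
                                       bq$sigma[nf])) / NP
    scal["pwpfp", L] <- if (WP_all > 0) WP_F / WP_all else 0
    scal["apwpf", L] <- if (nF > 0) WP_F / nF else 0
    inN <- logical(n); inN[lv] <- TRUE
    inNF <- logical(n); inNF[nf] <- TRUE
    E_N <- sum(inN[ia] & inN[ib])
    E_NF <- sum(inNF[ia] & inNF[ib])
    scal["pinpfp", L] <- if (E_N > 0) E_NF / E_N else 0
    scal["adpf", L] <- if (length(nf)) mean(deg[nf]) else 0
    scal["adpwpf", L] <- if (length(nf)) mean(deg[nf] * bq$wsum[nf]) else 0
    scal["pp", L] <- length(nf) / length(lv)
  }

  # PPL: over unordered pairs {s,t} of F at distance L, through-query paths
  # versus all shortest paths
  ppl <- numeric(max_L - 1L)
  if (nF >= 2) {
    through <- outer(sigma_qf, sigma_qf)       # sigma_s(q) * sigma_q(t)
    dsum <- outer(dist_qf, dist_qf, `+`)       # dist(s,q) + dist(q,t)
    ut <- upper.tri(dist_ff)
    for (L in 2:max_L) {
      atL <- ut & !is.na(dist_ff) & dist_ff == L
      if (!any(atL)) next
      A <- sum(sigma_ff[atL])
      on_path <- atL & !is.na(dsum) & dsum == L
      Tn <- sum(through[on_path])
      ppl[L - 1L] <- if (A > 0) Tn / A else 0
    }
  }

  out <- c(as.vector(apvw),
           as.vector(t(scal)),
           ppl)
  names(out) <- c(paste0("apvw_L", rep(seq_len(max_L), each = p), ".",
                         rep(descnames, max_L)),
                  paste0(rep(rownames(scal), each = max_L),
                         "_L", rep(seq_len(max_L), 6)),
                  paste0("ppl_L", 2:max_L))
  out
}

#' Term feature matrix for many proteins
#'
#' Featurises each protein in `queries` against the same function set,
#' sharing one all-pairs BFS precomputation.
#'
#' @inheritParams featurize
#' @param queries Protein IDs (default: every vertex).
#' @param paths Optional precomputed [all_pairs_paths()].
#' @return Numeric matrix, rows = queries, named feature columns.
#' @export
featurize_all <- function(net, members, queries = net$vertices,
                          max_L = MAX_L, paths = NULL) {
  if (is.null(paths)) paths <- all_pairs_paths(net)
  rows <- lapply(queries, function(q)
    featurize(net, members, q, max_L = max_L, paths = paths))
  out <- do.call(rbind, rows)
  rownames(out) <- queries
  out
}

#' Write a term feature matrix as TSV
#' @param mat Matrix from [featurize_all()].
#' @param path Output file.
#' @export
write_feature_matrix <- function(mat, path) {
  df <- data.frame(protein = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
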