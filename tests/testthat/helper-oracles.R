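# Independent oracles used to cross-check the package's shortest-path
# dynamic programme and feature algebra.  These deliberately go through
# igraph's geodesic enumeration (all_shortest_paths) and explicit per-path
# arithmetic, never through the package's BFS sigma/wsum recursion.

# random connected weighted graph with 5..12 vertices
random_connected_net <- function(n = sample(5:12, 1), p = stats::runif(1, 0.25, 0.5)) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  el <- igraph::as_edgelist(g)
  ids <- sprintf("v%02d", seq_len(n))
  edges <- data.frame(a = ids[el[, 1]], b = ids[el[, 2]],
                      confidence = stats::runif(nrow(el), 0.1, 1))
  ppi_network(edges)
}

# attach small random node-weight descriptors (p dims) for oracle tests
with_random_descriptors <- function(net, p = 3) {
  D <- matrix(stats::rnorm(length(net$vertices) * p),
              nrow = length(net$vertices),
              dimnames = list(net$vertices, paste0("d", seq_len(p))))
  set_node_weights(net, D)
}

.oracle_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("a", "b")], directed = FALSE,
                                vertices = net$vertices)
}

.oracle_edge_conf <- function(net) {
  key <- paste(pmin(net$edges$a, net$edges$b),
               pmax(net$edges$a, net$edges$b), sep = "|")
  stats::setNames(net$edges$confidence, key)
}

.oracle_path_weight <- function(path_ids, conf) {
  if (length(path_ids) < 2) return(1)
  w <- 1
  for (k in seq_len(length(path_ids) - 1)) {
    key <- paste(min(path_ids[k], path_ids[k + 1]),
                 max(path_ids[k], path_ids[k + 1]), sep = "|")
    w <- w * conf[[key]]
  }
  w
}

# all geodesics from `from` as a list of character-ID vectors
.oracle_geodesics <- function(g, from, to = igraph::V(g)) {
  sp <- igraph::all_shortest_paths(g, from = from, to = to)$vpaths
  lapply(sp, function(p) names(p))
}

# Exhaustive-enumeration version of featurize(): every family computed from
# the explicit list of shortest paths.
oracle_featurize <- function(net, members, query, max_L = 10) {
  g <- .oracle_igraph(net)
  conf <- .oracle_edge_conf(net)
  members <- setdiff(intersect(members, net$vertices), query)
  deg <- stats::setNames(igraph::degree(g), igraph::V(g)$name)
  D <- net$descriptors
  p <- ncol(D)
  paths <- .oracle_geodesics(g, query)
  plen <- vapply(paths, length, 1L) - 1L
  endpoint <- vapply(paths, function(x) x[length(x)], character(1))
  pweight <- vapply(paths, .oracle_path_weight, numeric(1), conf = conf)

  apvw <- matrix(0, p, max_L)
  scal <- matrix(0, 6, max_L,
                 dimnames = list(c("pwpfp", "apwpf", "pinpfp",
                                   "adpf", "adpwpf", "pp"), NULL))
  dmat <- igraph::distances(g, weights = NA)
  for (L in seq_len(max_L)) {
    atL <- plen == L
    if (!any(atL)) next
    ep <- endpoint[atL]
    wt <- pweight[atL]
    inF <- ep %in% members
    NP <- sum(atL)
    if (any(inF) && NP > 0)
      apvw[, L] <- colSums(D[ep[inF], , drop = FALSE]) / NP
    WP_all <- sum(wt); WP_F <- sum(wt[inF])
    scal["pwpfp", L] <- if (WP_all > 0) WP_F / WP_all else 0
    scal["apwpf", L] <- if (length(members)) WP_F / length(members) else 0
    N <- unique(ep); NF <- intersect(N, members)
    count_edges_within <- function(S) {
      if (length(S) < 2) return(0)
      sum(apply(utils::combn(S, 2), 2, function(pr)
        igraph::are_adjacent(g, pr[1], pr[2])))
    }
    E_N <- count_edges_within(N); E_NF <- count_edges_within(NF)
    scal["pinpfp", L] <- if (E_N > 0) E_NF / E_N else 0
    scal["adpf", L] <- if (length(NF)) mean(deg[NF]) else 0
    if (length(NF)) {
      wsumv <- vapply(NF, function(v) sum(wt[ep == v]), numeric(1))
      scal["adpwpf", L] <- mean(deg[NF] * wsumv)
    }
    scal["pp", L] <- length(NF) / length(N)
  }

  ppl_num <- numeric(max_L - 1)
  ppl_den <- numeric(max_L - 1)
  if (length(members) >= 2) {
    prs <- utils::combn(members, 2)
    for (k in seq_len(ncol(prs))) {
      s <- prs[1, k]; t <- prs[2, k]
      L <- dmat[s, t]
      if (L < 2 || L > max_L) next
      geo <- .oracle_geodesics(g, s, to = t)
      ppl_den[L - 1] <- ppl_den[L - 1] + length(geo)
      ppl_num[L - 1] <- ppl_num[L - 1] +
        sum(vapply(geo, function(pp) query %in% pp, logical(1)))
    }
  }
  ppl <- ifelse(ppl_den > 0, ppl_num / ppl_den, 0)

  descnames <- colnames(D)
  out <- c(as.vector(apvw), as.vector(t(scal)), ppl)
  names(out) <- c(paste0("apvw_L", rep(seq_len(max_L), each = p), ".",
                         rep(descnames, max_L)),
                  paste0(rep(rownames(scal), each = max_L),
                         "_L", rep(seq_len(max_L), 6)),
                  paste0("ppl_L", 2:max_L))
  out
}

# Direct-formula autocorrelation on a residue vector for one scale
oracle_autocorr <- function(chars, scale, kind, max_lag = 50) {
  z <- (scale - mean(scale)) / stats::sd(scale)
  p <- z[chars]
  n <- length(p)
  pbar <- mean(p)
  out <- numeric(max_lag)
  for (d in seq_len(max_lag)) {
    if (d >= n) next
    s <- 0
    for (i in seq_len(n - d)) {
      s <- s + switch(kind,
        moreau_broto = p[i] * p[i + d],
        moran = (p[i] - pbar) * (p[i + d] - pbar),
        geary = (p[i] - p[i + d])^2)
    }
    out[d] <- switch(kind,
      moreau_broto = s / (n - d),
      moran = {
        den <- sum((p - pbar)^2) / n
        if (den == 0) 0 else (s / (n - d)) / den
      },
      geary = {
        den <- sum((p - pbar)^2) / (n - 1)
        if (den == 0) 0 else (s / (2 * (n - d))) / den
      })
  }
  out
}

# table()-based mutual information in bits (independent of .mi_all)
oracle_mi <- function(x, y) {
  J <- table(x, y) / length(x)
  E <- outer(rowSums(J), colSums(J))
  nz <- J > 0
  sum(J[nz] * log2(J[nz] / E[nz]))
}

# Exhaustive greedy mRMR (MID) picks, evaluated with oracle_mi
oracle_mrmr_picks <- function(Xd, y, n_picks = 3) {
  p <- ncol(Xd)
  rel <- vapply(seq_len(p), function(j) oracle_mi(Xd[, j], y), numeric(1))
  sel <- integer(0)
  for (step in seq_len(n_picks)) {
    obj <- vapply(seq_len(p), function(j) {
      if (j %in% sel) return(-Inf)
      red <- if (length(sel)) mean(vapply(sel, function(s)
        oracle_mi(Xd[, j], Xd[, s]), numeric(1))) else 0
      rel[j] - red
    }, numeric(1))
    sel <- c(sel, which.max(obj))
  }
  colnames(Xd)[sel]
}

# small synthetic study reused across model-level tests
small_study <- function(seed = 7, h = 0.7) {
  simulate_ppi_study(n_proteins = 60, seq_len_range = c(30, 60),
                     positive_fraction = 0.4, homophily = h, seed = seed)
}
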