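# Weighted PPI network: vertices are proteins (optionally carrying the
# 1767-dim descriptor vector as node weight), edges carry an interaction
# confidence in (0,1].  All topology features consume the BFS shortest-path
# structure computed here: for a source i and every reachable v,
#   dist(v)  hop distance,
#   sigma(v) number of distinct shortest i->v paths,
#   wsum(v)  sum over those paths of the product of edge confidences.
# sigma/wsum follow the standard predecessor recursion (as in betweenness
# counting): a path is only extended through neighbours one level closer.

#' Construct a weighted PPI network
#'
#' Cleans an edge table (drops self-interactions and zero-confidence edges,
#' collapses duplicate pairs keeping the maximum confidence) and builds an
#' undirected weighted graph.
#'
#' @param edges data.frame with columns `a`, `b`, `confidence` (protein IDs
#'   and interaction confidence in (0,1]; 0-confidence rows are dropped).
#' @param descriptors Optional numeric matrix of node weights, rownames =
#'   protein IDs (see [descriptor_matrix()]).
#' @return Object of class `ppi_network`.
#' @export
ppi_network <- function(edges, descriptors = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 3)
  names(edges)[1:3] <- c("a", "b", "confidence")
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$confidence <- as.numeric(edges$confidence)
  if (anyNA(edges$confidence)) stop("non-numeric confidence value")
  if (any(edges$confidence < 0 | edges$confidence > 1))
    stop("confidence scores must lie in [0,1]")
  drop0 <- edges$confidence == 0
  if (any(drop0)) edges <- edges[!drop0, , drop = FALSE]
  self <- edges$a == edges$b
  if (any(self)) edges <- edges[!self, , drop = FALSE]
  if (nrow(edges) == 0L) stop("no usable edges")
  # canonical unordered pair; duplicates collapse to the max confidence
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    message(sprintf("collapsed %d duplicate interaction(s), keeping max confidence",
                    sum(duplicated(key))))
    conf <- tapply(edges$confidence, key, max)
    pair <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
    edges <- data.frame(a = pair[, 1], b = pair[, 2],
                        confidence = as.numeric(conf),
                        stringsAsFactors = FALSE, row.names = NULL)
  } else {
    edges <- data.frame(a = lo, b = hi, confidence = edges$confidence,
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  vertices <- sort(unique(c(edges$a, edges$b)))
  n <- length(vertices)
  ia <- match(edges$a, vertices)
  ib <- match(edges$b, vertices)
  adj <- vector("list", n)
  wadj <- vector("list", n)
  ord <- order(c(ia, ib))
  nb_from <- c(ia, ib)[ord]
  nb_to <- c(ib, ia)[ord]
  nb_w <- c(edges$confidence, edges$confidence)[ord]
  split_to <- split(nb_to, factor(nb_from, levels = seq_len(n)))
  split_w <- split(nb_w, factor(nb_from, levels = seq_len(n)))
  for (i in seq_len(n)) {
    adj[[i]] <- as.integer(split_to[[i]])
    wadj[[i]] <- as.numeric(split_w[[i]])
  }
  net <- structure(list(vertices = vertices, adj = adj, wadj = wadj,
                        edges = edges, edge_i = cbind(ia, ib),
                        descriptors = NULL),
                   class = "ppi_network")
  if (!is.null(descriptors)) net <- set_node_weights(net, descriptors)
  net
}

#' Attach node-weight descriptors to a network
#'
#' @param net A `ppi_network`.
#' @param descriptors Numeric matrix with rownames covering all vertices.
#' @return The network with descriptors attached.
#' @export
set_node_weights <- function(net, descriptors) {
  stopifnot(inherits(net, "ppi_network"), is.matrix(descriptors))
  missing <- setdiff(net$vertices, rownames(descriptors))
  if (length(missing))
    stop("descriptors missing for vertices: ",
         paste(utils::head(missing, 5), collapse = ", "))
  net$descriptors <- descriptors[net$vertices, , drop = FALSE]
  net
}

#' Read a HIPPIE-style weighted edge list
#'
#' Three tab-separated columns: proteinA, proteinB, confidence. A header line
#' is tolerated (detected by a non-numeric third field on line 1).
#'
#' @param path TSV file.
#' @param min_confidence Edges with confidence strictly below this are
#'   dropped (default 0, i.e. only exact-zero edges go).
#' @return A `ppi_network`.
#' @export
read_edge_list <- function(path, min_confidence = 0) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "", col.names = c("a", "b", "confidence"),
                           colClasses = "character", fill = FALSE)
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.numeric(raw$confidence[1]))))
    raw <- raw[-1, , drop = FALSE]
  conf <- suppressWarnings(as.numeric(raw$confidence))
  if (anyNA(conf))
    stop(sprintf("malformed confidence at line %d of %s",
                 which(is.na(conf))[1], path))
  raw$confidence <- conf
  ppi_network(raw[conf >= min_confidence, , drop = FALSE])
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("a", "b")], directed = FALSE,
                                vertices = net$vertices)
}

#' Largest connected component
#'
#' Induced subgraph on the largest component; on ties, the component
#' containing the lexicographically smallest protein ID wins.
#'
#' @param net A `ppi_network`.
#' @return A `ppi_network` restricted to the LCC.
#' @export
largest_connected_component <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  comp <- igraph::components(.as_igraph(net))
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: smallest member ID (vertices are sorted, so the first
    # occurrence of each tied component marks its smallest member)
    first_member <- vapply(best, function(k)
      net$vertices[which(comp$membership == k)[1]], character(1))
    best <- best[order(first_member)][1]
  }
  keep <- net$vertices[comp$membership == best]
  es <- net$edges
  es <- es[es$a %in% keep & es$b %in% keep, , drop = FALSE]
  out <- ppi_network(es)
  if (!is.null(net$descriptors))
    out <- set_node_weights(out, net$descriptors)
  out
}

#' Unweighted vertex degrees
#' @param net A `ppi_network`.
#' @return Named integer vector over all vertices.
#' @export
network_degree <- function(net) {
  d <- lengths(net$adj)
  names(d) <- net$vertices
  d
}

#' BFS shortest-path structure from one source
#'
#' Level-by-level breadth-first search recording, for every reachable vertex,
#' the hop distance, the number of shortest paths from the source (`sigma`)
#' and the sum over shortest paths of the product of edge confidences along
#' the path (`wsum`).
#'
#' @param net A `ppi_network`.
#' @param source Protein ID.
#' @param max_L Optional traversal depth cap; `NULL` (default) explores the
#'   whole component.
#' @return Object of class `bfs_paths`: list with `source`, `dist`, `sigma`,
#'   `wsum` (named vectors; `dist` is `NA` for unreachable vertices) and
#'   `levels` (list of vertex-ID vectors by distance).
#' @export
bfs_paths <- function(net, source, max_L = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  s <- match(source, net$vertices)
  if (is.na(s)) stop("unknown source vertex: ", source)
  n <- length(net$vertices)
  dist <- rep(NA_integer_, n)
  sigma <- numeric(n)
  wsum <- numeric(n)
  dist[s] <- 0L; sigma[s] <- 1; wsum[s] <- 1
  frontier <- s
  d <- 0L
  levels <- list()
  while (length(frontier) && (is.null(max_L) || d < max_L)) {
    d <- d + 1L
    newf <- integer(0)
    for (u in frontier) {
      nbrs <- net$adj[[u]]
      ws <- net$wadj[[u]]
      for (k in seq_along(nbrs)) {
        v <- nbrs[k]
        if (is.na(dist[v])) {
          dist[v] <- d
          newf <- c(newf, v)
        }
        if (dist[v] == d) {
          sigma[v] <- sigma[v] + sigma[u]
          wsum[v] <- wsum[v] + wsum[u] * ws[k]
        }
      }
    }
    if (length(newf)) levels[[d]] <- net$vertices[newf]
    frontier <- newf
  }
  names(dist) <- names(sigma) <- names(wsum) <- net$vertices
  structure(list(source = source, dist = dist, sigma = sigma, wsum = wsum,
                 levels = levels),
            class = "bfs_paths")
}

#' All-source shortest-path structure
#'
#' Runs [bfs_paths()] from every vertex and stacks the results into matrices
#' (rows = sources). Used by the path-length-proportion feature, which needs
#' shortest-path counts between arbitrary pairs of function proteins.
#'
#' @param net A `ppi_network`.
#' @return List of matrices `dist`, `sigma`, `wsum` (vertex x vertex) and the
#'   per-source `bfs_paths` objects in `per_source`.
#' @export
all_pairs_paths <- function(net) {
  per <- lapply(net$vertices, function(v) bfs_paths(net, v))
  names(per) <- net$vertices
  list(dist = do.call(rbind, lapply(per, `[[`, "dist")),
       sigma = do.call(rbind, lapply(per, `[[`, "sigma")),
       wsum = do.call(rbind, lapply(per, `[[`, "wsum")),
       per_source = per)
}

#' Count shortest s->t paths passing through a vertex
#'
#' `sigma_s(via) * sigma_via(t)` when `via` lies on a shortest s->t path
#' (i.e. `dist_s(via) + dist_via(t) == dist_s(t)`), else 0.
#'
#' @param bfs_s [bfs_paths()] result from `s`.
#' @param bfs_via [bfs_paths()] result from `via`.
#' @param t Target protein ID.
#' @param via Intermediate protein ID.
#' @return Numeric path count.
#' @export
paths_through <- function(bfs_s, bfs_via, t, via) {
  ds_via <- bfs_s$dist[[via]]
  dvia_t <- bfs_via$dist[[t]]
  ds_t <- bfs_s$dist[[t]]
  if (is.na(ds_via) || is.na(dvia_t) || is.na(ds_t)) return(0)
  if (ds_via + dvia_t != ds_t) return(0)
  bfs_s$sigma[[via]] * bfs_via$sigma[[t]]
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d weighted interactions\n",
              length(x$vertices), nrow(x$edges)))
  cat(sprintf("  confidence range: [%.3g, %.3g]\n",
              min(x$edges$confidence), max(x$edges$confidence)))
  cat(sprintf("  node weights: %s\n",
              if (is.null(x$descriptors)) "none"
              else paste0(ncol(x$descriptors), "-dim descriptors")))
  invisible(x)
}

#' @export
summary.ppi_network <- function(object, ...) {
  g <- .as_igraph(object)
  out <- list(vertices = length(object$vertices),
              edges = nrow(object$edges),
              components = igraph::count_components(g),
              diameter = igraph::diameter(g, weights = NA))
  class(out) <- "summary.ppi_network"
  out
}

#' @export
print.summary.ppi_network <- function(x, ...) {
  cat(sprintf("vertices: %d\nedges: %d\ncomponents: %d\ndiameter (hops): %d\n",
              x$vertices, x$edges, x$components, x$diameter))
  invisible(x)
}

#' Write a network edge list as TSV
#' @param net A `ppi_network`.
#' @param path Output file.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
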