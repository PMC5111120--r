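# Per-term benchmark datasets.  Proteins in the LCC are partitioned into
# positives (GO-style annotation table), negatives (NoGO-style table) and
# unknowns (neither).  A benchmark takes all positives plus equally many
# negatives sampled without replacement, topping up from the unknown pool
# when negatives run short (1:1 class ratio).  A degree-matched variant
# samples, for every positive of degree d, a non-positive of the closest
# available degree (ties to the lower degree), to control for degree as a
# confounder.

#' Read a protein-term annotation table
#'
#' Two or three tab-separated columns: protein, GO term, and optionally an
#' evidence code. When the evidence column is present, computationally
#' inferred/unsupported codes (ISS, ISO, ISA, ISM, IGC, RCA, IEA, NAS) are
#' filtered out; otherwise the table is taken as pre-filtered.
#'
#' @param path TSV file (a header line is tolerated).
#' @return data.frame with columns `protein`, `term`.
#' @export
read_annotations <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "", fill = TRUE,
                           colClasses = "character")
  if (nrow(raw) > 0 && (tolower(raw[1, 1]) %in% c("protein", "id")))
    raw <- raw[-1, , drop = FALSE]
  names(raw)[1:2] <- c("protein", "term")
  if (ncol(raw) >= 3) {
    excluded <- c("ISS", "ISO", "ISA", "ISM", "IGC", "RCA", "IEA", "NAS")
    keep <- !(toupper(raw[[3]]) %in% excluded)
    if (!all(keep))
      message(sprintf("filtered %d annotation(s) with excluded evidence codes",
                      sum(!keep)))
    raw <- raw[keep, , drop = FALSE]
  }
  unique(raw[, c("protein", "term")])
}

#' Term-wise protein sets from an annotation table
#' @param ann data.frame from [read_annotations()].
#' @return Named list: term -> character vector of proteins.
#' @export
annotation_sets <- function(ann) {
  lapply(split(ann$protein, ann$term), unique)
}

#' Partition LCC proteins for one GO term
#'
#' @param term GO term ID.
#' @param go Annotation data.frame (positives) or named list of protein sets.
#' @param nogo Negative-annotation data.frame or list (may be `NULL`).
#' @param net A `ppi_network` (its vertex set defines the universe).
#' @return Object of class `term_partition` with `positives`, `negatives`,
#'   `unknowns` (disjoint, all in the network).
#' @export
partition_term <- function(term, go, nogo, net) {
  as_sets <- function(x) if (is.data.frame(x)) annotation_sets(x) else x
  go <- as_sets(go); nogo <- as_sets(nogo)
  if (!term %in% names(go) || length(go[[term]]) == 0L)
    stop("term has no positive annotations: ", term)
  universe <- net$vertices
  pos_all <- unique(go[[term]])
  pos <- intersect(pos_all, universe)
  if (length(pos) < length(pos_all))
    message(sprintf("%s: %d positive(s) outside the network dropped",
                    term, length(pos_all) - length(pos)))
  neg <- character(0)
  if (!is.null(nogo) && term %in% names(nogo)) {
    neg <- intersect(unique(nogo[[term]]), universe)
    conflict <- intersect(neg, pos)
    if (length(conflict)) {
      message(sprintf(
        "%s: %d protein(s) annotated both positive and negative kept as positive",
        term, length(conflict)))
      neg <- setdiff(neg, conflict)
    }
  }
  structure(list(term = term, positives = pos, negatives = neg,
                 unknowns = setdiff(universe, c(pos, neg))),
            class = "term_partition")
}

#' @export
print.term_partition <- function(x, ...) {
  cat(sprintf("term %s: %d positives, %d negatives, %d unknowns\n", x$term,
              length(x$positives), length(x$negatives), length(x$unknowns)))
  invisible(x)
}

.check_min_positives <- function(part, min_positives) {
  if (length(part$positives) < min_positives)
    stop(structure(class = c("too_few_positives", "error", "condition"),
                   list(message = sprintf(
                     "term %s has %d positives (< %d required)",
                     part$term, length(part$positives), min_positives),
                     call = NULL)))
}

#' Build a balanced benchmark dataset for one term
#'
#' All positives, plus equally many negatives drawn uniformly without
#' replacement from the negative pool; any shortfall is topped up from the
#' unknown pool (logged). Deterministic for a given seed.
#'
#' @param part A `term_partition`.
#' @param seed RNG seed.
#' @param min_positives Minimum positive count (default 50); fewer raises a
#'   condition of class `too_few_positives`.
#' @return Object of class `benchmark_dataset`: data.frame `samples`
#'   (`protein`, `label` in {-1, +1}), `provenance` (negative/unknown pool of
#'   each -1 sample), `term`, `seed`.
#' @export
build_benchmark <- function(part, seed = 1L, min_positives = 50L) {
  stopifnot(inherits(part, "term_partition"))
  .check_min_positives(part, min_positives)
  n_pos <- length(part$positives)
  if (length(part$negatives) + length(part$unknowns) < n_pos)
    stop("negative and unknown pools jointly smaller than the positive set")
  with_seed(seed, {
    take_neg <- min(n_pos, length(part$negatives))
    neg <- if (take_neg > 0) sample(part$negatives, take_neg) else character(0)
    short <- n_pos - take_neg
    unk <- character(0)
    if (short > 0) {
      message(sprintf("%s: negative pool short by %d; topped up from unknowns",
                      part$term, short))
      unk <- sample(part$unknowns, short)
    }
    .benchmark(part$term, part$positives, neg, unk, seed)
  })
}

.benchmark <- function(term, pos, neg, unk, seed) {
  # canonical order: the dataset is a function of the selected sets only
  pos <- sort(pos); neg <- sort(neg); unk <- sort(unk)
  samples <- data.frame(
    protein = c(pos, neg, unk),
    label = c(rep(1L, length(pos)), rep(-1L, length(neg) + length(unk))),
    stringsAsFactors = FALSE)
  structure(list(term = term, samples = samples,
                 provenance = c(rep("positive", length(pos)),
                                rep("negative", length(neg)),
                                rep("unknown", length(unk))),
                 seed = seed),
            class = "benchmark_dataset")
}

#' Build a degree-matched benchmark dataset
#'
#' Like [build_benchmark()], but each positive of network degree d is paired
#' with a non-positive of the same degree; when that degree is exhausted the
#' closest available degree is used (ties favouring the lower degree).
#' Negatives are preferred over unknowns at the selected degree.
#'
#' @inheritParams build_benchmark
#' @param net The `ppi_network` supplying degrees.
#' @return A `benchmark_dataset`.
#' @export
build_degree_matched <- function(part, net, seed = 1L, min_positives = 50L) {
  stopifnot(inherits(part, "term_partition"), inherits(net, "ppi_network"))
  .check_min_positives(part, min_positives)
  deg <- network_degree(net)
  pool <- c(part$negatives, part$unknowns)
  pool_src <- c(rep("negative", length(part$negatives)),
                rep("unknown", length(part$unknowns)))
  if (length(pool) < length(part$positives))
    stop("negative and unknown pools jointly smaller than the positive set")
  with_seed(seed, {
    avail <- rep(TRUE, length(pool))
    pick <- integer(0)
    fallback <- 0L
    for (p in part$positives) {
      d <- deg[[p]]
      cand <- which(avail & deg[pool] == d)
      if (!length(cand)) {
        fallback <- fallback + 1L
        gap <- abs(deg[pool] - d)
        gap[!avail] <- Inf
        best_gap <- min(gap)
        cand <- which(gap == best_gap)
        # ties between degrees d-g and d+g: take the lower degree
        cand <- cand[deg[pool][cand] == min(deg[pool][cand])]
      }
      # prefer the negative pool at the selected degree
      if (any(pool_src[cand] == "negative"))
        cand <- cand[pool_src[cand] == "negative"]
      chosen <- if (length(cand) == 1L) cand else sample(cand, 1L)
      avail[chosen] <- FALSE
      pick <- c(pick, chosen)
    }
    if (fallback > 0)
      message(sprintf("%s: %d positive(s) matched at a neighbouring degree",
                      part$term, fallback))
    .benchmark(part$term, part$positives,
               pool[pick][pool_src[pick] == "negative"],
               pool[pick][pool_src[pick] == "unknown"], seed)
  })
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  tab <- table(x$samples$label)
  cat(sprintf("benchmark for %s: %d samples (+1: %d, -1: %d; seed %d)\n",
              x$term, nrow(x$samples), tab[["1"]], tab[["-1"]], x$seed))
  src <- table(x$provenance)
  cat("  provenance:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a benchmark dataset as TSV
#' @param ds A `benchmark_dataset`.
#' @param path Output file.
#' @export
write_benchmark <- function(ds, path) {
  utils::write.table(ds$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
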