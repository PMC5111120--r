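# Synthetic PPI study generator.  Emulates the four inputs the pipeline
# consumes: protein sequences (FASTA), a confidence-weighted interaction edge
# list (HIPPIE-style TSV), positive term annotations (GO-style TSV) and
# negative annotations (NoGO-style TSV).  Term membership is planted first;
# a homophily parameter h then rewires a fraction h of each member's edges
# toward co-members, so that h = 0 leaves annotations independent of the
# topology while large h builds a dense functional module — the signal the
# topology features are designed to detect.

#' Generate a synthetic weighted-PPI study
#'
#' @param n_proteins Number of proteins (default 300).
#' @param seq_len_range Sequence length range, uniform integer (default
#'   50-500 residues).
#' @param model Graph model: `"pa"` preferential attachment (heavy-tailed
#'   degrees, like real interactomes) or `"er"` Erdos-Renyi.
#' @param pa_m Edges brought in by each new vertex under `"pa"` (default 3).
#' @param er_p Edge probability under `"er"` (default 0.02).
#' @param n_terms Number of planted GO-like terms (default 1).
#' @param positive_fraction Fraction of proteins annotated per term
#'   (default 0.3).
#' @param homophily h in [0, 1]: probability that each member edge to a
#'   non-member is rewired to a co-member (default 0).
#' @param negative_fraction Fraction of non-members listed in the
#'   NoGO-style table per term (default 0.5).
#' @param biased_composition If `TRUE`, members' sequences are drawn with a
#'   biased amino-acid composition so node-weight (APVW) features carry term
#'   signal; default `FALSE` (i.i.d. uniform residues).
#' @param seed RNG seed; the same seed reproduces the study exactly.
#' @return Object of class `ppi_study`: `sequences` (named character),
#'   `edges` (data.frame a/b/confidence), `go` and `nogo` annotation
#'   data.frames, `members` (list term -> proteins), and the config.
#' @export
simulate_ppi_study <- function(n_proteins = 300L,
                               seq_len_range = c(50L, 500L),
                               model = c("pa", "er"),
                               pa_m = 3L, er_p = 0.02,
                               n_terms = 1L,
                               positive_fraction = 0.3,
                               homophily = 0,
                               negative_fraction = 0.5,
                               biased_composition = FALSE,
                               seed = 1L) {
  model <- match.arg(model)
  stopifnot(positive_fraction > 0, positive_fraction <= 1,
            homophily >= 0, homophily <= 1,
            negative_fraction >= 0, negative_fraction <= 1,
            n_proteins >= 10)
  with_seed(seed, {
    ids <- sprintf("P%05d", seq_len(n_proteins))
    # planted membership
    n_pos <- max(2L, round(positive_fraction * n_proteins))
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    members <- lapply(terms, function(t) sort(sample(ids, n_pos)))
    names(members) <- terms

    # base graph
    g <- if (model == "pa") {
      igraph::sample_pa(n_proteins, m = pa_m, directed = FALSE)
    } else {
      igraph::sample_gnp(n_proteins, er_p)
    }
    el <- igraph::as_edgelist(g, names = FALSE)

    # homophily rewiring: member edges to non-members move to co-members
    for (t in terms) {
      mem_idx <- match(members[[t]], ids)
      in_mem <- logical(n_proteins); in_mem[mem_idx] <- TRUE
      for (e in seq_len(nrow(el))) {
        a <- el[e, 1]; b <- el[e, 2]
        if (in_mem[a] == in_mem[b]) next
        if (stats::runif(1) >= homophily) next
        v <- if (in_mem[a]) a else b          # the member endpoint stays
        others <- setdiff(mem_idx, v)
        w <- others[sample.int(length(others), 1L)]  # new co-member endpoint
        el[e, ] <- c(min(v, w), max(v, w))
      }
    }
    # drop any duplicates/self-loops the rewiring introduced
    el <- unique(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
    el <- el[el[, 1] != el[, 2], , drop = FALSE]
    conf <- pmax(stats::runif(nrow(el)), 1e-6)
    edges <- data.frame(a = ids[el[, 1]], b = ids[el[, 2]],
                        confidence = conf, stringsAsFactors = FALSE)

    # sequences
    all_members <- unique(unlist(members))
    lens <- sample(seq(seq_len_range[1], seq_len_range[2]), n_proteins,
                   replace = TRUE)
    bias <- rep(1, 20)
    if (biased_composition) {
      # members over-use the first 5 residues of the alphabet
      bias_mem <- c(rep(3, 5), rep(1, 15))
    }
    sequences <- vapply(seq_len(n_proteins), function(i) {
      pr <- if (biased_composition && ids[i] %in% all_members) bias_mem else bias
      paste(sample(AA_ALPHABET, lens[i], replace = TRUE, prob = pr),
            collapse = "")
    }, character(1))
    names(sequences) <- ids

    # annotation tables
    go <- do.call(rbind, lapply(terms, function(t)
      data.frame(protein = members[[t]], term = t, stringsAsFactors = FALSE)))
    nogo <- do.call(rbind, lapply(terms, function(t) {
      non <- setdiff(ids, members[[t]])
      neg <- sort(sample(non, round(negative_fraction * length(non))))
      if (length(neg) == 0) return(NULL)
      data.frame(protein = neg, term = t, stringsAsFactors = FALSE)
    }))

    structure(list(sequences = sequences, edges = edges, go = go,
                   nogo = nogo, members = members,
                   config = list(n_proteins = n_proteins,
                                 seq_len_range = seq_len_range,
                                 model = model, pa_m = pa_m, er_p = er_p,
                                 n_terms = n_terms,
                                 positive_fraction = positive_fraction,
                                 homophily = homophily,
                                 negative_fraction = negative_fraction,
                                 biased_composition = biased_composition,
                                 seed = seed)),
              class = "ppi_study")
  })
}

#' @export
print.ppi_study <- function(x, ...) {
  cat(sprintf(
    "synthetic PPI study: %d proteins, %d interactions, %d term(s), h = %g\n",
    length(x$sequences), nrow(x$edges), length(x$members),
    x$config$homophily))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits `proteins.fasta`, `ppi.tsv` (proteinA, proteinB, confidence),
#' `go.tsv` and `nogo.tsv` (protein, term) in `dir`, byte-identical for a
#' given study object.
#'
#' @param study A `ppi_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ppi_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "proteins.fasta")
  writeLines(paste0(">", names(study$sequences), "\n", study$sequences), fa)
  utils::write.table(study$edges, file.path(dir, "ppi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(study$go, file.path(dir, "go.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(study$nogo, file.path(dir, "nogo.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Assemble the weighted network of a study
#'
#' Builds the `ppi_network` from the study's edge list, attaches the
#' 1767-dim descriptors computed from its sequences, and restricts to the
#' largest connected component.
#'
#' @param study A `ppi_study`.
#' @return A `ppi_network`.
#' @export
study_network <- function(study) {
  net <- ppi_network(study$edges)
  net <- largest_connected_component(net)
  desc <- descriptor_matrix(study$sequences[net$vertices])
  set_node_weights(net, desc)
}

#' Read a flat key:value fixture config
#'
#' Lines of the form `key: value`; `#` comments and blank lines ignored.
#' Values are coerced to numeric where possible.
#'
#' @param path Config file.
#' @return Named list suitable for `do.call(simulate_ppi_study, ...)`.
#' @export
read_fixture_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else if (v %in% c("TRUE", "FALSE")) as.logical(v) else v
  })
  names(out) <- vapply(kv, function(x) trimws(x[1]), character(1))
  out
}
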