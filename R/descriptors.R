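# Primary-structure descriptors: the 1767-dimensional node-weight vector.
# Block layout (fixed): AAC(20) | dipeptide(400) | normalized Moreau-Broto(400)
# | Moran(400) | Geary(400) | CTD composition(21) | CTD transition(21) |
# CTD distribution(105).

AC_MAX_LAG <- 50L

#' Sanitise a protein sequence
#'
#' Uppercases the sequence and handles residues outside the 20-letter
#' canonical alphabet (B, Z, X, U, O, gaps, ...). The default policy drops
#' them with a warning; alternatively they can be replaced by a fixed
#' canonical residue.
#'
#' @param seq Character scalar, amino-acid sequence.
#' @param noncanonical Either `"drop"` (default) or a single canonical
#'   residue used as replacement.
#' @return Character vector of single canonical residues.
#' @export
sanitize_sequence <- function(seq, noncanonical = "drop") {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    if (identical(noncanonical, "drop")) {
      warning(sprintf("dropped %d non-canonical residue(s): %s",
                      sum(bad), paste(unique(chars[bad]), collapse = ",")))
      chars <- chars[!bad]
    } else {
      stopifnot(noncanonical %in% AA_ALPHABET)
      chars[bad] <- noncanonical
    }
  }
  if (length(chars) == 0L) stop("sequence contains no canonical residues")
  chars
}

#' Amino-acid composition
#'
#' Frequency of each of the 20 amino acids, in fixed alphabetical order
#' (ACDEFGHIKLMNPQRSTVWY); entries sum to 1.
#'
#' @param seq Character scalar or sanitised residue vector.
#' @return Named numeric vector of length 20.
#' @export
aac <- function(seq) {
  chars <- if (length(seq) > 1L) seq else sanitize_sequence(seq)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  out <- as.numeric(counts) / length(chars)
  names(out) <- paste0("aac.", AA_ALPHABET)
  out
}

#' Dipeptide composition
#'
#' Frequency of each of the 400 ordered adjacent residue pairs, row-major over
#' the fixed alphabet (AA, AC, ..., YY), normalised by N-1.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 400.
#' @export
dipeptide <- function(seq) {
  chars <- if (length(seq) > 1L) seq else sanitize_sequence(seq)
  n <- length(chars)
  if (n < 2L) stop("dipeptide composition needs at least 2 residues")
  i1 <- match(chars[-n], AA_ALPHABET)
  i2 <- match(chars[-1], AA_ALPHABET)
  counts <- tabulate((i1 - 1L) * 20L + i2, nbins = 400L)
  out <- counts / (n - 1L)
  names(out) <- paste0("dipep.", rep(AA_ALPHABET, each = 20L),
                       rep(AA_ALPHABET, 20L))
  out
}

# One property scale standardised to zero mean / unit SD over the 20 residues.
.standardize_scale <- function(p) (p - mean(p)) / stats::sd(p)

#' Sequence autocorrelation descriptors
#'
#' Lagged autocorrelation of a physicochemical property profile along the
#' sequence, for the eight standard property scales and lags d = 1..50
#' (property-major order, 400 values). Three variants:
#' \describe{
#'   \item{moreau_broto}{normalized Moreau-Broto,
#'     \eqn{AC(d) = \frac{1}{N-d}\sum_{i=1}^{N-d} P_i P_{i+d}}}
#'   \item{moran}{Moran's I,
#'     \eqn{I(d) = \frac{\frac{1}{N-d}\sum (P_i-\bar P)(P_{i+d}-\bar P)}
#'                      {\frac{1}{N}\sum (P_i-\bar P)^2}}}
#'   \item{geary}{Geary's C,
#'     \eqn{C(d) = \frac{\frac{1}{2(N-d)}\sum (P_i-P_{i+d})^2}
#'                      {\frac{1}{N-1}\sum (P_i-\bar P)^2}}}
#' }
#' Property scales are standardised over the 20 amino acids before use.
#' Lags d >= N, and zero-variance (homopolymer) denominators for Moran/Geary,
#' yield 0 so the vector length is invariant.
#'
#' @inheritParams aac
#' @param kind One of `"moreau_broto"`, `"moran"`, `"geary"`.
#' @param scales Named list of property scales (default the 8 standard ones).
#' @param max_lag Maximum lag (default 50).
#' @return Named numeric vector of length `length(scales) * max_lag`.
#' @export
autocorrelation <- function(seq, kind = c("moreau_broto", "moran", "geary"),
                            scales = AA_PROPERTY_SCALES, max_lag = AC_MAX_LAG) {
  kind <- match.arg(kind)
  chars <- if (length(seq) > 1L) seq else sanitize_sequence(seq)
  n <- length(chars)
  idx <- match(chars, AA_ALPHABET)
  out <- numeric(length(scales) * max_lag)
  prefix <- c(moreau_broto = "mb", moran = "mr", geary = "ge")[[kind]]
  names(out) <- paste0(prefix, ".",
                       rep(names(scales), each = max_lag), "_lag",
                       rep(seq_len(max_lag), length(scales)))
  pos <- 0L
  for (sc in scales) {
    p <- .standardize_scale(sc)[idx]
    pbar <- mean(p)
    dev <- p - pbar
    ss_n <- sum(dev^2) / n          # Moran denominator
    ss_n1 <- sum(dev^2) / (n - 1)   # Geary denominator
    for (d in seq_len(max_lag)) {
      pos <- pos + 1L
      if (d >= n) next  # empty sum convention -> 0
      i <- seq_len(n - d)
      out[pos] <- switch(kind,
        moreau_broto = sum(p[i] * p[i + d]) / (n - d),
        moran = if (ss_n == 0) 0 else
          (sum(dev[i] * dev[i + d]) / (n - d)) / ss_n,
        geary = if (ss_n1 == 0) 0 else
          (sum((p[i] - p[i + d])^2) / (2 * (n - d))) / ss_n1)
    }
  }
  out
}

# class-index encoding of a residue vector for one CTD attribute
.ctd_encode <- function(chars, attr_groups) .ctd_class_map(attr_groups)[chars]

#' CTD composition descriptors
#'
#' For each of the 7 Dubchak attributes, the fraction of residues in each of
#' the 3 classes (counts divided by N); each attribute's triple sums to 1.
#'
#' @inheritParams aac
#' @param groups CTD attribute partitions (default [AA_CTD_GROUPS]).
#' @return Named numeric vector of length 21.
#' @export
ctd_composition <- function(seq, groups = AA_CTD_GROUPS) {
  chars <- if (length(seq) > 1L) seq else sanitize_sequence(seq)
  n <- length(chars)
  out <- numeric(0)
  for (a in names(groups)) {
    enc <- .ctd_encode(chars, groups[[a]])
    v <- tabulate(enc, nbins = 3L) / n
    names(v) <- paste0("ctdc.", a, "_", 1:3)
    out <- c(out, v)
  }
  out
}

#' CTD transition descriptors
#'
#' For each attribute, the frequencies of adjacent class changes 1<->2, 1<->3
#' and 2<->3 (both orders counted), divided by N-1.
#'
#' @inheritParams ctd_composition
#' @return Named numeric vector of length 21.
#' @export
ctd_transition <- function(seq, groups = AA_CTD_GROUPS) {
  chars <- if (length(seq) > 1L) seq else sanitize_sequence(seq)
  n <- length(chars)
  if (n < 2L) stop("CTD transitions need at least 2 residues")
  out <- numeric(0)
  for (a in names(groups)) {
    enc <- .ctd_encode(chars, groups[[a]])
    x <- enc[-n]; y <- enc[-1]
    lo <- pmin(x, y); hi <- pmax(x, y)
    v <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
           sum(lo == 2 & hi == 3)) / (n - 1L)
    names(v) <- paste0("ctdt.", a, "_", c("12", "13", "23"))
    out <- c(out, v)
  }
  out
}

#' CTD distribution descriptors
#'
#' For each attribute and class, five positional landmarks: the sequence
#' positions (1-based, as fractions of N) of the first, 25%, 50%, 75% and last
#' occurrence of that class (ceiling rule on the occurrence index); all five
#' are 0 when the class is absent.
#'
#' @inheritParams ctd_composition
#' @return Named numeric vector of length 105.
#' @export
ctd_distribution <- function(seq, groups = AA_CTD_GROUPS) {
  chars <- if (length(seq) > 1L) seq else sanitize_sequence(seq)
  n <- length(chars)
  out <- numeric(0)
  qs <- c("first", "q25", "q50", "q75", "last")
  for (a in names(groups)) {
    enc <- .ctd_encode(chars, groups[[a]])
    for (k in 1:3) {
      pos <- which(enc == k)
      v <- if (length(pos) == 0L) numeric(5) else {
        kk <- length(pos)
        pos[c(1L, ceiling(0.25 * kk), ceiling(0.50 * kk),
              ceiling(0.75 * kk), kk)] / n
      }
      names(v) <- paste0("ctdd.", a, "_", k, "_", qs)
      out <- c(out, v)
    }
  }
  out
}

#' Full 1767-dimensional primary-structure descriptor
#'
#' Concatenates, in fixed order: amino-acid composition (20), dipeptide
#' composition (400), normalized Moreau-Broto (400), Moran (400) and Geary
#' (400) autocorrelations, CTD composition (21), transition (21) and
#' distribution (105).
#'
#' @inheritParams aac
#' @return Named numeric vector of length 1767.
#' @export
full_descriptor <- function(seq) {
  chars <- if (length(seq) > 1L) seq else sanitize_sequence(seq)
  c(aac(chars),
    dipeptide(chars),
    autocorrelation(chars, "moreau_broto"),
    autocorrelation(chars, "moran"),
    autocorrelation(chars, "geary"),
    ctd_composition(chars),
    ctd_transition(chars),
    ctd_distribution(chars))
}

#' Descriptor matrix for a set of sequences
#'
#' @param seqs Named character vector of sequences, or a path to a FASTA file
#'   (IDs are the first whitespace-delimited token of each header).
#' @return Numeric matrix, one row per protein, 1767 named columns.
#' @export
descriptor_matrix <- function(seqs) {
  if (length(seqs) == 1L && is.null(names(seqs)) && file.exists(seqs))
    seqs <- read_fasta(seqs)
  stopifnot(!is.null(names(seqs)))
  t(vapply(seqs, full_descriptor, numeric(1767L)))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector; names are the first whitespace-delimited
#'   token of each record header.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write a descriptor matrix as TSV
#'
#' @param mat Matrix from [descriptor_matrix()].
#' @param path Output file.
#' @export
write_descriptor_matrix <- function(mat, path) {
  df <- data.frame(protein = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
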