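#' Canonical 21-letter amino acid alphabet
#'
#' The fixed symbol ordering used throughout the package for all arrays and
#' file formats: the alignment gap first, then the 20 natural amino acids in
#' alphabetical one-letter order, `"-ACDEFGHIKLMNPQRSTVWY"`. Index lookup is a
#' bijection between symbols and `1:21`; the gap always has index 1.
#'
#' @format A character vector of length 21.
#' @export
AA_ALPHABET <- strsplit("-ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @rdname AA_ALPHABET
#' @export
AA_GAP <- "-"

.aa_index <- local({
  idx <- seq_along(AA_ALPHABET)
  names(idx) <- AA_ALPHABET
  idx
})

#' Build a default alphabet of a given size
#'
#' Synthetic landscapes with reduced state spaces (e.g. `q = 4` for fast
#' tests) use the first `q - 1` amino acid letters; only the full `q = 21`
#' alphabet carries a gap symbol and supports codon-level evolution.
#'
#' @param q Alphabet size, between 2 and 21.
#' @return Character vector of `q` symbols.
#' @export
default_alphabet <- function(q) {
  stopifnot(q >= 2, q <= 21)
  if (q == 21) AA_ALPHABET else AA_ALPHABET[-1][seq_len(q)]
}

#' Encode aligned sequences as an integer matrix
#'
#' Sequences are stored internally as integer matrices (rows = sequences,
#' columns = alignment positions) indexing into an alphabet. This is the form
#' every statistic in the package consumes.
#'
#' @param x A character vector of aligned sequences (all the same length), a
#'   single string, an existing integer matrix (returned unchanged after
#'   validation), or an `XStringSet`.
#' @param alphabet Character vector of symbols; defaults to [AA_ALPHABET].
#' @return Integer matrix with entries in `1:length(alphabet)` and the
#'   alphabet attached as attribute `"alphabet"`.
#' @export
as_aa_matrix <- function(x, alphabet = AA_ALPHABET) {
  if (is.matrix(x) && is.numeric(x)) {
    storage.mode(x) <- "integer"
    if (any(is.na(x)) || any(x < 1L) || any(x > length(alphabet)))
      stop("integer sequence matrix has entries outside the alphabet")
    attr(x, "alphabet") <- alphabet
    return(x)
  }
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) == 0L)
    stop("need a character vector of aligned sequences")
  n <- nchar(x)
  if (length(unique(n)) != 1L)
    stop("sequences are not aligned: unequal lengths ", paste(unique(n), collapse = ", "))
  chars <- matrix(unlist(strsplit(x, ""), use.names = FALSE),
                  nrow = length(x), byrow = TRUE)
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("symbol(s) outside the alphabet: ", paste(bad, collapse = " "))
  }
  m <- matrix(as.integer(idx), nrow = length(x))
  rownames(m) <- names(x)
  attr(m, "alphabet") <- alphabet
  m
}

#' Decode an integer sequence matrix back to strings
#'
#' @param m Integer matrix as produced by [as_aa_matrix()].
#' @param alphabet Alphabet to decode with; defaults to the matrix's own
#'   `"alphabet"` attribute, falling back to [AA_ALPHABET].
#' @return Character vector of sequences.
#' @export
aa_strings <- function(m, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- attr(m, "alphabet")
  if (is.null(alphabet)) alphabet <- AA_ALPHABET
  m <- as.matrix(m)
  out <- apply(m, 1L, function(r) paste(alphabet[r], collapse = ""))
  names(out) <- rownames(m)
  out
}

#' Read / write an aligned FASTA file as an integer sequence matrix
#'
#' Thin wrappers around `Biostrings` that apply the package's alphabet
#' encoding. Gaps are `'-'`; all records must have equal length.
#'
#' @param path File path.
#' @param alphabet Alphabet used for encoding/decoding.
#' @return `read_msa()` returns an integer sequence matrix; `write_msa()`
#'   returns `path` invisibly.
#' @export
read_msa <- function(path, alphabet = AA_ALPHABET) {
  set <- Biostrings::readBStringSet(path)
  as_aa_matrix(as.character(set), alphabet = alphabet)
}

#' @rdname read_msa
#' @param m Integer sequence matrix (or character vector of sequences).
#' @param names Optional sequence names; defaults to rownames or `seq_1..n`.
#' @export
write_msa <- function(m, path, names = NULL, alphabet = NULL) {
  if (is.character(m)) {
    seqs <- m
    if (is.null(names)) names <- names(m)
  } else {
    seqs <- aa_strings(m, alphabet)
    if (is.null(names)) names <- rownames(m)
  }
  if (is.null(names)) names <- paste0("seq_", seq_along(seqs))
  set <- Biostrings::BStringSet(stats::setNames(seqs, names))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
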