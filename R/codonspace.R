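#' Codon-space utilities
#'
#' The evolutionary chain mutates DNA one nucleotide at a time, so the amino
#' acids reachable at a site are constrained by the current codon through the
#' standard genetic code. These helpers enumerate that accessibility
#' structure. Codons are 3-letter strings over `ACGT`; the gap codon is
#' `"---"` and corresponds to a gap in the amino acid sequence. Stop codons
#' are excluded everywhere: a mutation creating a stop has zero proposal
#' probability.
#'
#' @name codonspace
NULL

NUCLEOTIDES <- c("A", "C", "G", "T")

# all 64 codons in a fixed order; translations from the standard code
# (NCBI table 1), stops marked "*"
.codon_tables <- local({
  grid <- expand.grid(n3 = NUCLEOTIDES, n2 = NUCLEOTIDES, n1 = NUCLEOTIDES,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$n1, grid$n2, grid$n3)
  list(codons = codons)
})

CODONS <- .codon_tables$codons

.codon_aa_chr <- function() {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[CODONS])
}

.codon_env <- new.env(parent = emptyenv())

# lazily built lookups: codon -> aa index (NA for stops), single-nt neighbor
# codon indices, accessible aa sets, candidate codon sets
.codon_data <- function() {
  if (!is.null(.codon_env$data)) return(.codon_env$data)
  aa_chr <- .codon_aa_chr()
  aa_idx <- ifelse(aa_chr == "*", NA_integer_, match(aa_chr, AA_ALPHABET))
  nbr <- vector("list", 64L)
  for (ci in seq_len(64L)) {
    cod <- strsplit(CODONS[ci], "")[[1]]
    out <- integer(0)
    for (pos in 1:3) for (n in NUCLEOTIDES) {
      if (n == cod[pos]) next
      mut <- cod; mut[pos] <- n
      out <- c(out, match(paste(mut, collapse = ""), CODONS))
    }
    nbr[[ci]] <- out
  }
  acc <- vector("list", 64L)
  cand <- vector("list", 64L)
  for (ci in seq_len(64L)) {
    if (is.na(aa_idx[ci])) next  # stop codons never occur in a state
    reach <- c(ci, nbr[[ci]])
    sense <- reach[!is.na(aa_idx[reach])]
    acc[[ci]] <- sort(unique(aa_idx[sense]))
    cand[[ci]] <- lapply(stats::setNames(acc[[ci]], AA_ALPHABET[acc[[ci]]]),
                         function(b) sort(unique(sense[aa_idx[sense] == b])))
  }
  .codon_env$data <- list(aa_idx = aa_idx, neighbors = nbr,
                          accessible = acc, candidates = cand)
  .codon_env$data
}

.codon_index <- function(codon) {
  if (codon == "---") return(NA_integer_)
  ci <- match(codon, CODONS)
  if (is.na(ci)) stop("malformed codon: ", codon)
  ci
}

#' Translate a codon sequence
#'
#' Standard genetic code; the gap triplet `"---"` translates to the alignment
#' gap `'-'`. Stop codons are an error — they are not allowed in any evolving
#' state.
#'
#' @param dna Character vector of codons (3-letter strings), or a single
#'   nucleotide string whose length is a multiple of 3.
#' @return Amino acid sequence as a single string.
#' @export
translate_codons <- function(dna) {
  dna <- .split_codons(dna)
  cd <- .codon_data()
  out <- character(length(dna))
  for (k in seq_along(dna)) {
    if (dna[k] == "---") { out[k] <- AA_GAP; next }
    ci <- .codon_index(dna[k])
    if (is.na(cd$aa_idx[ci])) stop("stop codon ", dna[k], " at position ", k)
    out[k] <- AA_ALPHABET[cd$aa_idx[ci]]
  }
  paste(out, collapse = "")
}

.split_codons <- function(dna) {
  if (length(dna) == 1L && nchar(dna) > 3L) {
    if (nchar(dna) %% 3L != 0L) stop("nucleotide sequence length not a multiple of 3")
    dna <- substring(dna, seq(1L, nchar(dna), 3L), seq(3L, nchar(dna), 3L))
  }
  bad <- nchar(dna) != 3L | (!grepl("^[ACGT]{3}$", dna) & dna != "---")
  if (any(bad)) stop("malformed codon(s): ", paste(unique(dna[bad]), collapse = " "))
  dna
}

#' Amino acids accessible from a codon by one nucleotide change
#'
#' The set returned is the selection proposal set of the evolutionary model:
#' translations of the codon itself and of its nine single-nucleotide
#' neighbors, with stop codons excluded. It always contains the codon's own
#' amino acid (via the identity / synonymous moves).
#'
#' @param codon A sense codon (3-letter string).
#' @return Character vector of amino acids, sorted in alphabet order.
#' @export
accessible_amino_acids <- function(codon) {
  cd <- .codon_data()
  if (identical(codon, "---")) stop("gap codons are never mutated")
  ci <- .codon_index(codon)
  if (is.na(cd$aa_idx[ci])) stop("stop codon has no evolving state: ", codon)
  AA_ALPHABET[cd$accessible[[ci]]]
}

#' Codons for an amino acid within one nucleotide of a codon
#'
#' All sense codons of `b` at nucleotide Hamming distance at most 1 from
#' `codon` (including `codon` itself when `b` is its own amino acid). The
#' evolutionary chain picks the new codon uniformly from this set.
#'
#' @param codon A sense codon.
#' @param b Target amino acid; must be in [accessible_amino_acids()] of
#'   `codon`.
#' @return Character vector of codons.
#' @export
codons_within_one <- function(codon, b) {
  cd <- .codon_data()
  ci <- .codon_index(codon)
  if (is.na(ci) || is.na(cd$aa_idx[ci])) stop("need a sense codon")
  set <- cd$candidates[[ci]][[b]]
  if (is.null(set))
    stop("amino acid ", b, " is not accessible from codon ", codon)
  CODONS[set]
}

#' Paired codon / amino acid evolving state
#'
#' The state of the evolutionary chain: a codon sequence and the amino acid
#' sequence it translates to, kept mutually consistent (gap triplets pair
#' with gap positions; no stop codons).
#'
#' @param dna Character vector of codons, or one nucleotide string.
#' @return Object of class `evolving_state`: list with integer vectors `aa`
#'   (alphabet indices, gap = 1) and `codon` (1..64 codon indices, `NA` at
#'   gaps), plus the codon strings.
#' @export
evolving_state <- function(dna) {
  dna <- .split_codons(dna)
  cd <- .codon_data()
  ci <- vapply(dna, function(x) if (x == "---") NA_integer_ else .codon_index(x), 0L)
  aa <- ifelse(is.na(ci), match(AA_GAP, AA_ALPHABET), cd$aa_idx[ci])
  if (anyNA(aa)) stop("stop codon in state: ",
                      paste(dna[is.na(aa)], collapse = " "))
  structure(list(aa = as.integer(aa), codon = unname(ci), dna = unname(dna)),
            class = "evolving_state")
}

#' @export
print.evolving_state <- function(x, ...) {
  cat(sprintf("Evolving state: %d sites (%d gaps)\n aa:  %s\n",
              length(x$aa), sum(is.na(x$codon)),
              paste(AA_ALPHABET[x$aa], collapse = "")))
  invisible(x)
}

#' Amino acid string of an evolving state
#' @param state An [evolving_state()].
#' @return Single string over the 21-letter alphabet.
#' @export
state_aa <- function(state) paste(AA_ALPHABET[state$aa], collapse = "")

#' Nucleotide string of an evolving state
#' @param state An [evolving_state()].
#' @return Single DNA string (gap triplets as `---`).
#' @export
state_dna <- function(state) paste(state$dna, collapse = "")

#' Assign codons to an amino acid sequence
#'
#' Builds a consistent [evolving_state()] when only the protein sequence is
#' known (or validates a user-provided coding sequence).
#'
#' @param aa Aligned amino acid sequence (string over the 21-letter alphabet).
#' @param mode `"random_synonymous"` draws each codon uniformly among the
#'   synonymous sense codons; `"first_codon"` takes the first codon of each
#'   amino acid in the fixed codon order (deterministic); `"given_dna"`
#'   validates `dna` against `aa`.
#' @param dna Coding DNA, required for `mode = "given_dna"`.
#' @param seed Optional integer seed for `"random_synonymous"`.
#' @return An [evolving_state()] whose translation equals `aa`.
#' @export
assign_codons <- function(aa, mode = c("random_synonymous", "first_codon",
                                       "given_dna"),
                          dna = NULL, seed = NULL) {
  mode <- match.arg(mode)
  idx <- as_aa_matrix(aa)[1L, ]
  cd <- .codon_data()
  gap <- match(AA_GAP, AA_ALPHABET)
  if (mode == "given_dna") {
    if (is.null(dna)) stop("mode 'given_dna' needs dna")
    st <- evolving_state(dna)
    if (!identical(st$aa, unname(idx)))
      stop("provided DNA is inconsistent with the amino acid sequence at position(s) ",
           paste(which(st$aa != idx), collapse = ", "))
    return(st)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  dna <- vapply(idx, function(a) {
    if (a == gap) return("---")
    syn <- CODONS[which(cd$aa_idx == a)]
    if (mode == "first_codon") syn[1L] else syn[sample.int(length(syn), 1L)]
  }, "")
  evolving_state(dna)
}

#' Report codon-level mismatches between a DNA and protein sequence
#'
#' Validation utility: translates `dna` codon by codon and tabulates the
#' positions where it disagrees with `aa`.
#'
#' @inheritParams assign_codons
#' @param dna Coding DNA (string or codon vector).
#' @return Data frame with columns `site`, `codon`, `translated`, `expected`;
#'   zero rows when consistent.
#' @export
validate_coding_dna <- function(dna, aa) {
  dna <- .split_codons(dna)
  idx <- as_aa_matrix(aa)[1L, ]
  if (length(dna) != length(idx))
    stop("codon count ", length(dna), " does not match protein length ", length(idx))
  cd <- .codon_data()
  tr <- vapply(dna, function(x) {
    if (x == "---") return(AA_GAP)
    ai <- cd$aa_idx[.codon_index(x)]
    if (is.na(ai)) "*" else AA_ALPHABET[ai]
  }, "")
  bad <- which(tr != AA_ALPHABET[idx])
  data.frame(site = bad, codon = dna[bad], translated = unname(tr[bad]),
             expected = AA_ALPHABET[idx[bad]], stringsAsFactors = FALSE)
}
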