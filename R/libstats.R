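#' Amino acid Hamming distance
#'
#' Number of alignment positions at which two aligned sequences differ.
#' Gaps are ordinary symbols here; since gaps are conserved by the
#' evolutionary model, gap positions never differ between a simulated
#' sequence and its wildtype.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (strings or integer
#'   vectors).
#' @return Integer count of differing positions.
#' @export
hamming_distance <- function(seq_a, seq_b) {
  if (is.character(seq_a)) seq_a <- strsplit(seq_a, "")[[1]]
  if (is.character(seq_b)) seq_b <- strsplit(seq_b, "")[[1]]
  if (length(seq_a) != length(seq_b))
    stop("sequences have different lengths")
  sum(seq_a != seq_b)
}

.hamming_to_ref <- function(msa, ref) {
  rowSums(msa != matrix(ref, nrow(msa), length(ref), byrow = TRUE))
}

#' Site-specific amino acid frequency table
#'
#' The mutational spectrum `f_i(a)`: the (optionally weighted) fraction of
#' library sequences carrying state `a` at position `i`. Rows are probability
#' vectors.
#'
#' @param msa Aligned sequences (anything [as_aa_matrix()] accepts).
#' @param weights Optional per-sequence weights; default uniform.
#' @param alphabet Alphabet to tabulate over.
#' @return Object of class `site_freq_table`: list with `values` (`L x q`
#'   matrix, rows summing to 1), `n_sequences`, `weighted`.
#' @export
site_frequencies <- function(msa, weights = NULL, alphabet = AA_ALPHABET) {
  m <- as_aa_matrix(msa, alphabet)
  if (nrow(m) == 0L) stop("empty alignment")
  q <- length(alphabet)
  if (is.null(weights)) {
    w <- rep(1, nrow(m))
    weighted <- FALSE
  } else {
    stopifnot(length(weights) == nrow(m), all(weights > 0))
    w <- weights
    weighted <- TRUE
  }
  f <- matrix(0, ncol(m), q, dimnames = list(NULL, alphabet))
  for (a in seq_len(q)) f[, a] <- colSums((m == a) * w)
  f <- f / sum(w)
  structure(list(values = f, n_sequences = nrow(m), weighted = weighted),
            class = "site_freq_table")
}

#' @export
print.site_freq_table <- function(x, ...) {
  cat(sprintf("Site frequency table: %d sites x %d states from %d sequences%s\n",
              nrow(x$values), ncol(x$values), x$n_sequences,
              if (x$weighted) " (weighted)" else ""))
  invisible(x)
}

#' Rank correlation between two mutational spectra
#'
#' Spearman correlation across selected `(site, amino acid)` entries of two
#' site frequency tables of the same shape. Because single-nucleotide
#' accessibility forces many entries to be exactly zero in both codon-level
#' libraries, the comparison can be restricted to the entries actually
#' reachable from the wildtype codons (`"accessible_only"`, the default), to
#' non-wildtype entries, or taken over all entries.
#'
#' @param f1,f2 [site_frequencies()] tables (or bare `L x q` matrices) of the
#'   same dimensions.
#' @param entry_filter Which `(i, a)` entries enter the correlation.
#' @param wildtype An [evolving_state()]; required for the
#'   `"accessible_only"` and `"non_wildtype"` filters.
#' @return Spearman rank correlation in `[-1, 1]`.
#' @export
spectra_correlation <- function(f1, f2,
                                entry_filter = c("accessible_only",
                                                 "non_wildtype", "all"),
                                wildtype = NULL) {
  entry_filter <- match.arg(entry_filter)
  v1 <- if (inherits(f1, "site_freq_table")) f1$values else f1
  v2 <- if (inherits(f2, "site_freq_table")) f2$values else f2
  if (!identical(dim(v1), dim(v2)))
    stop("frequency tables have different shapes")
  keep <- matrix(TRUE, nrow(v1), ncol(v1))
  if (entry_filter != "all") {
    if (is.null(wildtype))
      stop("entry_filter '", entry_filter, "' needs the wildtype state")
    stopifnot(inherits(wildtype, "evolving_state"),
              length(wildtype$aa) == nrow(v1), ncol(v1) == 21L)
    if (entry_filter == "non_wildtype") {
      keep[cbind(seq_len(nrow(v1)), wildtype$aa)] <- FALSE
    } else {
      keep[] <- FALSE
      for (i in seq_len(nrow(v1))) {
        if (is.na(wildtype$codon[i])) next
        acc <- match(accessible_amino_acids(wildtype$dna[i]), AA_ALPHABET)
        keep[i, acc] <- TRUE
      }
    }
  }
  x <- v1[keep]; y <- v2[keep]
  if (length(x) < 3L) stop("fewer than 3 entries after filtering")
  stats::cor(x, y, method = "spearman")
}

#' Energy versus distance summary of a library
#'
#' Per-sequence energy differences to the wildtype, summarized by amino acid
#' Hamming distance — the library-level view of how selection strength shapes
#' the energy drift away from the wildtype.
#'
#' @param msa Aligned library.
#' @param model A [potts_model()] or [profile_model()].
#' @param wildtype Wildtype sequence (string, integer vector, or
#'   [evolving_state()]).
#' @param breaks Optional distance bin breaks (as in [cut()]); default one
#'   bin per observed distance.
#' @return Data frame with columns `distance` (bin midpoint or exact
#'   distance), `n`, `mean_dE`, `sd_dE`; bin counts sum to `nrow(msa)`.
#' @export
energy_distance_profile <- function(msa, model, wildtype, breaks = NULL) {
  m <- as_aa_matrix(msa, model$alphabet)
  if (nrow(m) == 0L) stop("empty alignment")
  wt <- if (inherits(wildtype, "evolving_state")) wildtype$aa
        else .seq_to_idx(model, wildtype)
  dE <- msa_energies(model, m) - energy(model, wt)
  d <- .hamming_to_ref(m, wt)
  if (is.null(breaks)) {
    grp <- d
  } else {
    grp <- as.character(cut(d, breaks = breaks, include.lowest = TRUE))
  }
  agg <- split(dE, grp)
  dist_key <- if (is.null(breaks)) as.numeric(names(agg)) else
    vapply(split(d, grp), function(v) mean(range(v)), 0)
  out <- data.frame(distance = dist_key,
                    n = lengths(agg),
                    mean_dE = vapply(agg, mean, 0),
                    sd_dE = vapply(agg, function(v)
                      if (length(v) > 1L) stats::sd(v) else 0, 0))
  out[order(out$distance), , drop = FALSE]
}

#' Write a site frequency table as TSV
#'
#' Columns `site`, `aa`, `frequency` (long format), 1-based sites.
#'
#' @param f A [site_frequencies()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_frequencies <- function(f, path) {
  v <- f$values
  long <- data.frame(site = rep(seq_len(nrow(v)), ncol(v)),
                     aa = rep(colnames(v), each = nrow(v)),
                     frequency = as.vector(v))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
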