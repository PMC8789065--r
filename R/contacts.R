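#' Residue--residue contact map
#'
#' A set of unordered position pairs counted as true contacts, after the two
#' standard coevolution filters: a distance cutoff (strictly below, in
#' Angstrom) and a minimum separation along the sequence.
#'
#' @param L Number of alignment positions.
#' @param pairs Two-column integer matrix of contacting pairs (1-based,
#'   unordered; stored with `i < j`).
#' @param min_separation Minimum `|i - j|` for a pair to be eligible.
#' @param distance_cutoff Cutoff used to build the map (recorded for
#'   provenance; `NA` for planted maps).
#' @return Object of class `contact_map`.
#' @export
contact_map <- function(L, pairs, min_separation = 5L, distance_cutoff = NA_real_) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs)) {
    pairs <- t(apply(pairs, 1L, sort))
    if (any(pairs[, 1L] == pairs[, 2L])) stop("self-pairs are not contacts")
    if (any(pairs < 1L | pairs > L)) stop("pair index out of range")
    pairs <- unique(pairs)
    pairs <- pairs[pairs[, 2L] - pairs[, 1L] >= min_separation, , drop = FALSE]
  }
  structure(list(L = as.integer(L), pairs = pairs,
                 min_separation = as.integer(min_separation),
                 distance_cutoff = distance_cutoff),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: %d contacts on %d positions (|i-j| >= %d%s)\n",
              nrow(x$pairs), x$L, x$min_separation,
              if (is.na(x$distance_cutoff)) ""
              else sprintf(", d < %g A", x$distance_cutoff)))
  invisible(x)
}

#' Build a contact map from a residue distance table
#'
#' Pairs with minimal heavy-atom distance strictly below `cutoff` and
#' sequence separation `|i - j| >= min_separation` are kept as contacts (the
#' standard 8 Angstrom / separation-5 convention of coevolutionary contact
#' prediction).
#'
#' @param distance_table Data frame with columns `i`, `j` (1-based
#'   positions) and `distance` (Angstrom), e.g. from
#'   [read_distance_table()].
#' @param L Number of alignment positions.
#' @param cutoff Distance cutoff in Angstrom (default 8; 5.5 is appropriate
#'   for families whose structural variability is well covered).
#' @param min_separation Minimum sequence separation (default 5).
#' @return A [contact_map()].
#' @export
contact_map_from_distances <- function(distance_table, L, cutoff = 8,
                                       min_separation = 5L) {
  d <- distance_table
  stopifnot(all(c("i", "j", "distance") %in% names(d)))
  if (any(d$distance < 0)) stop("negative distances")
  keep <- d$distance < cutoff & abs(d$i - d$j) >= min_separation
  contact_map(L, cbind(d$i[keep], d$j[keep]), min_separation, cutoff)
}

#' Read a pair-distance TSV
#'
#' Expected columns: `i`, `j`, `distance` (tab-separated, with header);
#' positions may be 0-based (the common DCA tooling convention) or 1-based.
#'
#' @param path File path.
#' @param zero_based Are positions in the file 0-based? Default `TRUE`.
#' @return Data frame with 1-based `i`, `j` and `distance`.
#' @export
read_distance_table <- function(path, zero_based = TRUE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("i", "j", "distance") %in% names(d)))
  if (zero_based) { d$i <- d$i + 1L; d$j <- d$j + 1L }
  d
}

#' Phylogenetic reweighting of alignment sequences
#'
#' Each sequence gets weight `1 / n_s` where `n_s` counts the sequences
#' (itself included) with fractional identity at or above the threshold. With
#' `threshold = NULL` (reweighting off, the appropriate setting for simulated
#' libraries of independent chains) all weights are 1.
#'
#' @param msa Aligned library.
#' @param identity_threshold Fractional identity threshold in `(0, 1]`, or
#'   `NULL` to disable reweighting.
#' @param alphabet Alphabet of the alignment.
#' @return Numeric vector of per-sequence weights.
#' @export
sequence_weights <- function(msa, identity_threshold = 0.8,
                             alphabet = AA_ALPHABET) {
  m <- as_aa_matrix(msa, alphabet)
  if (nrow(m) == 0L) stop("empty alignment")
  if (is.null(identity_threshold)) return(rep(1, nrow(m)))
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  q <- length(alphabet); L <- ncol(m)
  matches <- matrix(0, nrow(m), nrow(m))
  for (a in seq_len(q)) {
    ind <- (m == a) * 1
    matches <- matches + tcrossprod(ind)
  }
  n_similar <- rowSums(matches / L >= identity_threshold)
  1 / n_similar
}

#' Symmetric pair-score matrix from Gaussian DCA
#'
#' Multivariate-Gaussian direct coupling analysis: the alignment columns are
#' one-hot encoded over the first `q - 1` states (the last alphabet state is
#' dropped; the gap is an ordinary state), one- and two-site frequencies are
#' computed with sequence weights and mixed toward the uniform independent
#' model with a pseudocount, and the resulting covariance matrix is inverted.
#' The score of a pair is the Frobenius norm of its `(q-1) x (q-1)` inverse
#' covariance (coupling) block. Apply [apc_correction()] before ranking.
#'
#' @param msa Aligned library (at least 2 sequences and 2 positions).
#' @param pseudocount Mixing weight toward uniform, in `(0, 1)`; default 0.6,
#'   the robust choice for libraries of widely varying statistics (0.5 is a
#'   common alternative).
#' @param weights Per-sequence weights (default all 1, i.e. reweighting off).
#' @param alphabet Alphabet of the alignment.
#' @return Symmetric `L x L` score matrix with zero diagonal, of class
#'   `score_matrix`.
#' @export
gauss_dca_scores <- function(msa, pseudocount = 0.6, weights = NULL,
                             alphabet = AA_ALPHABET) {
  m <- as_aa_matrix(msa, alphabet)
  M <- nrow(m); L <- ncol(m); q <- length(alphabet)
  if (M < 2L) stop("need at least 2 sequences")
  if (L < 2L) stop("need at least 2 positions")
  stopifnot(pseudocount > 0, pseudocount < 1)
  if (is.null(weights)) weights <- rep(1, M)
  stopifnot(length(weights) == M)
  Meff <- sum(weights)
  qe <- q - 1L  # encoded states: all but the last alphabet symbol
  X <- matrix(0, M, L * qe)
  for (a in seq_len(qe))
    X[, (seq_len(L) - 1L) * qe + a] <- (m == a) * 1
  fi <- colSums(X * weights) / Meff
  Fij <- crossprod(X * sqrt(weights)) / Meff
  lam <- pseudocount
  fi_t <- (1 - lam) * fi + lam / q
  Ft <- (1 - lam) * Fij + lam / q^2
  # diagonal blocks carry the single-site delta structure, not q^-2 mixing
  for (i in seq_len(L)) {
    idx <- (i - 1L) * qe + seq_len(qe)
    blk <- (1 - lam) * Fij[idx, idx]
    diag(blk) <- (1 - lam) * fi[idx] + lam / q
    Ft[idx, idx] <- blk
  }
  C <- Ft - tcrossprod(fi_t)
  invC <- tryCatch(solve(C), error = function(e)
    stop("covariance matrix is singular; raise the pseudocount (",
         conditionMessage(e), ")"))
  S <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    blk <- invC[(i - 1L) * qe + seq_len(qe), (j - 1L) * qe + seq_len(qe)]
    S[i, j] <- S[j, i] <- sqrt(sum(blk^2))
  }
  structure(S, class = c("score_matrix", "matrix", "array"))
}

#' Average-product correction of a pair-score matrix
#'
#' Removes the background row/column signal:
#' `S'_ij = S_ij - (mean_i S)(mean_j S) / (mean S)`, with means taken over
#' off-diagonal entries. An all-zero matrix is returned unchanged.
#'
#' @param scores Symmetric score matrix.
#' @return Corrected symmetric matrix (zero diagonal) of class
#'   `score_matrix`.
#' @export
apc_correction <- function(scores) {
  S <- unclass(scores)
  L <- nrow(S)
  stopifnot(ncol(S) == L)
  if (max(abs(S - t(S))) > 1e-8) stop("score matrix must be symmetric")
  diag(S) <- 0
  tot <- sum(S) / (L * (L - 1L))
  if (tot == 0) return(structure(S, class = c("score_matrix", "matrix", "array")))
  rowm <- rowSums(S) / (L - 1L)
  out <- S - outer(rowm, rowm) / tot
  diag(out) <- 0
  structure(out, class = c("score_matrix", "matrix", "array"))
}

.eligible_pairs <- function(L, min_separation) {
  pr <- .pair_index(L)
  pr[pr[, 2L] - pr[, 1L] >= min_separation, , drop = FALSE]
}

.rank_pairs <- function(scores, min_separation) {
  S <- unclass(scores)
  el <- .eligible_pairs(nrow(S), min_separation)
  sc <- S[el]
  # ties broken lexicographically by (i, j) for determinism
  el[order(-sc, el[, 1L], el[, 2L]), , drop = FALSE]
}

#' Positive predictive value of a contact ranking
#'
#' Fraction of the `n_predictions` top-scoring eligible pairs (separation
#' `>= min_separation` of the map) that are true contacts. The conventional
#' reporting uses the first 100 predictions.
#'
#' @param scores Symmetric score matrix (typically APC-corrected).
#' @param map A [contact_map()].
#' @param n_predictions Number of top pairs to evaluate (default 100).
#' @return PPV in `[0, 1]`.
#' @export
ppv <- function(scores, map, n_predictions = 100L) {
  stopifnot(inherits(map, "contact_map"))
  ranked <- .rank_pairs(scores, map$min_separation)
  if (nrow(ranked) < n_predictions)
    stop("fewer than ", n_predictions, " eligible pairs")
  top <- ranked[seq_len(n_predictions), , drop = FALSE]
  if (!nrow(map$pairs)) return(0)
  key <- function(p) p[, 1L] * (map$L + 1L) + p[, 2L]
  mean(key(top) %in% key(map$pairs))
}

#' Expected PPV of a random ranking
#'
#' The null baseline: the contact density among eligible pairs, which is the
#' expected PPV of ranking pairs at random.
#'
#' @param map A [contact_map()].
#' @return Scalar density in `[0, 1]`.
#' @export
ppv_null_baseline <- function(map) {
  el <- .eligible_pairs(map$L, map$min_separation)
  if (!nrow(el)) return(0)
  nrow(map$pairs) / nrow(el)
}

#' Scan contact-prediction accuracy over simulation parameters
#'
#' For each selection temperature and replicate, one deep library
#' (`max(library_sizes)` chains) is simulated with snapshots at
#' `snapshot_steps`; every requested smaller depth is drawn from it by
#' subsampling without replacement. Each `(T, steps, M)` cell is scored with
#' Gaussian DCA + APC and evaluated as PPV against `map`, then averaged over
#' replicates. This is the machinery behind the divergence-versus-depth and
#' selection-strength scans of epistatic-signal emergence.
#'
#' @param model Landscape on the 21-letter alphabet (codon mode) or a
#'   reduced alphabet (seec mode).
#' @param wildtype Wildtype state or sequence.
#' @param T_values Selection temperatures to scan.
#' @param snapshot_steps Step counts at which libraries are evaluated.
#' @param library_sizes Library depths `M` to evaluate.
#' @param map True [contact_map()].
#' @param n_replicates Independent simulation runs per temperature
#'   (default 5).
#' @param n_predictions Top pairs evaluated for the PPV.
#' @param pseudocount Gaussian-DCA pseudocount.
#' @param seed Master seed.
#' @param mode Chain mode, as in [evolver_config()].
#' @return List with `grid` (one row per cell: `T`, `steps`, `M`,
#'   `mean_ppv`, `sd_ppv`, `mean_hamming`, `null_ppv`) and `cells` (the
#'   per-replicate rows).
#' @export
parameter_scan <- function(model, wildtype, T_values, snapshot_steps,
                           library_sizes, map, n_replicates = 5L,
                           n_predictions = 100L, pseudocount = 0.6,
                           seed = 1L, mode = "codon") {
  stopifnot(inherits(map, "contact_map"))
  wt_aa <- if (inherits(wildtype, "evolving_state")) wildtype$aa
           else as_aa_matrix(wildtype, model$alphabet)[1L, ]
  M_max <- max(library_sizes)
  rows <- list()
  for (Ti in seq_along(T_values)) {
    for (r in seq_len(n_replicates)) {
      cfg <- evolver_config(T = T_values[Ti], n_steps = max(snapshot_steps),
                            n_chains = M_max, snapshot_steps = snapshot_steps,
                            seed = seed + 1000L * Ti + r, mode = mode)
      lib <- evolve_library(wildtype, model, cfg)
      for (st in as.character(snapshot_steps)) {
        full <- lib$snapshots[[st]]
        for (M in library_sizes) {
          sub <- if (M == M_max) full else
            subsample_msa(full, M, seed = seed + 7L * M + r)
          p <- tryCatch({
            sc <- apc_correction(gauss_dca_scores(sub, pseudocount,
                                                  alphabet = model$alphabet))
            ppv(sc, map, n_predictions)
          }, error = function(e) NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            T = T_values[Ti], steps = as.integer(st), M = M, replicate = r,
            ppv = p, mean_hamming = mean(.hamming_to_ref(sub, wt_aa)))
        }
      }
    }
  }
  cells <- do.call(rbind, rows)
  grid <- do.call(rbind, lapply(
    split(cells, list(cells$T, cells$steps, cells$M), drop = TRUE),
    function(g) data.frame(T = g$T[1L], steps = g$steps[1L], M = g$M[1L],
                           mean_ppv = mean(g$ppv), sd_ppv = stats::sd(g$ppv),
                           mean_hamming = mean(g$mean_hamming),
                           null_ppv = ppv_null_baseline(map))))
  grid <- grid[order(grid$T, grid$steps, grid$M), , drop = FALSE]
  rownames(grid) <- NULL
  list(grid = grid, cells = cells)
}
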