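#' Potts sequence landscape
#'
#' A Potts model over aligned sequences of length `L` on a `q`-state alphabet
#' assigns each sequence the statistical energy
#' \deqn{E(a_1,\dots,a_L) = -\sum_i h_i(a_i) - \sum_{i<j} J_{ij}(a_i,a_j),}
#' a proxy for negative fitness: low energy means high model probability
#' \eqn{P \propto e^{-E}}. Fields `h` encode site-specific amino acid biases;
#' couplings `J` encode pairwise epistasis, and their strong entries are the
#' basis of DCA contact prediction.
#'
#' @param h Numeric `L x q` matrix of fields `h[i, a]`.
#' @param J Numeric `L x L x q x q` array of couplings `J[i, j, a, b]`;
#'   must satisfy the symmetry `J[i, j, a, b] == J[j, i, b, a]` and have zero
#'   diagonal blocks `J[i, i, , ]`.
#' @param alphabet Character vector of `q` symbols; defaults to
#'   [default_alphabet()] of the matching size.
#' @return An object of class `potts_model` with elements `L`, `q`, `h`, `J`,
#'   `alphabet`.
#' @seealso [profile_model()], [energy()], [random_potts()]
#' @export
potts_model <- function(h, J, alphabet = NULL) {
  h <- as.matrix(h)
  L <- nrow(h); q <- ncol(h)
  if (is.null(alphabet)) alphabet <- default_alphabet(q)
  stopifnot(length(alphabet) == q)
  if (!is.array(J) || !identical(dim(J), c(L, L, q, q)))
    stop("J must be an L x L x q x q array matching h")
  if (!all(is.finite(h)) || !all(is.finite(J)))
    stop("all Potts parameters must be finite")
  Jt <- aperm(J, c(2, 1, 4, 3))
  if (max(abs(J - Jt)) > 1e-8)
    stop("couplings violate the symmetry J[i,j,a,b] == J[j,i,b,a]")
  for (i in seq_len(L)) if (any(J[i, i, , ] != 0))
    stop("diagonal coupling blocks J[i,i,,] must be zero")
  structure(list(L = L, q = q, h = h, J = J, alphabet = alphabet),
            class = "potts_model")
}

#' Profile (independent-site) sequence model
#'
#' The non-epistatic baseline: fields only, no couplings, so the energy is a
#' sum of independent per-site terms and every mutational effect is context
#' free.
#'
#' @inheritParams potts_model
#' @return An object of class `profile_model` with elements `L`, `q`, `h`,
#'   `alphabet`.
#' @export
profile_model <- function(h, alphabet = NULL) {
  h <- as.matrix(h)
  if (!all(is.finite(h))) stop("all fields must be finite")
  q <- ncol(h)
  if (is.null(alphabet)) alphabet <- default_alphabet(q)
  stopifnot(length(alphabet) == q)
  structure(list(L = nrow(h), q = q, h = h, alphabet = alphabet),
            class = "profile_model")
}

#' @export
print.potts_model <- function(x, ...) {
  nz <- 0L
  for (i in seq_len(x$L - 1L)) for (j in (i + 1L):x$L)
    if (any(x$J[i, j, , ] != 0)) nz <- nz + 1L
  cat(sprintf("Potts landscape: L = %d sites, q = %d states, %d coupled pairs\n",
              x$L, x$q, nz))
  invisible(x)
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("Profile model: L = %d sites, q = %d states (no couplings)\n",
              x$L, x$q))
  invisible(x)
}

.seq_to_idx <- function(model, seq) {
  if (is.character(seq)) seq <- as_aa_matrix(seq, model$alphabet)[1L, ]
  seq <- as.integer(seq)
  if (length(seq) != model$L)
    stop("sequence length ", length(seq), " does not match model L = ", model$L)
  if (any(seq < 1L) || any(seq > model$q))
    stop("sequence contains symbols outside the model alphabet")
  seq
}

#' Statistical energy of a sequence
#'
#' Computes \eqn{E = -\sum_i h_i(a_i) - \sum_{i<j} J_{ij}(a_i, a_j)}. For a
#' profile model the coupling term is absent.
#'
#' @param model A [potts_model()] or [profile_model()].
#' @param seq Aligned sequence: a string over the model alphabet or an integer
#'   vector of state indices.
#' @return Scalar energy.
#' @export
energy <- function(model, seq) {
  a <- .seq_to_idx(model, seq)
  L <- model$L
  e <- -sum(model$h[cbind(seq_len(L), a)])
  if (inherits(model, "potts_model") && L > 1L) {
    pr <- .pair_index(L)
    e <- e - sum(model$J[cbind(pr[, 1L], pr[, 2L], a[pr[, 1L]], a[pr[, 2L]])])
  }
  e
}

.pair_cache <- new.env(parent = emptyenv())
.pair_index <- function(L) {
  key <- as.character(L)
  if (is.null(.pair_cache[[key]])) {
    .pair_cache[[key]] <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  }
  .pair_cache[[key]]
}

#' Energy change of a point mutation
#'
#' \eqn{\Delta E = E(\mathrm{mutant}) - E(\mathrm{sequence})} for substituting
#' state `b` at position `site`, computed locally in O(L) from the fields and
#' the couplings to the unchanged context, never by two full energy
#' evaluations.
#'
#' @inheritParams energy
#' @param site Position to mutate (1-based).
#' @param b Replacement state: a single symbol or its index.
#' @return Scalar energy difference (0 for the identity substitution).
#' @export
delta_energy <- function(model, seq, site, b) {
  a <- .seq_to_idx(model, seq)
  if (length(site) != 1L || site < 1L || site > model$L)
    stop("invalid site")
  if (is.character(b)) {
    b <- match(b, model$alphabet)
    if (is.na(b)) stop("replacement symbol outside the model alphabet")
  }
  b <- as.integer(b)
  if (b < 1L || b > model$q) stop("replacement state index out of range")
  a_old <- a[site]
  if (b == a_old) return(0)
  d <- -(model$h[site, b] - model$h[site, a_old])
  if (inherits(model, "potts_model")) {
    js <- setdiff(seq_len(model$L), site)
    d <- d - sum(model$J[cbind(site, js, b, a[js])] -
                 model$J[cbind(site, js, a_old, a[js])])
  }
  d
}

#' Full single-mutant energy scan
#'
#' The in-silico analogue of a deep mutational scan: `delta_energy()` for
#' every position and every one of the 20 amino acids. Gaps are never mutation
#' targets, and positions that are gaps in `seq` are reported as `NA`.
#'
#' @inheritParams energy
#' @return Numeric `L x 20` matrix of energy differences; rows named by
#'   position, columns by target amino acid. Entries where the target equals
#'   the current amino acid are 0.
#' @export
mutant_scan <- function(model, seq) {
  a <- .seq_to_idx(model, seq)
  gap <- match(AA_GAP, model$alphabet)
  targets <- setdiff(seq_len(model$q), if (is.na(gap)) integer() else gap)
  out <- matrix(NA_real_, model$L, length(targets),
                dimnames = list(seq_len(model$L), model$alphabet[targets]))
  for (i in seq_len(model$L)) {
    if (!is.na(gap) && a[i] == gap) next
    out[i, ] <- vapply(targets, function(b) delta_energy(model, a, i, b), 0)
  }
  out
}

#' Conditional substitution distribution at one site
#'
#' The probability, at inverse temperature `beta`, of substituting state `b`
#' at `site` given the rest of the sequence, restricted to an allowed set:
#' \deqn{P(b) \propto \exp\{\beta h_i(b) + \beta \sum_{j \ne i} J_{ij}(b, a_j)\}.}
#' This is the selection kernel of the evolutionary chain; the allowed set is
#' there the codon-accessible amino acids. `beta = 0` gives the uniform
#' (selection-free) limit. Exponentials are max-shifted before normalization.
#'
#' @inheritParams delta_energy
#' @param allowed Non-empty vector of candidate states (symbols or indices).
#' @param beta Inverse selection temperature, `>= 0`.
#' @return Named probability vector over `allowed` (names from the alphabet).
#' @export
conditional_distribution <- function(model, seq, site, allowed, beta = 1) {
  a <- .seq_to_idx(model, seq)
  if (length(allowed) == 0L) stop("allowed set is empty")
  if (is.character(allowed)) {
    allowed <- match(allowed, model$alphabet)
    if (anyNA(allowed)) stop("allowed set contains symbols outside the alphabet")
  }
  allowed <- as.integer(allowed)
  stopifnot(all(allowed >= 1L), all(allowed <= model$q), beta >= 0)
  s <- model$h[site, allowed]
  if (inherits(model, "potts_model")) {
    js <- setdiff(seq_len(model$L), site)
    if (length(js))
      s <- s + vapply(allowed,
                      function(b) sum(model$J[cbind(site, js, b, a[js])]), 0)
  }
  w <- exp(beta * s - max(beta * s))
  p <- w / sum(w)
  names(p) <- model$alphabet[allowed]
  p
}

#' Transform a Potts model to the zero-sum gauge
#'
#' The Potts energy is invariant under gauge transformations that shift
#' parameters between fields and couplings. The zero-sum gauge is the
#' canonical normalization with \eqn{\sum_a h_i(a) = 0} and
#' \eqn{\sum_a J_{ij}(a,b) = \sum_b J_{ij}(a,b) = 0}; energy *differences*
#' between any two sequences are unchanged (total energies shift by a
#' constant).
#'
#' @param model A [potts_model()].
#' @return A gauge-equivalent `potts_model` in the zero-sum gauge.
#' @export
zero_sum_gauge <- function(model) {
  stopifnot(inherits(model, "potts_model"))
  L <- model$L; q <- model$q
  h <- model$h; J <- model$J
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    blk <- J[i, j, , ]
    rm_ <- rowMeans(blk); cm_ <- colMeans(blk); mm <- mean(blk)
    nb <- blk - outer(rm_, rep(1, q)) - outer(rep(1, q), cm_) + mm
    J[i, j, , ] <- nb
    J[j, i, , ] <- t(nb)
    h[i, ] <- h[i, ] + (rm_ - mm)
    h[j, ] <- h[j, ] + (cm_ - mm)
  }
  h <- h - rowMeans(h)
  potts_model(h, J, model$alphabet)
}

#' Fit a profile model from an alignment
#'
#' Fields are log frequencies of a (weighted) pseudocount-regularized site
#' frequency table: \eqn{h_i(a) = \log \tilde f_i(a)} with
#' \eqn{\tilde f = (1-\lambda) f + \lambda / q}.
#'
#' @param msa Aligned sequences (anything [as_aa_matrix()] accepts).
#' @param weights Optional per-sequence weights (default uniform).
#' @param pseudocount Mixing weight \eqn{\lambda \in [0, 1]} toward the
#'   uniform distribution; default 0.01.
#' @param alphabet Alphabet of the model; default [AA_ALPHABET].
#' @return A [profile_model()].
#' @export
profile_from_msa <- function(msa, weights = NULL, pseudocount = 0.01,
                             alphabet = AA_ALPHABET) {
  m <- as_aa_matrix(msa, alphabet)
  if (nrow(m) == 0L) stop("empty alignment")
  stopifnot(pseudocount >= 0, pseudocount <= 1)
  f <- site_frequencies(m, weights = weights, alphabet = alphabet)$values
  ft <- (1 - pseudocount) * f + pseudocount / length(alphabet)
  profile_model(log(ft), alphabet)
}
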