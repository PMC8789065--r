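#' Generate a synthetic Potts landscape with planted contacts
#'
#' Draws a random landscape whose coupling structure sits on a planted edge
#' graph, standing in for a DCA model inferred from natural homologs: every
#' other module can then be exercised with a known ground truth. Fields are
#' Gaussian with sd `field_scale`; coupling blocks are Gaussian with sd
#' `coupling_scale` on planted edges and exactly zero elsewhere, so planted
#' pairs are the true "contacts". The model is returned in the zero-sum
#' gauge. On the full 21-letter alphabet the gap state is given a strongly
#' negative field and carries no couplings, so gap-free sequences dominate
#' the equilibrium ensemble (the simulated wildtypes carry no gaps, and the
#' evolutionary moves never propose any).
#'
#' @param L Number of sites.
#' @param q Alphabet size (4 for fast tests, 21 for codon-level runs).
#' @param topology `"random_graph"` (each eligible pair is an edge with
#'   probability `edge_prob`), `"chain"` (successive neighbors), or
#'   `"lattice2d"` (near-square grid adjacency).
#' @param edge_prob Edge probability for `"random_graph"`.
#' @param coupling_scale Coupling block sd; the default gives single-mutant
#'   `|dE|` values spanning roughly 0--4 at `q = 21`, a realistic dynamic
#'   range for mutational effects.
#' @param field_scale Field sd.
#' @param seed Integer seed.
#' @param min_separation Planted pairs closer than this along the sequence
#'   are excluded from the returned contact map (they would be ineligible
#'   for contact prediction anyway).
#' @return List with `model` (a [potts_model()]) and `map` (the planted
#'   [contact_map()]).
#' @export
random_potts <- function(L, q = 21, topology = c("random_graph", "chain",
                                                 "lattice2d"),
                         edge_prob = 0.08, coupling_scale = 0.3,
                         field_scale = 0.8, seed = 1L, min_separation = 5L) {
  topology <- match.arg(topology)
  stopifnot(coupling_scale >= 0, field_scale >= 0)
  set.seed(seed)
  alphabet <- default_alphabet(q)
  gap <- match(AA_GAP, alphabet)
  h <- matrix(stats::rnorm(L * q, sd = field_scale), L, q)
  if (!is.na(gap)) h[, gap] <- -8 * max(field_scale, 1)
  states <- setdiff(seq_len(q), if (is.na(gap)) integer() else gap)
  edges <- switch(topology,
    random_graph = {
      pr <- .pair_index(L)
      pr[stats::runif(nrow(pr)) < edge_prob, , drop = FALSE]
    },
    chain = cbind(seq_len(L - 1L), 2L:L),
    lattice2d = {
      side <- ceiling(sqrt(L))
      e <- list()
      for (i in seq_len(L)) {
        r <- (i - 1L) %/% side; c <- (i - 1L) %% side
        if (c + 1L < side && i + 1L <= L) e[[length(e) + 1L]] <- c(i, i + 1L)
        if (i + side <= L) e[[length(e) + 1L]] <- c(i, i + side)
      }
      do.call(rbind, e)
    })
  J <- array(0, c(L, L, q, q))
  if (coupling_scale > 0 && nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1L]; j <- edges[k, 2L]
      blk <- matrix(0, q, q)
      blk[states, states] <- stats::rnorm(length(states)^2, sd = coupling_scale)
      J[i, j, , ] <- blk
      J[j, i, , ] <- t(blk)
    }
  } else {
    edges <- edges[0, , drop = FALSE]
  }
  model <- zero_sum_gauge(potts_model(h, J, alphabet))
  list(model = model,
       map = contact_map(L, edges, min_separation = min_separation))
}

#' Equilibrium sample from a Potts model
#'
#' Single-site heat-bath Gibbs sampling: one chain is burnt in and then
#' recorded every `thinning` sweeps, emulating an alignment of naturally
#' diverged homologs drawn from the landscape's equilibrium distribution
#' `P = exp(-E)/Z`.
#'
#' @param model A [potts_model()] or [profile_model()].
#' @param n_sequences Number of sequences to return.
#' @param burn_in Burn-in, in full sweeps over all sites.
#' @param thinning Sweeps between recorded states.
#' @param seed Integer seed.
#' @param beta Inverse temperature of the target distribution (default 1).
#' @return Integer sequence matrix (`n_sequences x L`).
#' @export
gibbs_sample <- function(model, n_sequences, burn_in = 200L, thinning = 5L,
                         seed = 1L, beta = 1) {
  set.seed(seed)
  state <- matrix(sample.int(model$q, model$L, replace = TRUE) - 1L, 1L)
  state <- cpp_gibbs_sweeps(model$h, .model_J_or_null(model), state, beta,
                            as.integer(burn_in))
  out <- matrix(0L, n_sequences, model$L)
  for (s in seq_len(n_sequences)) {
    state <- cpp_gibbs_sweeps(model$h, .model_J_or_null(model), state, beta,
                              as.integer(thinning))
    out[s, ] <- state[1L, ]
  }
  out <- out + 1L
  attr(out, "alphabet") <- model$alphabet
  out
}

#' Construct a low-energy synthetic wildtype
#'
#' A greedy zero-temperature quench from a random start: sites are swept and
#' set to the state of maximal conditional weight. The quench is short by
#' default (a single sweep): the result sits far below the equilibrium
#' energy bulk — like a real wildtype, which is fit but not the global
#' optimum of an inferred landscape — while still leaving beneficial
#' substitutions available, so that strong selection can decrease the energy
#' further. Running the quench to a fixed point (large `quench_sweeps`)
#' instead yields a strict local minimum. On the 21-letter alphabet the
#' result is gap free and gets a random synonymous codon assignment, giving
#' a consistent starting state for the codon-level chain.
#'
#' @param model Landscape.
#' @param seed Integer seed (used for the random start and the codon
#'   assignment).
#' @param quench_sweeps Number of greedy sweeps (the quench also stops at a
#'   fixed point).
#' @return An [evolving_state()] for the canonical alphabet, otherwise the
#'   amino acid sequence as a string.
#' @export
synthetic_wildtype <- function(model, seed = 1L, quench_sweeps = 1L) {
  set.seed(seed)
  gap <- match(AA_GAP, model$alphabet)
  states <- setdiff(seq_len(model$q), if (is.na(gap)) integer() else gap)
  a <- sample(states, model$L, replace = TRUE)
  for (sw in seq_len(quench_sweeps)) {
    changed <- FALSE
    for (i in seq_len(model$L)) {
      s <- model$h[i, states]
      if (inherits(model, "potts_model")) {
        js <- setdiff(seq_len(model$L), i)
        s <- s + vapply(states, function(b)
          sum(model$J[cbind(i, js, b, a[js])]), 0)
      }
      best <- states[which.max(s)]
      if (best != a[i]) { a[i] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  aa <- paste(model$alphabet[a], collapse = "")
  if (identical(model$alphabet, AA_ALPHABET))
    assign_codons(aa, mode = "random_synonymous", seed = seed + 1L)
  else aa
}

#' Toy Boltzmann-machine learner for Potts models
#'
#' Desk-scale maximum-likelihood inference by stochastic gradient ascent:
#' the gradient of the regularized likelihood is the gap between the
#' (pseudocounted) data one-/two-site frequencies and the model's own,
#' estimated from persistent Gibbs chains. Intended only to close the
#' inference-to-simulation loop in tests on small alphabets — it is not a
#' production DCA engine, hence the hard scale guard.
#'
#' @param msa Aligned training sample.
#' @param l2_penalty Ridge penalty on fields and couplings.
#' @param n_epochs Gradient epochs; 0 returns the profile-initialized model
#'   (fields `log` pseudocounted frequencies, zero couplings) unchanged.
#' @param mc_samples Number of persistent chains used for the model-moment
#'   estimates.
#' @param seed Integer seed.
#' @param alphabet Alphabet of the alignment (`length <= 8`).
#' @param learning_rate Base step size; decays as `1/(1 + epoch/50)`.
#' @param pseudocount Pseudocount mixing for the data frequencies.
#' @param sweeps_per_epoch Gibbs sweeps advancing the persistent chains
#'   between gradient steps.
#' @return A [potts_model()].
#' @export
toy_bm_learn <- function(msa, l2_penalty = 0.01, n_epochs = 200L,
                         mc_samples = 300L, seed = 1L,
                         alphabet = NULL, learning_rate = 0.1,
                         pseudocount = 0.01, sweeps_per_epoch = 2L) {
  if (is.null(alphabet)) alphabet <- attr(msa, "alphabet")
  if (is.null(alphabet)) alphabet <- AA_ALPHABET
  m <- as_aa_matrix(msa, alphabet)
  L <- ncol(m); q <- length(alphabet)
  if (L > 25L || q > 8L)
    stop("toy learner scale guard: needs L <= 25 and q <= 8 (got L = ",
         L, ", q = ", q, ")")
  set.seed(seed)
  one_hot <- function(mm) {
    X <- matrix(0, nrow(mm), L * q)
    for (a in seq_len(q)) X[, (seq_len(L) - 1L) * q + a] <- (mm == a) * 1
    X
  }
  mix1 <- function(f) (1 - pseudocount) * f + pseudocount / q
  mix2 <- function(f) (1 - pseudocount) * f + pseudocount / q^2
  Xd <- one_hot(m)
  fi_d <- mix1(colMeans(Xd))
  Fij_d <- mix2(crossprod(Xd) / nrow(m))
  h <- log(matrix(fi_d, L, q, byrow = TRUE))
  J <- array(0, c(L, L, q, q))
  pairs <- .pair_index(L)
  if (n_epochs > 0L) {
    chains <- matrix(sample.int(q, mc_samples * L, replace = TRUE) - 1L,
                     mc_samples, L)
    for (ep in seq_len(n_epochs)) {
      chains <- cpp_gibbs_sweeps(h, J, chains, 1, as.integer(sweeps_per_epoch))
      Xm <- one_hot(chains + 1L)
      fi_m <- colMeans(Xm)
      Fij_m <- crossprod(Xm) / mc_samples
      lr <- learning_rate / (1 + ep / 50)
      h <- h + lr * (matrix(fi_d - fi_m, L, q, byrow = TRUE) - l2_penalty * h)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1L]; j <- pairs[k, 2L]
        ii <- (i - 1L) * q + seq_len(q); jj <- (j - 1L) * q + seq_len(q)
        g <- (Fij_d[ii, jj] - Fij_m[ii, jj]) - l2_penalty * J[i, j, , ]
        J[i, j, , ] <- J[i, j, , ] + lr * g
        J[j, i, , ] <- t(J[i, j, , ])
      }
    }
  }
  potts_model(h, J, alphabet)
}
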