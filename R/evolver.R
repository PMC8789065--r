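#' Configuration of the evolutionary Monte Carlo
#'
#' Bundles the free parameters of the mutation--selection chain: the
#' selection temperature `T` (selection strength is `beta = 1/T`; small `T`
#' means strong selection as in directed evolution, large `T` near-neutral
#' accumulation), the number of mutational steps `n_steps` per chain, the
#' library size `n_chains`, and the steps at which library snapshots are
#' emitted. Every call to the one-step kernel counts as one MC step,
#' including synonymous and identity moves, so the Hamming distance to the
#' wildtype can take any value between 0 and the step count.
#'
#' @param T Selection temperature, `> 0`; `T = 0` is handled as an exact
#'   greedy (argmax) limit with uniform tie-breaking.
#' @param n_steps Number of MC steps per chain (`>= 0`).
#' @param n_chains Number of independent chains = library depth `M`.
#' @param snapshot_steps Sorted step counts at which to emit snapshots;
#'   defaults to `n_steps` only. Must lie in `[0, n_steps]`.
#' @param seed Integer seed; all chains are advanced under one seeded RNG
#'   stream so a run is exactly reproducible.
#' @param mode `"codon"` for the nucleotide-level model (substitutions
#'   restricted to single-nucleotide-accessible amino acids), `"seec"` for
#'   the amino-acid-level chain where all 20 amino acids are accessible.
#' @return Object of class `evolver_config`.
#' @export
evolver_config <- function(T = 1, n_steps = 100L, n_chains = 1L,
                           snapshot_steps = NULL, seed = 1L,
                           mode = c("codon", "seec")) {
  mode <- match.arg(mode)
  stopifnot(T >= 0, n_steps >= 0, n_chains >= 1)
  if (is.null(snapshot_steps)) snapshot_steps <- n_steps
  snapshot_steps <- sort(unique(as.integer(snapshot_steps)))
  if (any(snapshot_steps < 0L) || any(snapshot_steps > n_steps))
    stop("snapshot_steps must lie in [0, n_steps]")
  structure(list(T = T, beta = if (T > 0) 1 / T else Inf, argmax = (T == 0),
                 n_steps = as.integer(n_steps), n_chains = as.integer(n_chains),
                 snapshot_steps = snapshot_steps, seed = as.integer(seed),
                 mode = mode),
            class = "evolver_config")
}

.model_J_or_null <- function(model) {
  if (inherits(model, "potts_model")) model$J else NULL
}

.check_canonical <- function(model) {
  if (!identical(model$alphabet, AA_ALPHABET))
    stop("codon-level evolution needs the full 21-letter alphabet (q = 21)")
}

#' One step of the codon-level mutation--selection chain
#'
#' Reference (pure R) implementation of the three-step kernel:
#' (1) a site is chosen uniformly at random, re-drawn while it is a gap;
#' (2) an amino acid `b` is drawn from the accessible set of the current
#' codon with probability proportional to
#' `exp(beta * (h_i(b) + sum_j J_ij(b, a_j)))` (equivalently
#' `exp(-beta * deltaE)`); (3) one codon of `b` within one nucleotide of the
#' current codon is chosen uniformly. The fast library simulators in
#' [evolve_chain()] / [evolve_library()] implement the same kernel in
#' compiled code.
#'
#' @param state An [evolving_state()].
#' @param model A [potts_model()] or [profile_model()] on the 21-letter
#'   alphabet.
#' @param beta Inverse selection temperature (`>= 0`); ignored when
#'   `argmax = TRUE`.
#' @param argmax If `TRUE`, pick the accessible amino acid of maximal
#'   conditional weight (minimal `deltaE`), ties broken uniformly — the exact
#'   `T = 0` greedy limit.
#' @return The new [evolving_state()]; exactly one codon differs from the
#'   input by at most one nucleotide (possibly none, for the identity move).
#' @export
evolution_step <- function(state, model, beta = 1, argmax = FALSE) {
  .check_canonical(model)
  mut <- which(!is.na(state$codon))
  if (!length(mut)) stop("all-gap sequence: no mutable site")
  i <- mut[sample.int(length(mut), 1L)]
  acc <- accessible_amino_acids(state$dna[i])
  if (argmax) {
    s <- log(conditional_distribution(model, state$aa, i, acc, beta = 1))
    # the conditional at beta = 1 preserves the ordering of the local fields
    best <- which(s >= max(s) - 1e-12)
    b <- acc[best[sample.int(length(best), 1L)]]
  } else {
    p <- conditional_distribution(model, state$aa, i, acc, beta = beta)
    b <- acc[sample.int(length(acc), 1L, prob = p)]
  }
  cands <- codons_within_one(state$dna[i], b)
  new_dna <- state$dna
  new_dna[i] <- cands[sample.int(length(cands), 1L)]
  evolving_state(new_dna)
}

.codon0_vec <- function(state) {
  ifelse(is.na(state$codon), -1L, state$codon - 1L)
}

.snapshot_list <- function(arr, snapshots, alphabet) {
  S <- dim(arr)[1]
  out <- vector("list", S)
  names(out) <- as.character(snapshots)
  for (s in seq_len(S)) {
    m <- matrix(arr[s, , ], nrow = dim(arr)[2]) + 1L
    attr(m, "alphabet") <- alphabet
    out[[s]] <- m
  }
  out
}

#' Evolve a single chain and record its trajectory
#'
#' Runs `config$n_steps` steps of the evolutionary chain from the wildtype
#' and records the state at `config$snapshot_steps`, together with the
#' statistical energy and the amino acid Hamming distance to the wildtype at
#' each snapshot.
#'
#' @param wildtype An [evolving_state()] (codon mode) or an aligned amino
#'   acid sequence (seec mode).
#' @param model A [potts_model()] or [profile_model()].
#' @param config An [evolver_config()] with `n_chains = 1`.
#' @return Object of class `trajectory`: data frame columns `step`, `energy`,
#'   `hamming`, plus the snapshot sequences as attribute `"states"` (integer
#'   matrix, one row per snapshot) and, in codon mode, `"dna"` (character).
#' @export
evolve_chain <- function(wildtype, model, config) {
  config$n_chains <- 1L
  lib <- evolve_library(wildtype, model, config,
                        return_codons = (config$mode == "codon"))
  steps <- config$snapshot_steps
  wt_aa <- attr(lib, "wildtype_aa")
  states <- do.call(rbind, lapply(lib$snapshots, function(m) m[1L, ]))
  en <- vapply(seq_along(steps), function(s) energy(model, states[s, ]), 0)
  hd <- apply(states, 1L, function(a) sum(a != wt_aa))
  out <- data.frame(step = steps, energy = en, hamming = as.integer(hd))
  attr(out, "states") <- states
  if (!is.null(lib$dna)) attr(out, "dna") <- lapply(lib$dna, function(d) d[1L, ])
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Simulate an evolved sequence library
#'
#' Starts `config$n_chains` independent chains from the wildtype and returns
#' one aligned library (integer sequence matrix) per snapshot step. All
#' chains share one seeded RNG stream, so two runs with the same config are
#' identical; snapshots reuse the same chains across increasing step counts
#' (one long run per chain), mirroring the subsample-from-the-deepest-library
#' scheme used to keep simulation cost down.
#'
#' @inheritParams evolve_chain
#' @param config An [evolver_config()].
#' @param return_codons Keep the codon-level snapshots (codon mode only).
#' @return Object of class `evolved_library`: list with `snapshots` (named
#'   list, step -> `M x L` integer sequence matrix) and optionally `dna`;
#'   attributes `wildtype_aa`, `config`.
#' @export
evolve_library <- function(wildtype, model, config, return_codons = FALSE) {
  stopifnot(inherits(config, "evolver_config"))
  set.seed(config$seed)
  snaps <- config$snapshot_steps
  if (config$mode == "codon") {
    .check_canonical(model)
    if (is.character(wildtype)) wildtype <- assign_codons(wildtype)
    stopifnot(inherits(wildtype, "evolving_state"))
    cd <- .codon_data()
    res <- cpp_evolve_library(model$h, .model_J_or_null(model),
                              wildtype$aa - 1L, .codon0_vec(wildtype),
                              ifelse(is.na(cd$aa_idx), -1L, cd$aa_idx - 1L),
                              beta = if (config$argmax) 0 else config$beta,
                              argmax = config$argmax,
                              snapshots = snaps, M = config$n_chains,
                              return_codons = return_codons, check = FALSE)
    out <- list(snapshots = .snapshot_list(res$aa, snaps, model$alphabet))
    if (return_codons) {
      S <- length(snaps)
      out$dna <- lapply(seq_len(S), function(s) {
        ci <- matrix(res$codon[s, , ], nrow = config$n_chains)
        dna <- matrix(CODONS[ci + 1L], nrow = config$n_chains)
        dna[ci < 0L] <- "---"
        dna
      })
      names(out$dna) <- as.character(snaps)
    }
    wt_aa <- wildtype$aa
  } else {
    aa0 <- if (inherits(wildtype, "evolving_state")) wildtype$aa
           else as_aa_matrix(wildtype, model$alphabet)[1L, ]
    gap <- match(AA_GAP, model$alphabet)
    allowed <- setdiff(seq_len(model$q), if (is.na(gap)) integer() else gap)
    arr <- cpp_seec_library(model$h, .model_J_or_null(model), aa0 - 1L,
                            allowed - 1L,
                            gap_state = if (is.na(gap)) -1L else gap - 1L,
                            beta = if (config$argmax) 0 else config$beta,
                            argmax = config$argmax,
                            snapshots = snaps, M = config$n_chains)
    out <- list(snapshots = .snapshot_list(arr, snaps, model$alphabet))
    wt_aa <- aa0
  }
  attr(out, "wildtype_aa") <- wt_aa
  attr(out, "config") <- config
  class(out) <- "evolved_library"
  out
}

#' @export
print.evolved_library <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Evolved library: %d chains, T = %g, mode = %s\n snapshots at steps: %s\n",
              cfg$n_chains, cfg$T, cfg$mode,
              paste(names(x$snapshots), collapse = ", ")))
  invisible(x)
}

#' Subsample an aligned library without replacement
#'
#' Smaller libraries are drawn from the deepest simulated one by seeded
#' sampling without replacement, the same scheme used for the depth scans.
#'
#' @param msa Integer sequence matrix.
#' @param size Number of sequences to keep (`<= nrow(msa)`).
#' @param seed Optional integer seed.
#' @return Integer sequence matrix with `size` rows.
#' @export
subsample_msa <- function(msa, size, seed = NULL) {
  if (size > nrow(msa)) stop("subsample size exceeds library size")
  if (!is.null(seed)) set.seed(seed)
  keep <- sample.int(nrow(msa), size)
  out <- msa[keep, , drop = FALSE]
  attr(out, "alphabet") <- attr(msa, "alphabet")
  out
}

#' Per-sequence energies of an aligned library
#'
#' @param model A [potts_model()] or [profile_model()].
#' @param msa Integer sequence matrix (or character sequences).
#' @return Numeric vector of statistical energies, one per sequence.
#' @export
msa_energies <- function(model, msa) {
  m <- as_aa_matrix(msa, model$alphabet)
  cpp_msa_energy(model$h, .model_J_or_null(model), m - 1L)
}
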