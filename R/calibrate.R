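#' Slope of statistical energy against Hamming distance
#'
#' Ordinary least-squares fit of the per-sequence energy difference to the
#' wildtype, `dE = E(seq) - E(wildtype)`, against the amino acid Hamming
#' distance, with free intercept. The slope (energy units per substitution)
#' is the statistic used to calibrate the selection temperature against a
#' reference library: strong selection gives a negative or shallow slope,
#' weak selection a steep positive one. A `binned` variant fits the
#' per-distance mean energies instead.
#'
#' @param msa Aligned library.
#' @param model A [potts_model()] or [profile_model()].
#' @param wildtype Wildtype sequence.
#' @param binned If `TRUE`, fit the per-distance means rather than the
#'   per-sequence points.
#' @return List with `slope`, `intercept`, `stderr` (of the slope), `n`.
#' @export
energy_vs_distance_slope <- function(msa, model, wildtype, binned = FALSE) {
  m <- as_aa_matrix(msa, model$alphabet)
  wt <- if (inherits(wildtype, "evolving_state")) wildtype$aa
        else .seq_to_idx(model, wildtype)
  dE <- msa_energies(model, m) - energy(model, wt)
  d <- .hamming_to_ref(m, wt)
  if (binned) {
    agg <- split(dE, d)
    dE <- vapply(agg, mean, 0)
    d <- as.numeric(names(agg))
  }
  if (length(unique(d)) < 2L)
    stop("degenerate design: all sequences at a single Hamming distance")
  fit <- stats::lm(dE ~ d)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["d", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       stderr = unname(sm["d", "Std. Error"]),
       n = length(dE))
}

.pilot_snap_grid <- function(budget) {
  g <- unique(c(0L, round(exp(seq(0, log(max(budget, 1L)), length.out = 25L)))))
  sort(unique(as.integer(pmin(g, budget))))
}

#' Calibrate the chain length to a target divergence
#'
#' Runs a pilot library with snapshots on a log-spaced step grid up to
#' `budget` steps and returns the snapshot step whose mean Hamming distance
#' to the wildtype is closest to `target_mean_hamming` (smallest such step on
#' ties). This is how the number of MC steps is matched to the average number
#' of substituted amino acids of a reference library.
#'
#' @param model Landscape.
#' @param wildtype Wildtype ([evolving_state()] in codon mode).
#' @param T Selection temperature for the pilot runs.
#' @param target_mean_hamming Target mean amino acid Hamming distance; must
#'   not exceed the number of non-gap sites.
#' @param budget Maximum number of MC steps explored.
#' @param n_pilot Pilot library depth.
#' @param seed Integer seed.
#' @param mode Chain mode, as in [evolver_config()].
#' @return List with `fitted_steps`, and `diagnostics` (step vs achieved mean
#'   distance).
#' @export
fit_chain_length <- function(model, wildtype, T, target_mean_hamming,
                             budget = 2000L, n_pilot = 200L, seed = 1L,
                             mode = "codon") {
  wt_aa <- if (inherits(wildtype, "evolving_state")) wildtype$aa
           else as_aa_matrix(wildtype, model$alphabet)[1L, ]
  gap <- match(AA_GAP, model$alphabet)
  n_mut <- if (is.na(gap)) length(wt_aa) else sum(wt_aa != gap)
  if (target_mean_hamming > n_mut)
    stop("target mean distance exceeds the number of non-gap sites (", n_mut, ")")
  if (target_mean_hamming == 0)
    return(list(fitted_steps = 0L,
                diagnostics = data.frame(step = 0L, mean_hamming = 0)))
  snaps <- .pilot_snap_grid(budget)
  cfg <- evolver_config(T = T, n_steps = max(snaps), n_chains = n_pilot,
                        snapshot_steps = snaps, seed = seed, mode = mode)
  lib <- evolve_library(wildtype, model, cfg)
  mh <- vapply(lib$snapshots, function(m) mean(.hamming_to_ref(m, wt_aa)), 0)
  diag <- data.frame(step = snaps, mean_hamming = unname(mh))
  best <- which.min(abs(mh - target_mean_hamming))
  list(fitted_steps = snaps[best], diagnostics = diag)
}

#' Calibrate the selection temperature against a reference library
#'
#' For each candidate temperature, the chain length is first matched to the
#' reference's mean Hamming distance ([fit_chain_length()]), a pilot library
#' is simulated at the fitted length, and its energy-versus-distance slope is
#' compared with the reference's. The returned temperature minimizes the
#' absolute slope mismatch; a second, finer local grid around the best coarse
#' candidate refines it. Common random numbers (the same seed) are used for
#' every candidate so the noisy objective is comparable across the grid.
#'
#' @inheritParams fit_chain_length
#' @param reference_msa Reference aligned library (sequences over the model
#'   alphabet), e.g. an experimental library or a simulation to be recovered.
#' @param T_grid Positive candidate temperatures (coarse stage).
#' @param budget Maximum MC steps for the length calibration.
#' @param n_pilot Pilot depth per candidate.
#' @param pilot_replicates Pilot libraries per candidate; their slopes are
#'   averaged, which suppresses the sampling noise of the objective.
#' @param refine Number of extra candidates in the local refinement stage
#'   (0 disables refinement).
#' @return Object of class `calibration_result`: list with `fitted_T`,
#'   `fitted_steps`, `target_mean_hamming`, `target_slope`, `diagnostics`
#'   (one row per candidate: T, steps, slope, objective).
#' @export
fit_temperature <- function(model, wildtype, reference_msa,
                            T_grid = exp(seq(log(0.25), log(8), length.out = 9)),
                            budget = 2000L, n_pilot = 500L, seed = 1L,
                            mode = "codon", pilot_replicates = 3L, refine = 5L) {
  if (!length(T_grid) || any(T_grid <= 0)) stop("T_grid must be positive")
  wt_aa <- if (inherits(wildtype, "evolving_state")) wildtype$aa
           else as_aa_matrix(wildtype, model$alphabet)[1L, ]
  ref <- as_aa_matrix(reference_msa, model$alphabet)
  target_d <- mean(.hamming_to_ref(ref, wt_aa))
  ref_slope <- energy_vs_distance_slope(ref, model, wt_aa)$slope
  eval_T <- function(T) {
    fl <- fit_chain_length(model, wildtype, T, target_d, budget = budget,
                           n_pilot = n_pilot, seed = seed, mode = mode)
    if (fl$fitted_steps == 0L) return(list(steps = 0L, slope = NA_real_))
    # common random numbers: the same pilot seeds are reused for every
    # candidate T, so the noisy objective is comparable across the grid
    sl <- vapply(seq_len(pilot_replicates), function(r) {
      cfg <- evolver_config(T = T, n_steps = fl$fitted_steps,
                            n_chains = n_pilot, seed = seed + r, mode = mode)
      lib <- evolve_library(wildtype, model, cfg)
      tryCatch(
        energy_vs_distance_slope(lib$snapshots[[1L]], model, wt_aa)$slope,
        error = function(e) NA_real_)
    }, 0)
    list(steps = fl$fitted_steps, slope = mean(sl))
  }
  run_grid <- function(grid) {
    rows <- lapply(grid, function(T) {
      ev <- eval_T(T)
      data.frame(T = T, steps = ev$steps, slope = ev$slope,
                 objective = abs(ev$slope - ref_slope))
    })
    do.call(rbind, rows)
  }
  diag <- run_grid(sort(T_grid))
  ok <- which(is.finite(diag$objective))
  if (!length(ok)) stop("no candidate temperature produced a usable slope")
  best <- ok[which.min(diag$objective[ok])]
  if (refine > 0L && length(T_grid) > 1L) {
    lo <- if (best > 1L) diag$T[best - 1L] else diag$T[best] / 1.6
    hi <- if (best < nrow(diag)) diag$T[best + 1L] else diag$T[best] * 1.6
    fine <- exp(seq(log(lo), log(hi), length.out = refine + 2L))
    fine <- setdiff(round(fine, 10), round(diag$T, 10))
    if (length(fine)) {
      diag <- rbind(diag, run_grid(fine))
      diag <- diag[order(diag$T), , drop = FALSE]
    }
    ok <- which(is.finite(diag$objective))
    best <- ok[which.min(diag$objective[ok])]
  }
  # slope is monotone in T, so invert a local linear fit of slope on log T
  # around the best candidate: this pools the grid evaluations, suppressing
  # both pointwise noise and grid quantization
  fitted_T <- diag$T[best]
  fitted_steps <- diag$steps[best]
  win <- ok[abs(log(diag$T[ok] / fitted_T)) <= log(2.3)]
  if (length(win) >= 4L) {
    lf <- stats::lm(slope ~ lT, data.frame(slope = diag$slope[win],
                                           lT = log(diag$T[win])))
    b <- stats::coef(lf)
    if (is.finite(b[2L]) && b[2L] > 0) {
      T_hat <- exp((ref_slope - b[1L]) / b[2L])
      T_hat <- min(max(T_hat, min(diag$T[win])), max(diag$T[win]))
      fitted_T <- unname(T_hat)
      fitted_steps <- fit_chain_length(model, wildtype, fitted_T, target_d,
                                       budget = budget, n_pilot = n_pilot,
                                       seed = seed, mode = mode)$fitted_steps
    }
  }
  structure(list(fitted_T = fitted_T, fitted_steps = fitted_steps,
                 target_mean_hamming = target_d, target_slope = ref_slope,
                 diagnostics = diag),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("Calibration: fitted T = %.3g (steps = %d)\n",
                     " target mean distance = %.2f, target slope = %.3g\n",
                     " %d candidates evaluated\n"),
              x$fitted_T, x$fitted_steps, x$target_mean_hamming,
              x$target_slope, nrow(x$diagnostics)))
  invisible(x)
}

#' Slope estimation error under library subsampling
#'
#' Repeatedly subsamples a library without replacement at each requested
#' size, refits the energy-versus-distance slope, and reports the dispersion
#' of the estimates — quantifying how many sequences are needed before the
#' slope stabilizes.
#'
#' @inheritParams energy_vs_distance_slope
#' @param sizes Subsample sizes (each `<= nrow(msa)`).
#' @param replicates Subsamples per size.
#' @param seed Integer seed.
#' @return Data frame with columns `size`, `slope_mean`, `slope_sd`,
#'   `replicates`.
#' @export
slope_subsample_error <- function(msa, model, wildtype, sizes,
                                  replicates = 20L, seed = 1L) {
  m <- as_aa_matrix(msa, model$alphabet)
  if (any(sizes > nrow(m))) stop("subsample size exceeds library size")
  set.seed(seed)
  rows <- lapply(sizes, function(s) {
    sl <- vapply(seq_len(replicates), function(r) {
      sub <- m[sample.int(nrow(m), s), , drop = FALSE]
      energy_vs_distance_slope(sub, model, wildtype)$slope
    }, 0)
    data.frame(size = s, slope_mean = mean(sl), slope_sd = stats::sd(sl),
               replicates = replicates)
  })
  do.call(rbind, rows)
}
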