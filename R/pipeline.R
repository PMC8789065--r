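#' Null quantile of the PPV under random ranking
#'
#' The number of true contacts among `n_predictions` pairs drawn at random
#' from the eligible set is hypergeometric; this returns the given quantile
#' of the corresponding PPV, the threshold below which a prediction is
#' indistinguishable from the permutation null.
#'
#' @param map A [contact_map()].
#' @param n_predictions Number of top pairs evaluated.
#' @param prob Quantile (default 0.95).
#' @return PPV value in `[0, 1]`.
#' @export
ppv_null_quantile <- function(map, n_predictions = 100L, prob = 0.95) {
  el <- nrow(.eligible_pairs(map$L, map$min_separation))
  K <- nrow(map$pairs)
  stats::qhyper(prob, K, el - K, n_predictions) / n_predictions
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.config_model <- function(config) {
  if (inherits(config$model, c("potts_model", "profile_model")))
    return(config$model)
  stopifnot(!is.null(config$model_file), !is.null(config$L))
  q <- if (is.null(config$q)) 21L else config$q
  read_potts_params(config$model_file, L = config$L, q = q)
}

.config_wildtype <- function(config, model) {
  wt <- config$wildtype
  if (inherits(wt, "evolving_state")) return(wt)
  if (is.null(wt) && !is.null(config$wildtype_file))
    wt <- aa_strings(read_msa(config$wildtype_file, model$alphabet))[1L]
  if (is.null(wt)) stop("config needs a wildtype (or wildtype_file)")
  if (!is.null(config$wildtype_dna))
    return(assign_codons(wt, mode = "given_dna", dna = config$wildtype_dna))
  if (identical(model$alphabet, AA_ALPHABET))
    assign_codons(wt, seed = config$seed) else wt
}

.write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Workflow: compare predicted and measured mutational effects
#'
#' Runs the full single-mutant energy scan of the epistatic model and of a
#' non-epistatic profile baseline, and rank-correlates the predictions with
#' an external per-mutation effect table (e.g. a deep mutational scan).
#' Because low energies mean high fitness, a good model shows a strongly
#' negative Spearman correlation between `dE` and measured fitness effects.
#'
#' @param config List (or YAML path) with: `model` (or `model_file` + `L`),
#'   `wildtype` (string or state), `effects` (data frame or TSV path with
#'   columns `site`, `aa`, `effect`), optional `profile` (a
#'   [profile_model()]) or `natural_msa` to fit one from; otherwise the
#'   profile baseline is fitted to an equilibrium sample of the model
#'   itself. Optional `out_dir`, `seed`.
#' @return Report list: `spearman_potts`, `spearman_profile`, `scan_potts`,
#'   `scan_profile`, `n_effects`, `config`.
#' @export
run_mutational_comparison <- function(config) {
  config <- .load_config(config)
  model <- .config_model(config)
  wt <- .config_wildtype(config, model)
  wt_aa <- if (inherits(wt, "evolving_state")) wt$aa
           else as_aa_matrix(wt, model$alphabet)[1L, ]
  eff <- config$effects
  if (is.character(eff)) eff <- utils::read.table(eff, header = TRUE, sep = "\t")
  stopifnot(all(c("site", "aa", "effect") %in% names(eff)))
  prof <- config$profile
  if (is.null(prof)) {
    nat <- config$natural_msa
    if (is.null(nat))
      nat <- gibbs_sample(model, n_sequences = 2000L, seed = config$seed)
    prof <- profile_from_msa(nat, pseudocount = 0.01,
                             alphabet = model$alphabet)
  }
  scan_p <- mutant_scan(model, wt_aa)
  scan_f <- mutant_scan(prof, wt_aa)
  pick <- function(scan) {
    idx <- cbind(eff$site, match(eff$aa, colnames(scan)))
    if (anyNA(idx) || any(eff$site < 1L) || any(eff$site > nrow(scan)))
      stop("effect table has positions or amino acids outside the scan")
    scan[idx]
  }
  de_p <- pick(scan_p); de_f <- pick(scan_f)
  keep <- !is.na(de_p) & !is.na(de_f)
  rep <- list(
    spearman_potts = stats::cor(de_p[keep], eff$effect[keep], method = "spearman"),
    spearman_profile = stats::cor(de_f[keep], eff$effect[keep], method = "spearman"),
    scan_potts = scan_p, scan_profile = scan_f,
    n_effects = sum(keep), config = config)
  .write_tsv(data.frame(site = eff$site, aa = eff$aa, effect = eff$effect,
                        dE_potts = de_p, dE_profile = de_f),
             config$out_dir, "mutational_comparison.tsv")
  rep
}

#' Workflow: forecast an evolution experiment
#'
#' Optionally calibrates `(T, steps)` against a reference library, then
#' simulates libraries over a protocol grid and reports the statistics an
#' experimentalist would use to choose a protocol: mean divergence,
#' energy-versus-distance slope, site frequency spectra and — when a contact
#' map is supplied — a PPV grid per selection temperature.
#'
#' @param config List (or YAML path) with `model`, `wildtype` (as in
#'   [run_mutational_comparison()]), optional `reference_msa` (matrix or
#'   FASTA path) to calibrate against, `T_values`, `snapshot_steps`,
#'   `library_sizes`, optional `map` (a [contact_map()]), `n_replicates`,
#'   `out_dir`, `seed`.
#' @return Report list: `calibration` (or `NULL`), `library_stats` (data
#'   frame), `scan` (output of [parameter_scan()], or `NULL`), `config`.
#' @export
run_forecast <- function(config) {
  config <- .load_config(config)
  model <- .config_model(config)
  wt <- .config_wildtype(config, model)
  mode <- if (identical(model$alphabet, AA_ALPHABET)) "codon" else "seec"
  calib <- NULL
  T_values <- config$T_values
  if (!is.null(config$reference_msa)) {
    ref <- config$reference_msa
    if (is.character(ref) && length(ref) == 1L && file.exists(ref))
      ref <- read_msa(ref, model$alphabet)
    calib <- fit_temperature(model, wt, ref, seed = config$seed, mode = mode)
    if (is.null(T_values)) T_values <- calib$fitted_T
  }
  if (is.null(T_values)) T_values <- 1
  steps <- config$snapshot_steps
  if (is.null(steps))
    steps <- if (!is.null(calib)) calib$fitted_steps else 100L
  sizes <- if (is.null(config$library_sizes)) 200L else config$library_sizes
  wt_aa <- if (inherits(wt, "evolving_state")) wt$aa
           else as_aa_matrix(wt, model$alphabet)[1L, ]
  rows <- list()
  for (T in T_values) {
    cfg <- evolver_config(T = T, n_steps = max(steps), n_chains = max(sizes),
                          snapshot_steps = steps,
                          seed = config$seed + round(1000 * T), mode = mode)
    lib <- evolve_library(wt, model, cfg)
    for (st in names(lib$snapshots)) {
      m <- lib$snapshots[[st]]
      sl <- tryCatch(energy_vs_distance_slope(m, model, wt_aa),
                     error = function(e) list(slope = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        T = T, steps = as.integer(st), M = nrow(m),
        mean_hamming = mean(.hamming_to_ref(m, wt_aa)),
        slope = sl$slope)
    }
  }
  stats_df <- do.call(rbind, rows)
  scan <- NULL
  if (!is.null(config$map)) {
    scan <- parameter_scan(model, wt, T_values, steps, sizes, config$map,
                           n_replicates = if (is.null(config$n_replicates)) 5L
                                          else config$n_replicates,
                           n_predictions = if (is.null(config$n_predictions))
                             100L else config$n_predictions,
                           seed = config$seed, mode = mode)
    .write_tsv(scan$grid, config$out_dir, "forecast_ppv_grid.tsv")
  }
  .write_tsv(stats_df, config$out_dir, "forecast_library_stats.tsv")
  list(calibration = calib, library_stats = stats_df, scan = scan,
       config = config)
}

#' Workflow: scan for the emergence of epistatic signal
#'
#' Delegates to [parameter_scan()] and annotates every cell of the
#' divergence-by-depth grid with its mean divergence and whether its mean
#' PPV is statistically indistinguishable from the random-ranking null
#' (below the hypergeometric null quantile).
#'
#' @param config List (or YAML path) with `model`, `wildtype`, `map`, and
#'   optionally `T_values`, `snapshot_steps`, `library_sizes`,
#'   `n_replicates`, `n_predictions`, `out_dir`, `seed`.
#' @return Report list: `grid` (with added logical column `null_like`),
#'   `cells`, `null_quantile`, `config`.
#' @export
run_emergence_scan <- function(config) {
  config <- .load_config(config)
  model <- .config_model(config)
  wt <- .config_wildtype(config, model)
  stopifnot(inherits(config$map, "contact_map"))
  mode <- if (identical(model$alphabet, AA_ALPHABET)) "codon" else "seec"
  n_pred <- if (is.null(config$n_predictions)) 100L else config$n_predictions
  scan <- parameter_scan(
    model, wt,
    T_values = if (is.null(config$T_values)) 1 else config$T_values,
    snapshot_steps = if (is.null(config$snapshot_steps)) 100L
                     else config$snapshot_steps,
    library_sizes = if (is.null(config$library_sizes)) 200L
                    else config$library_sizes,
    map = config$map,
    n_replicates = if (is.null(config$n_replicates)) 5L else config$n_replicates,
    n_predictions = n_pred, seed = config$seed, mode = mode)
  nq <- ppv_null_quantile(config$map, n_pred)
  grid <- scan$grid
  grid$null_like <- grid$mean_ppv <= nq
  .write_tsv(grid, config$out_dir, "emergence_scan.tsv")
  list(grid = grid, cells = scan$cells, null_quantile = nq, config = config)
}
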