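test_that("random landscapes plant couplings exactly on the contact graph", {
  rp <- random_potts(20, 4, edge_prob = 0.2, seed = 91)
  # non-edges carry exactly zero coupling blocks, edges strictly positive norm
  edge_key <- rp$map$pairs[, 1] * 100 + rp$map$pairs[, 2]
  for (i in 1:19) for (j in (i + 1):20) {
    nrm <- sqrt(sum(rp$model$J[i, j, , ]^2))
    if ((i * 100 + j) %in% edge_key) expect_gt(nrm, 0)
    # pairs below the separation filter may carry couplings but are not
    # in the returned map
    else if (j - i >= rp$map$min_separation) expect_equal(nrm, 0)
  }
  # zero-sum gauge
  expect_lt(max(abs(rowSums(rp$model$h))), 1e-10)

  # no couplings at zero coupling scale
  rp0 <- random_potts(10, 4, coupling_scale = 0, seed = 92)
  expect_true(all(rp0$model$J == 0))
  expect_equal(nrow(rp0$map$pairs), 0L)

  # determinism
  rp2 <- random_potts(20, 4, edge_prob = 0.2, seed = 91)
  expect_identical(rp2$model$J, rp$model$J)
  expect_identical(rp2$map$pairs, rp$map$pairs)

  # alternative topologies produce the expected edge structure
  ch <- random_potts(10, 4, topology = "chain", seed = 93, min_separation = 1)
  expect_equal(nrow(ch$map$pairs), 9L)
})

test_that("Gibbs sampling is uniform on the flat model and seed-stable", {
  al <- default_alphabet(4)
  flat <- potts_model(matrix(0, 4, 4), array(0, c(4, 4, 4, 4)), al)
  m <- gibbs_sample(flat, 10000, burn_in = 20, thinning = 1, seed = 94)
  f <- site_frequencies(m, alphabet = al)$values
  sigma <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(f - 0.25) < 3.6 * sigma))
  expect_identical(gibbs_sample(flat, 50, seed = 95),
                   gibbs_sample(flat, 50, seed = 95))
})

test_that("Gibbs sampling reaches the exact Boltzmann distribution", {
  m <- rand_small_potts(3, 3, seed = 96)
  states <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  E <- apply(states, 1, function(s) oracle_energy(m, s))
  p_exact <- exp(-E) / sum(exp(-E))
  samp <- gibbs_sample(m, 40000, burn_in = 50, thinning = 2, seed = 97)
  id <- (samp[, 1] - 1) + 3 * (samp[, 2] - 1) + 9 * (samp[, 3] - 1)
  id_exact <- (states[, 1] - 1) + 3 * (states[, 2] - 1) + 9 * (states[, 3] - 1)
  p_emp <- tabulate(id + 1, nbins = 27)[order(id_exact)]
  p_emp <- p_emp / sum(p_emp)
  expect_lt(0.5 * sum(abs(p_emp - p_exact[order(id_exact)])), 0.02)
})

test_that("synthetic wildtypes are deep local minima with consistent codons", {
  # fields-only landscape: the quench ends at the per-site argmax
  al <- default_alphabet(4)
  set.seed(98)
  h <- matrix(rnorm(8 * 4), 8, 4)
  pm <- profile_model(h, al)
  wt <- synthetic_wildtype(pm, seed = 99)
  expect_identical(wt, paste(al[apply(h, 1, which.max)], collapse = ""))

  rp <- random_potts(20, 21, seed = 100)
  wt21 <- synthetic_wildtype(rp$model, seed = 101)
  expect_s3_class(wt21, "evolving_state")
  expect_identical(translate_codons(paste(wt21$dna, collapse = "")),
                   state_aa(wt21))
  expect_identical(synthetic_wildtype(rp$model, seed = 101)$dna, wt21$dna)
  # lower energy than the bulk of the equilibrium ensemble
  eq <- gibbs_sample(rp$model, 400, burn_in = 100, thinning = 3, seed = 102)
  expect_lte(energy(rp$model, wt21$aa),
             median(msa_energies(rp$model, eq)))
})

test_that("the toy Boltzmann machine recovers fields and matches marginals", {
  al <- default_alphabet(4)
  set.seed(103)
  h <- matrix(rnorm(10 * 4), 10, 4)
  truth <- profile_model(h, al)
  msa <- gibbs_sample(truth, 5000, burn_in = 50, thinning = 1, seed = 104)

  # zero epochs: the profile-initialized model, couplings identically zero
  init <- toy_bm_learn(msa, n_epochs = 0, alphabet = al)
  f <- site_frequencies(msa, alphabet = al)$values
  expect_equal(init$h, log(0.99 * f + 0.01 / 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(init$J == 0))

  fit <- toy_bm_learn(msa, n_epochs = 200, mc_samples = 300, seed = 105,
                      alphabet = al)
  # data were independent-site: learned couplings stay at the
  # regularization floor, field ranks recovered
  expect_lt(max(abs(fit$J)), 0.15)
  ctr <- function(x) as.vector(x - rowMeans(x))
  expect_gt(cor(ctr(h), ctr(fit$h), method = "spearman"), 0.9)

  # one-site marginals of the fitted model match the data within 0.02
  samp <- gibbs_sample(fit, 5000, burn_in = 100, thinning = 1, seed = 106)
  f_fit <- site_frequencies(samp, alphabet = al)$values
  expect_lt(max(abs(f_fit - f)), 0.02)

  expect_error(toy_bm_learn(matrix(1L, 3, 30), alphabet = al), "guard")
})

test_that("the full loop from landscape to contact recovery closes", {
  # landscape -> equilibrium sample -> toy inference -> evolution ->
  # DCA scoring: planted contacts re-emerge above the null baseline
  al <- default_alphabet(4)
  rp <- random_potts(20, 4, edge_prob = 0.25, coupling_scale = 1.2,
                     field_scale = 0.5, seed = 107, min_separation = 3)
  msa <- gibbs_sample(rp$model, 4000, burn_in = 150, thinning = 2, seed = 108)
  fit <- toy_bm_learn(msa, n_epochs = 250, mc_samples = 400, seed = 109,
                      alphabet = al)
  wt <- synthetic_wildtype(fit, seed = 110)
  cfg <- evolver_config(T = 1, n_steps = 250, n_chains = 1500, seed = 111,
                        mode = "seec")
  lib <- evolve_library(wt, fit, cfg)$snapshots[[1]]
  map <- contact_map(20, rp$map$pairs, min_separation = 3)
  sc <- apc_correction(gauss_dca_scores(lib, pseudocount = 0.3, alphabet = al))
  n_top <- min(10L, nrow(map$pairs))
  expect_gt(ppv(sc, map, n_top), 2 * ppv_null_baseline(map))
})
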