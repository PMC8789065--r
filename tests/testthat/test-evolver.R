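test_that("evolver_config validates its invariants", {
  expect_error(evolver_config(T = 1, n_steps = 10, snapshot_steps = c(0, 11)),
               "snapshot_steps")
  cfg <- evolver_config(T = 0, n_steps = 5)
  expect_true(cfg$argmax)
  expect_identical(cfg$snapshot_steps, 5L)
})

test_that("a single step changes at most one codon by one nucleotide", {
  fx <- fixture_landscape(seed = 21)
  set.seed(22)
  st <- fx$wt
  for (k in 1:200) {
    new <- evolution_step(st, fx$model, beta = 1)
    # consistency: translation matches amino acids, stop-free by construction
    expect_identical(translate_codons(paste(new$dna, collapse = "")),
                     state_aa(new))
    diff <- which(new$dna != st$dna)
    expect_lte(length(diff), 1L)
    if (length(diff) == 1L) {
      nt_diff <- sum(strsplit(new$dna[diff], "")[[1]] !=
                     strsplit(st$dna[diff], "")[[1]])
      expect_lte(nt_diff, 1L)
    }
    st <- new
  }
})

test_that("gap positions are never touched and gaps never created", {
  rp <- random_potts(10, 21, seed = 23)
  wt <- assign_codons("AC-DEFG-HI", seed = 24)
  cfg <- evolver_config(T = 2, n_steps = 500, n_chains = 20, seed = 25)
  lib <- evolve_library(wt, rp$model, cfg)
  final <- lib$snapshots[[1]]
  gap_idx <- match("-", AA_ALPHABET)
  expect_true(all(final[, c(3, 8)] == gap_idx))
  expect_true(all(final[, -c(3, 8)] != gap_idx))
})

test_that("greedy (T = 0) trajectories never increase the energy", {
  fx <- fixture_landscape(seed = 26)
  cfg <- evolver_config(T = 0, n_steps = 60, snapshot_steps = 0:60, seed = 27)
  tr <- evolve_chain(fx$wt, fx$model, cfg)
  expect_true(all(diff(tr$energy) <= 1e-9))
})

test_that("trajectories respect step-count bounds and the argmax retention limit", {
  fx <- fixture_landscape(seed = 28)
  cfg <- evolver_config(T = 1, n_steps = 40, snapshot_steps = c(0, 5, 20, 40),
                        seed = 29)
  tr <- evolve_chain(fx$wt, fx$model, cfg)
  expect_identical(tr$step, c(0L, 5L, 20L, 40L))
  expect_true(all(tr$hamming <= tr$step))
  expect_equal(tr$hamming[1], 0L)

  # n_steps = 0: the wildtype itself
  tr0 <- evolve_chain(fx$wt, fx$model, evolver_config(T = 1, n_steps = 0))
  expect_equal(tr0$hamming, 0L)
  expect_equal(tr0$energy, energy(fx$model, fx$wt$aa))

  # fields-only model whose wildtype is the strict per-site argmax: at T = 0
  # the amino acid sequence can never change (synonymous moves only)
  set.seed(30)
  h <- matrix(rnorm(12 * 21), 12, 21)
  h[, 1] <- -20  # keep gaps out of reach
  pm <- profile_model(h, AA_ALPHABET)
  wt_aa <- paste(AA_ALPHABET[apply(h, 1, which.max)], collapse = "")
  wt <- assign_codons(wt_aa, seed = 31)
  trg <- evolve_chain(wt, pm, evolver_config(T = 0, n_steps = 300, seed = 32))
  expect_equal(trg$hamming[length(trg$hamming)], 0L)
})

test_that("mean divergence grows with the number of steps", {
  fx <- fixture_landscape(seed = 33)
  cfg <- evolver_config(T = 1, n_steps = 400, n_chains = 150,
                        snapshot_steps = c(10, 50, 150, 400), seed = 34)
  lib <- evolve_library(fx$wt, fx$model, cfg)
  mh <- vapply(lib$snapshots, mean_hamming_to, 0, ref = fx$wt$aa)
  expect_true(all(diff(mh) > 0))
})

test_that("libraries are reproducible and snapshot 0 is the wildtype", {
  fx <- fixture_landscape(seed = 35)
  cfg <- evolver_config(T = 1.4, n_steps = 50, n_chains = 30,
                        snapshot_steps = c(0, 50), seed = 36)
  lib1 <- evolve_library(fx$wt, fx$model, cfg)
  lib2 <- evolve_library(fx$wt, fx$model, cfg)
  expect_identical(lib1$snapshots, lib2$snapshots)
  s0 <- lib1$snapshots[["0"]]
  expect_true(all(t(s0) == fx$wt$aa))
  # different seeds give different libraries
  cfg2 <- evolver_config(T = 1.4, n_steps = 50, n_chains = 30,
                         snapshot_steps = c(0, 50), seed = 37)
  expect_false(identical(evolve_library(fx$wt, fx$model, cfg2)$snapshots,
                         lib1$snapshots))
})

test_that("codon-level state stays consistent over a long stress run", {
  fx <- fixture_landscape(seed = 38)
  cfg <- evolver_config(T = 2, n_steps = 10000,
                        snapshot_steps = seq(0, 10000, by = 500), seed = 39)
  lib <- evolve_library(fx$wt, fx$model, cfg, return_codons = TRUE)
  for (s in names(lib$snapshots)) {
    dna <- lib$dna[[s]][1, ]
    aa <- lib$snapshots[[s]][1, ]
    expect_identical(translate_codons(paste(dna, collapse = "")),
                     paste(AA_ALPHABET[aa], collapse = ""))
  }
})

test_that("subsampling without replacement is seeded and bounded", {
  m <- matrix(sample.int(4, 200, replace = TRUE), 50, 4)
  s1 <- subsample_msa(m, 20, seed = 5)
  s2 <- subsample_msa(m, 20, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 20L)
  expect_error(subsample_msa(m, 51), "exceeds")
})

test_that("seec mode explores all amino acids while codon mode is restricted", {
  # from a tryptophan-only wildtype, codon moves can only reach A_acc(TGG),
  # while the amino-acid-level chain populates (nearly) all 20 amino acids
  rp <- random_potts(12, 21, coupling_scale = 0, field_scale = 0, seed = 40)
  wt <- assign_codons(strrep("W", 12), mode = "first_codon")
  cfg <- function(mode) evolver_config(T = 1, n_steps = 1, n_chains = 400,
                                       seed = 41, mode = mode)
  lib_c <- evolve_library(wt, rp$model, cfg("codon"))$snapshots[[1]]
  lib_s <- evolve_library(wt, rp$model, cfg("seec"))$snapshots[[1]]
  acc <- match(accessible_amino_acids("TGG"), AA_ALPHABET)
  expect_true(all(unique(as.vector(lib_c)) %in% acc))
  expect_gt(length(unique(as.vector(lib_s))), length(acc))
})
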