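test_that("contact maps apply the distance and separation filters", {
  empty <- contact_map_from_distances(
    data.frame(i = integer(0), j = integer(0), distance = numeric(0)), L = 20)
  expect_equal(nrow(empty$pairs), 0L)

  d <- data.frame(i = c(1, 1, 2), j = c(6, 9, 6), distance = c(7.9, 8.0, 3))
  cm <- contact_map_from_distances(d, L = 20)
  # 7.9 at separation 5 is a contact; 8.0 exactly is not (strict cutoff);
  # 3 Angstrom at separation 4 fails the separation filter
  expect_equal(cm$pairs, matrix(c(1L, 6L), 1))
  expect_error(contact_map_from_distances(
    data.frame(i = 1, j = 7, distance = -1), L = 10), "negative")
})

test_that("sequence reweighting matches the all-pairs identity oracle", {
  al <- default_alphabet(4)
  m <- matrix(c(1L, 2L, 3L, 4L,
                4L, 3L, 2L, 1L,
                1L, 3L, 2L, 4L), 3, byrow = TRUE)
  expect_equal(sequence_weights(m, 0.8, alphabet = al), rep(1, 3))
  dup <- m[c(1, 1, 1, 2), ]
  expect_equal(sequence_weights(dup, 0.8, alphabet = al),
               c(1/3, 1/3, 1/3, 1))
  expect_equal(sequence_weights(dup, NULL, alphabet = al), rep(1, 4))

  set.seed(81)
  for (k in 1:5) {
    r <- matrix(sample.int(3, 12 * 8, replace = TRUE), 12, 8)
    thr <- runif(1, 0.3, 0.9)
    w <- sequence_weights(r, thr, alphabet = default_alphabet(3))
    worx <- vapply(1:12, function(s)
      1 / sum(vapply(1:12, function(t) mean(r[s, ] == r[t, ]) >= thr, TRUE)), 0)
    expect_equal(w, worx, tolerance = 1e-12)
  }
})

test_that("Gaussian DCA ranks covarying columns first and is permutation invariant", {
  al <- default_alphabet(4)
  set.seed(82)
  M <- 600
  base <- sample.int(4, M, replace = TRUE)
  m <- cbind(base, base,  # perfectly covarying pair (1, 2)
             matrix(sample.int(4, M * 4, replace = TRUE), M, 4))
  sc <- gauss_dca_scores(m, pseudocount = 0.4, alphabet = al)
  expect_true(isSymmetric(unclass(sc)))
  off <- which(upper.tri(sc), arr.ind = TRUE)
  top <- off[which.max(sc[off]), ]
  expect_equal(unname(top), c(1L, 2L))

  perm <- m[sample.int(M), ]
  expect_equal(unclass(gauss_dca_scores(perm, 0.4, alphabet = al)),
               unclass(sc), tolerance = 1e-10)

  # i.i.d. uniform columns: no spuriously dominant pair
  un <- matrix(sample.int(4, 3000 * 8, replace = TRUE), 3000, 8)
  s0 <- gauss_dca_scores(un, pseudocount = 0.4, alphabet = al)
  v <- s0[upper.tri(s0)]
  expect_lt(max(v), 5 * median(v))
  expect_error(gauss_dca_scores(m[1, , drop = FALSE], 0.4, alphabet = al),
               "2 sequences")
})

test_that("APC matches the direct three-loop formula", {
  # constant off-diagonal scores are annihilated
  S <- matrix(3, 6, 6); diag(S) <- 0
  expect_true(all(abs(apc_correction(S)) < 1e-12))

  set.seed(83)
  for (k in 1:10) {
    A <- matrix(rnorm(36), 6, 6); A <- abs(A + t(A)); diag(A) <- 0
    got <- apc_correction(A)
    expect_true(isSymmetric(unclass(got)))
    means_i <- rowSums(A) / 5
    mean_all <- sum(A) / 30
    for (i in 1:6) for (j in 1:6) {
      if (i == j) next
      expect_equal(got[i, j], A[i, j] - means_i[i] * means_i[j] / mean_all,
                   tolerance = 1e-12)
    }
  }
  # all-zero input returned unchanged
  expect_true(all(apc_correction(matrix(0, 4, 4)) == 0))
})

test_that("PPV evaluates rankings against the map correctly", {
  set.seed(84)
  L <- 30
  map <- contact_map(L, cbind(c(1, 2, 3), c(10, 12, 20)), min_separation = 5)
  # perfect oracle ranking: the contacts themselves on top
  S <- matrix(0, L, L)
  for (r in seq_len(nrow(map$pairs)))
    S[map$pairs[r, 1], map$pairs[r, 2]] <- S[map$pairs[r, 2], map$pairs[r, 1]] <- 10 - r
  expect_equal(ppv(S, map, n_predictions = 3), 1)
  # empty map: PPV 0
  expect_equal(ppv(S, contact_map(L, matrix(0L, 0, 2)), 3), 0)
  expect_error(ppv(S, map, n_predictions = 10000), "eligible")

  # random rankings: mean PPV equals the eligible contact density (the
  # permutation oracle), within 3 sigma of the Monte Carlo mean
  rp <- random_potts(25, 4, edge_prob = 0.2, seed = 85)
  dens <- ppv_null_baseline(rp$map)
  n_top <- 10
  draws <- vapply(1:1000, function(k) {
    R <- matrix(0, 25, 25)
    R[upper.tri(R)] <- runif(300)
    R <- R + t(R)
    ppv(R, rp$map, n_top)
  }, 0)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - dens), 3 * se + 1e-12)
  # analytic null quantile brackets the random draws
  expect_gte(mean(draws <= ppv_null_quantile(rp$map, n_top, 0.95)), 0.9)
})

test_that("parameter scans are reproducible and structured", {
  fx <- fixture_landscape(seed = 86, L = 25)
  sc1 <- parameter_scan(fx$model, fx$wt, T_values = 1, snapshot_steps = 40,
                        library_sizes = c(20, 80), map = fx$map,
                        n_replicates = 1, n_predictions = 10, seed = 87)
  sc2 <- parameter_scan(fx$model, fx$wt, T_values = 1, snapshot_steps = 40,
                        library_sizes = c(20, 80), map = fx$map,
                        n_replicates = 1, n_predictions = 10, seed = 87)
  expect_identical(sc1$grid, sc2$grid)
  expect_equal(nrow(sc1$grid), 2L)
  expect_true(all(c("mean_ppv", "mean_hamming", "null_ppv") %in%
                  names(sc1$grid)))
})
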