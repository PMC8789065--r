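test_that("energy reproduces hand-computed and brute-force values", {
  # all-zero model: empty sums
  z <- potts_model(matrix(0, 3, 2), array(0, c(3, 3, 2, 2)),
                   alphabet = c("A", "B"))
  expect_identical(energy(z, "ABA"), 0)

  # L=2, q=2 toy by direct substitution
  h <- matrix(0, 2, 2); h[1, 1] <- 1
  J <- array(0, c(2, 2, 2, 2)); J[1, 2, 1, 2] <- 0.5; J[2, 1, 2, 1] <- 0.5
  toy <- potts_model(h, J, alphabet = c("A", "B"))
  expect_equal(energy(toy, "AB"), -1.5)

  # random models vs the double-loop oracle
  m <- rand_small_potts(6, 4, seed = 101)
  set.seed(102)
  for (k in 1:100) {
    a <- rand_seq(m)
    expect_equal(energy(m, a), oracle_energy(m, a), tolerance = 1e-12)
  }
})

test_that("energy rejects bad sequences", {
  m <- rand_small_potts(4, 4, seed = 1)
  expect_error(energy(m, c(1L, 2L, 3L)), "length")
  expect_error(energy(m, c(1L, 2L, 3L, 9L)), "outside")
})

test_that("delta_energy equals the full energy difference", {
  h <- matrix(0, 2, 2); h[1, 1] <- 1
  J <- array(0, c(2, 2, 2, 2)); J[1, 2, 1, 2] <- 0.5; J[2, 1, 2, 1] <- 0.5
  toy <- potts_model(h, J, alphabet = c("A", "B"))
  expect_equal(delta_energy(toy, "AB", 1, "B"), 1.5)
  expect_identical(delta_energy(toy, "AB", 1, "A"), 0)

  set.seed(103)
  for (k in 1:10) {
    m <- rand_small_potts(sample(2:6, 1), sample(2:4, 1), seed = 200 + k)
    for (r in 1:100) {
      a <- rand_seq(m)
      i <- sample.int(m$L, 1)
      b <- sample.int(m$q, 1)
      mut <- a; mut[i] <- b
      expect_equal(delta_energy(m, a, i, b),
                   oracle_energy(m, mut) - oracle_energy(m, a),
                   tolerance = 1e-10)
    }
  }
})

test_that("mutant_scan matches per-entry delta_energy and handles gaps", {
  fx <- rand_small_potts(5, 4, seed = 301)
  a <- rand_seq(fx)
  sc <- mutant_scan(fx, a)
  expect_equal(dim(sc), c(5L, 4L))  # reduced alphabet: no gap column drop
  for (i in 1:5) for (b in 1:4)
    expect_equal(sc[i, b], delta_energy(fx, a, i, b), tolerance = 1e-12)
  # self column is zero
  expect_true(all(sc[cbind(1:5, a)] == 0))

  # canonical alphabet: 20 columns, gap rows NA, gap never a target
  rp <- random_potts(8, 21, seed = 302)
  aa <- as_aa_matrix("AC-DEFG-")[1, ]
  sc21 <- mutant_scan(rp$model, aa)
  expect_equal(ncol(sc21), 20L)
  expect_false("-" %in% colnames(sc21))
  expect_true(all(is.na(sc21[c(3, 8), ])))
  expect_true(all(!is.na(sc21[-c(3, 8), ])))
})

test_that("profile model mutant effects are context independent", {
  pm <- profile_model(matrix(rnorm(6 * 4), 6, 4), default_alphabet(4))
  set.seed(304)
  a1 <- sample.int(4, 6, replace = TRUE)
  a2 <- sample.int(4, 6, replace = TRUE)
  i <- 3
  a2[i] <- a1[i]
  s1 <- mutant_scan(pm, a1)[i, ]
  s2 <- mutant_scan(pm, a2)[i, ]
  expect_equal(s1, s2)
})

test_that("conditional_distribution matches direct evaluation and limits", {
  m <- rand_small_potts(4, 4, seed = 401)
  a <- c(1L, 2L, 3L, 4L)

  # beta = 0: uniform over allowed (mutation accumulation without selection)
  p0 <- conditional_distribution(m, a, 2, c(1L, 3L, 4L), beta = 0)
  expect_equal(unname(p0), rep(1 / 3, 3))

  # singleton allowed set
  expect_equal(unname(conditional_distribution(m, a, 1, 2L, beta = 2)), 1)

  # direct hand-normalized exponentials
  allowed <- c(1L, 2L, 4L)
  beta <- 1.3
  s <- vapply(allowed, function(b) {
    m$h[2, b] + sum(vapply(setdiff(1:4, 2), function(j) m$J[2, j, b, a[j]], 0))
  }, 0)
  expect_equal(unname(conditional_distribution(m, a, 2, allowed, beta)),
               exp(beta * s) / sum(exp(beta * s)), tolerance = 1e-12)

  # probability vector
  p <- conditional_distribution(m, a, 3, 1:4, beta = 0.7)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(conditional_distribution(m, a, 3, integer(0)), "empty")
})

test_that("zero-sum gauge normalizes without changing energy differences", {
  m <- rand_small_potts(5, 4, seed = 501)
  g <- zero_sum_gauge(m)
  # definition: zero marginal sums
  expect_lt(max(abs(rowSums(g$h))), 1e-10)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(max(abs(rowSums(g$J[i, j, , ]))), 1e-10)
    expect_lt(max(abs(colSums(g$J[i, j, , ]))), 1e-10)
  }
  # idempotence
  g2 <- zero_sum_gauge(g)
  expect_equal(g2$h, g$h, tolerance = 1e-12)
  expect_equal(g2$J, g$J, tolerance = 1e-12)
  # gauge invariance of mutational effects
  set.seed(502)
  for (k in 1:100) {
    a <- rand_seq(m)
    i <- sample.int(5, 1); b <- sample.int(4, 1)
    expect_equal(delta_energy(m, a, i, b), delta_energy(g, a, i, b),
                 tolerance = 1e-10)
  }
})

test_that("profile_from_msa applies the pseudocount formula and recovers fields", {
  al <- default_alphabet(4)
  # single sequence, lambda = 0.5
  pm <- profile_from_msa("AC", pseudocount = 0.5, alphabet = c("A", "C"))
  f_expect <- 0.5 * 1 + 0.5 / 2
  expect_equal(unname(pm$h[1, 1]), log(f_expect))
  expect_equal(unname(pm$h[1, 2]), log(0.5 / 2))

  # lambda = 1: uniform model
  pu <- profile_from_msa(c("AC", "CA"), pseudocount = 1, alphabet = c("A", "C"))
  expect_true(all(abs(pu$h - pu$h[1, 1]) < 1e-12))

  # parameter recovery from a large equilibrium sample
  set.seed(601)
  h_true <- matrix(rnorm(20 * 4), 20, 4)
  truth <- profile_model(h_true, al)
  msa <- gibbs_sample(truth, 10000, burn_in = 50, thinning = 1, seed = 602)
  fit <- profile_from_msa(msa, pseudocount = 0.01, alphabet = al)
  ctr <- function(h) as.vector(h - rowMeans(h))
  expect_gt(cor(ctr(h_true), ctr(fit$h), method = "spearman"), 0.9)
})

test_that("parameter file dialect round-trips and symmetrizes", {
  m <- rand_small_potts(4, 3, seed = 701)
  # sparsify so missing entries are exercised on read
  path <- withr::local_tempfile(fileext = ".txt")
  write_potts_params(m, path)
  m2 <- read_potts_params(path, L = 4, q = 3)
  expect_identical(m2$h, m$h)
  expect_identical(m2$J, m$J)

  # file with only h lines: couplings all zero
  writeLines(c("h 0 0 1.25", "h 2 1 -0.5"), path)
  m3 <- suppressWarnings(read_potts_params(path, L = 3, q = 2))
  expect_true(all(m3$J == 0))
  expect_equal(m3$h[1, 1], 1.25)
  expect_warning(read_potts_params(path, L = 3, q = 2), "missing")

  # one J line populates both orientations
  writeLines(c("J 0 2 1 0 0.75"), path)
  m4 <- suppressWarnings(read_potts_params(path, L = 3, q = 2))
  expect_equal(m4$J[1, 3, 2, 1], 0.75)
  expect_equal(m4$J[3, 1, 1, 2], 0.75)

  writeLines("K 0 0 1", path)
  expect_error(suppressWarnings(read_potts_params(path, L = 2, q = 2)),
               "malformed|tag")
  writeLines("h 9 0 1", path)
  expect_error(suppressWarnings(read_potts_params(path, L = 2, q = 2)),
               "range")
})

test_that("potts_model validates symmetry and finiteness", {
  h <- matrix(0, 2, 2)
  J <- array(0, c(2, 2, 2, 2)); J[1, 2, 1, 2] <- 1  # asymmetric
  expect_error(potts_model(h, J, alphabet = c("A", "B")), "symmetry")
  J2 <- array(0, c(2, 2, 2, 2)); J2[1, 1, 1, 1] <- 1
  expect_error(potts_model(h, J2, alphabet = c("A", "B")), "diagonal")
  expect_error(potts_model(matrix(NA_real_, 2, 2), array(0, c(2, 2, 2, 2)),
                           alphabet = c("A", "B")), "finite")
})
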