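# Shared fixtures and independent oracles, built in code.

# dense random Potts model on a small alphabet (direct construction,
# independent of random_potts)
rand_small_potts <- function(L, q, seed, coupling_sd = 0.5, field_sd = 1) {
  set.seed(seed)
  h <- matrix(rnorm(L * q, sd = field_sd), L, q)
  J <- array(0, c(L, L, q, q))
  if (L >= 2) for (i in 1:(L - 1)) for (j in (i + 1):L) {
    blk <- matrix(rnorm(q * q, sd = coupling_sd), q, q)
    J[i, j, , ] <- blk
    J[j, i, , ] <- t(blk)
  }
  potts_model(h, J, default_alphabet(q))
}

# brute-force double-loop energy oracle (never uses energy())
oracle_energy <- function(model, a) {
  e <- 0
  for (i in seq_len(model$L)) e <- e - model$h[i, a[i]]
  if (inherits(model, "potts_model") && model$L >= 2)
    for (i in 1:(model$L - 1)) for (j in (i + 1):model$L)
      e <- e - model$J[i, j, a[i], a[j]]
  e
}

rand_seq <- function(model) sample.int(model$q, model$L, replace = TRUE)

# exhaustive single-nucleotide-neighbor oracle for the genetic code,
# built from the Biostrings code table rather than the package's lookups
oracle_codon_tables <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)  # DNA codons in Biostrings order
  nb <- function(cod) {
    s <- strsplit(cod, "")[[1]]
    out <- character(0)
    for (p in 1:3) for (n in c("A", "C", "G", "T")) {
      if (n == s[p]) next
      t <- s; t[p] <- n
      out <- c(out, paste(t, collapse = ""))
    }
    out
  }
  acc <- lapply(codons, function(cod) {
    aa <- unname(gc[c(cod, nb(cod))])
    sort(unique(aa[aa != "*"]))
  })
  names(acc) <- codons
  cand <- lapply(codons, function(cod) {
    reach <- c(cod, nb(cod))
    keep <- unname(gc[reach]) != "*"
    lapply(split(reach[keep], unname(gc[reach])[keep]), sort)
  })
  names(cand) <- codons
  list(gc = gc, sense = codons[gc != "*"], accessible = acc, candidates = cand)
}

# small planted-contact landscape + wildtype for simulation tests
fixture_landscape <- function(seed = 51, coupling_scale = 1.5, L = 30) {
  rp <- random_potts(L, 21, coupling_scale = coupling_scale, seed = seed)
  wt <- synthetic_wildtype(rp$model, seed = seed + 1)
  list(model = rp$model, map = rp$map, wt = wt)
}

mean_hamming_to <- function(msa, ref)
  mean(rowSums(msa != matrix(ref, nrow(msa), length(ref), byrow = TRUE)))

# exact outcome distribution of ONE codon-level evolutionary step from a
# fixed state: P(site i ends in codon c') marginalized over the three-step
# kernel, with an extra "unchanged" category for identity moves
one_step_codon_expectation <- function(model, wt, beta) {
  mut <- which(!is.na(wt$codon))
  p_site <- 1 / length(mut)
  rows <- list()
  p_unchanged <- 0
  for (i in mut) {
    acc <- accessible_amino_acids(wt$dna[i])
    pb <- conditional_distribution(model, wt$aa, i, acc, beta = beta)
    for (k in seq_along(acc)) {
      cands <- codons_within_one(wt$dna[i], acc[k])
      for (cp in cands) {
        pr <- p_site * pb[k] / length(cands)
        if (cp == wt$dna[i]) p_unchanged <- p_unchanged + pr
        else rows[[length(rows) + 1L]] <-
          data.frame(site = i, codon = cp, p = unname(pr))
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- stats::aggregate(p ~ site + codon, out, sum)
  rbind(out, data.frame(site = 0L, codon = "unchanged", p = p_unchanged))
}

# observed counts of the same categories from M one-step chains
one_step_codon_observed <- function(model, wt, beta, M, seed) {
  cfg <- evolver_config(T = if (beta == 0) Inf else 1 / beta, n_steps = 1,
                        n_chains = M, seed = seed)
  lib <- evolve_library(wt, model, cfg, return_codons = TRUE)
  dna <- lib$dna[[1]]
  obs <- data.frame(site = integer(M), codon = character(M))
  for (m in seq_len(M)) {
    diff <- which(dna[m, ] != wt$dna)
    if (length(diff) == 0L) {
      obs$site[m] <- 0L; obs$codon[m] <- "unchanged"
    } else {
      obs$site[m] <- diff[1L]; obs$codon[m] <- dna[m, diff[1L]]
    }
  }
  obs
}
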