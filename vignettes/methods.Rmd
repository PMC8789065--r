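---
title: "Simulating protein evolution in Potts landscapes: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating protein evolution in Potts landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottsim)
```

## The landscape model

`pottsim` treats protein fitness through the statistical energy of a Potts
model on aligned sequences of length $L$ over $q = 21$ states (20 amino
acids plus the alignment gap):

$$E(a) = -\sum_i h_i(a_i) - \sum_{i<j} J_{ij}(a_i, a_j), \qquad
  P(a) = e^{-E(a)}/Z.$$

Low energy stands for high fitness. The fields $h$ capture site-specific
amino acid preferences; the couplings $J$ capture pairwise epistasis, and
their strong entries correspond to residue–residue contacts — which is what
makes contact prediction from evolved libraries possible at all. A
`profile_model` (fields only) is the non-epistatic baseline throughout.

Parameters are gauge-redundant: adding site terms to $J$ and subtracting
them from $h$ leaves all energy differences unchanged. `zero_sum_gauge()`
fixes the canonical normalization ($\sum_a h_i(a) = 0$, zero row/column sums
of every coupling block); every mutational-effect computation is invariant
under it, which the test suite checks explicitly. The partition function $Z$
is never computed at scale — only the tiny enumeration oracle in the tests
evaluates it, on state spaces of at most a few dozen configurations.

Gaps are ordinary Potts states in the energy (the usual DCA convention) but
are frozen by the dynamics: they are never chosen for mutation and never
created. The fixed alphabet ordering is `-ACDEFGHIKLMNPQRSTVWY` in all
arrays and file formats.

## The evolutionary chain

Mutation acts on DNA, selection on protein. One Monte Carlo step:

1. choose a site uniformly at random, re-drawing while it is a gap;
2. among the amino acids $A_{acc}$ reachable from the current codon by at
   most one nucleotide substitution (stop codons excluded; the current
   amino acid is always a member), draw $b$ with probability
   $\propto \exp\{\beta h_i(b) + \beta \sum_{j \ne i} J_{ij}(b, a_j)\}$,
   i.e. $\propto e^{-\beta \Delta E}$;
3. choose the new codon uniformly among the codons of $b$ within one
   nucleotide of the current codon.

Every step counts, including synonymous and identity moves, so the Hamming
distance to the wildtype is bounded by, but usually well below, the step
count. The accessibility structure matters: most amino acids are *not*
reachable from a given codon, which is why evolved libraries show many
exactly-zero entries in their mutational spectra; the package's `seec` mode
(an amino-acid-level chain where all 20 amino acids are accessible) exists
to quantify exactly this contrast and doubles as a Gibbs sampler whose
stationary distribution is verified against exact enumeration.

The temperature $T = 1/\beta$ scales selection. $T = 0$ is implemented as
an exact argmax over the accessible set with uniform tie-breaking rather
than a very large $\beta$, which avoids overflow and makes the greedy limit
exact; $\beta = 0$ gives uniform proposals (mutation accumulation without
selection). Numerical stabilization everywhere is by max-shift before
exponentiation; probability normalization is checked to $10^{-12}$.

All chains of a library run sequentially under one seeded RNG stream (R's
own generator, threaded through the compiled core). This makes an entire
simulation exactly reproducible from a single integer seed, which we judged
more valuable than per-chain counter-based streams; chains remain
statistically independent because no state is shared. Snapshots at
increasing step counts reuse the same chains (one long run per chain), and
smaller libraries are seeded subsamples without replacement of the deepest
one — the resource-saving scheme also used for the parameter scans.

## Calibration

Two knobs connect simulation time to experiment: the number of MC steps and
$T$. `fit_chain_length()` matches the mean Hamming distance of a reference
library using a pilot run with snapshots on a log-spaced step grid (25
points up to the budget), picking the step whose pilot mean distance is
closest to the target. `fit_temperature()` then, for each candidate $T$ on
a log-spaced grid, re-matches the chain length, simulates pilot libraries,
and compares the ordinary least-squares slope of per-sequence
$\Delta E$ against Hamming distance (free intercept; a binned variant is
available) with the reference's slope.

Because the slope objective is noisy, three design choices stabilize it:
pilot replicates are averaged (3 × 500 chains by default), the same pilot
seeds are reused for every candidate (common random numbers), and the final
estimate inverts a local linear regression of slope on $\log T$ around the
best grid point rather than returning the noisy argmin — the slope is
monotone in $T$, so this pooled inversion removes both grid quantization
and most of the pointwise noise. The slope–temperature curve flattens at
weak selection and high divergence; calibration is therefore most reliable
against references of moderate divergence (tests use about one substitution
per five sites, the regime of real evolved libraries). The paper-style
subsampling analysis (`slope_subsample_error()`) shows the slope is stable
from a few hundred sequences.

## Contact scoring

`gauss_dca_scores()` implements Gaussian DCA: sequences are one-hot encoded
over $q - 1$ states (the last alphabet state is dropped; the gap is an
ordinary state), one- and two-site frequencies are computed with optional
sequence weights and mixed toward the uniform independent model by a
pseudocount $\lambda$ (default 0.6 — the robust choice when library
statistics vary wildly; 0.5 is a common alternative), and the covariance
matrix is inverted. A pair's score is the Frobenius norm of its inverse
covariance block; `apc_correction()` subtracts the average-product
background, and ranking ties are broken lexicographically for determinism.
Reweighting defaults to off for simulated libraries (chains are independent
by construction) and to a 0.8-identity threshold for experimental
alignments, where phylogenetic structure is expected.

Contacts are pairs below 8 Å (strictly) with sequence separation at least
5; both are configurable (5.5 Å suits families whose structural variability
is already well sampled). `ppv()` is the fraction of true contacts among
the top-$n$ eligible pairs. On a planted-contact map the exact null is
hypergeometric: `ppv_null_baseline()` (the eligible contact density) is the
expected PPV of a random ranking and `ppv_null_quantile()` the threshold
below which a cell of a scan is indistinguishable from noise. At the $L =
30$ desk scale used in the tests, $n$ is set to the number of planted
contacts (about 20–40) rather than the conventional 100 of full-length
domains, keeping the ceiling of the statistic at 1.

## The synthetic generator

`random_potts()` emulates what an inferred landscape provides: Gaussian
fields (sd 0.8) and Gaussian coupling blocks (sd 0.3) placed only on a
planted random graph (edge probability 0.08), zero-sum gauged, with the gap
state strongly disfavored and uncoupled so that equilibrium sequences are
essentially gap free. The default scales were chosen once so that the bulk
of single-mutant $|\Delta E|$ spans roughly 0–4 at $q = 21$ — the dynamic
range typical of measured mutational effects; tests that specifically need
a detectable coevolution signal raise `coupling_scale` to 1.5
("strongly coupled"), since couplings at the default scale are genuinely
too weak to recover from desk-scale libraries — itself a faithful
reflection of how weak the epistatic signal is.

`synthetic_wildtype()` is a greedy conditional-argmax quench from a random
start, one sweep by default. A quench run to a fixed point would be a
strict local minimum, at which strong selection could not lower the energy
any further and the directed-evolution regime (negative energy-versus-
distance slope at $T \ll 1$) would be structurally impossible; stopping
after one sweep leaves the wildtype far below the equilibrium energy bulk —
real wildtypes are fit, not optimal — while improving substitutions remain.

`gibbs_sample()` (single-site heat bath, burn-in plus thinning) stands in
for the alignment of natural homologs, and `toy_bm_learn()` closes the
inference loop at toy scale ($L \le 25$, $q \le 8$): persistent-chain
stochastic gradient ascent on the ridge-regularized likelihood, initialized
at the profile model. It is a test utility for verifying that
landscape → sample → inference → evolution → contact recovery works end to
end, not a production DCA trainer.

What the generator does *not* emulate: phylogenetic correlations between
library sequences (chains are independent), insertions/deletions, mutational
biases of error-prone PCR (transition/transversion or codon-usage bias),
and selection bottlenecks with explicit population dynamics. Passing tests
therefore validate the machinery and its statistical behavior, not these
aspects of real experiments.

## Problem sizes and determinism

The test and demonstration scale is $L = 30$, $q = 21$, libraries up to
2000 chains and 600 steps, pilot calibrations with 500 chains, and scans
averaged over 5 replicate runs; stationarity checks use $10^6$ steps on
$3^3$-state toy models, and stress tests $10^5$ steps. Every stochastic
function takes an explicit integer seed and is exactly reproducible;
generators, simulators and scans are deterministic given (seed,
parameters).

## Known limitations

* The calibration inverts a noisy monotone curve; at very weak selection
  ($T \gtrsim 5$ with saturating divergence) the slope carries little
  information about $T$ and recovered temperatures are correspondingly
  uncertain.
* Gaussian DCA with a large pseudocount is biased toward conservative
  scores; it ranks pairs well but its absolute score values are not
  interpretable as coupling strengths.
* The codon-level chain assumes the wildtype DNA is consistent with the
  aligned protein; it validates, but does not construct, codon-level
  alignments.
* `toy_bm_learn()` is deliberately guarded to toy sizes; inferring
  landscapes at realistic scale is out of scope.
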