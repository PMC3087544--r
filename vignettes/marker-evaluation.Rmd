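---
title: "Methods: evaluating DNA barcode markers with barcodeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating DNA barcode markers with barcodeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures implemented, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the underlying methodology is genuinely open.

# The evaluation problem

A DNA barcode marker is useful for a taxon when the genetic divergence
*between* species is reliably larger than the variation *within* species
(the "barcoding gap"), and when assigning a query sequence to the closest
reference recovers the true species. `barcodeval` quantifies both, compares
candidate markers statistically, and wraps the whole procedure — input
filtering, distances, divergence metrics, marker comparison,
identification, marker combination, contaminant screening — into one
reproducible pipeline (`run_full_evaluation()`).

# Genetic distance: the Kimura 2-parameter model

All distances are K2P distances. For an aligned pair, sites where either
sequence has a gap or a non-ACGT symbol are excluded (pairwise deletion);
over the remaining $L$ sites, $P$ is the fraction of transitions (A↔G,
C↔T) and $Q$ the fraction of transversions, and

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).$$

**Degenerate inputs.** The distance is undefined (`NA`) when $L = 0$ or
when either logarithm's argument is non-positive (saturation). Undefined
distances are never silently dropped: the matrix records them, downstream
metrics count them (`n_undefined`), and the nearest-distance classifier
treats them as $+\infty$. `count_site_patterns()` is the package's own
implementation (it is part of the contribution surface); `ape::dist.dna`
with the K80 model serves as an independent cross-check in the test suite,
never as the implementation.

**Alignment modes.** `distance_matrix()` either trusts the input as a
pre-computed alignment (`"pre-aligned"`) or aligns each pair globally
(`"pairwise-global"`, the default for real data of unequal length).
Pairwise alignment is delegated to `Biostrings::pairwiseAlignment` behind
the package's interface. The scoring scheme is megablast-like — match +1,
mismatch −2, a gap of length $k$ costing $\text{gap\_open} + (k-1)\,
\text{gap\_extend}$ with defaults −5/−2 — and IUPAC ambiguity codes score
as a match whenever the two symbols' base sets intersect. Where a dynamic
program has co-optimal alignments the tie-break is Biostrings' own
deterministic one; determinism, not a particular traceback order, is the
contract.

# Divergence metrics and the barcoding gap

Three intra-specific summaries are computed over species with at least two
representatives: the pooled average distance over all conspecific pairs
(`avg_intra`), θ (`theta`, the mean of per-species mean distances, which
removes unequal-sampling bias), and the average coalescent depth
(`avg_coalescent_depth`, the mean of per-species maxima). Three
inter-specific summaries are computed over genera with at least two
species, at the individual level and excluding conspecific pairs by
default: the pooled average (`avg_inter`), θ′ (`theta_prime`, mean of
per-genus means), and the mean smallest inter-specific distance
(`min_inter`). `include_conspecific = TRUE` gives the all-pairs variant.
A detectable gap shows `min_inter` above `avg_intra`.

# Comparing markers: Wilcoxon signed-rank

Markers are compared on paired per-genus mean inter-specific distances
(genera qualifying in both markers, sorted by name). The pairing unit is
the genus: it matches the sample sizes such comparisons typically report,
and a per-species pairing is available through the metrics tables if
wanted. Zero differences are dropped; absolute differences receive
midranks; the default p-value is the two-sided normal approximation

$$z = \frac{W_+ - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24}}$$

with **no** continuity correction and no tie correction — this exact
variant is what reproduces the classical published p-values the test suite
pins (e.g. $n = 8$, $W_+ = 36 \rightarrow p \approx 0.0117$). Both
corrections are available as options.

**Accuracy region.** The suite also enumerates the exact null
distribution (via `stats::psignrank`, and a rank-convolution DP for tied
data). On tie-free data the approximation agrees with the exact p-value
within 0.01 wherever the exact p ≤ 0.1 — the region where the verdicts
live — but the discrepancy can reach about 0.05 near the null center for
small $n$. The property tests assert exactly these two bounds; treat
mid-range p-values from the approximation as indicative only, or use
`method = "exact"` ($n \le 25$).

# Identification and marker combination

Two classifiers are implemented: **BLAST1** (assign the query to the
species of its best Smith–Waterman local-alignment hit) and **nearest
distance** (minimal K2P). Both use the *tie-failure* convention: the
assignment is correct only if *every* optimal reference is conspecific
with the query; optima spanning species yield `"ambiguous"` and count as
failures. The default mode is self-inclusive (the query's own record stays
in the database), with leave-one-out as the stricter alternative. The
self-inclusive/tie-failure pair is the only convention under which a
reference set with singleton species can show high success while each
cross-species identical pair produces exactly two failures — which makes
planted-truth arithmetic exact: $k$ planted identical pairs across species
give a species-level success of $100\,(N - 2k)/N$ on $N$ records.

The traffic-light combination evaluates marker sets on the samples
sequenced for **all** members (intersection) and scores a sample as
identified if **any** member identifies it; the combination rate is
therefore monotone — never below the best member on the common set.

# Contaminant screening with a profile HMM

The screen models a contaminant family (e.g. fungal ITS2 in a plant
dataset) as a Durbin-style profile HMM built from an aligned training set:
alignment columns with gap fraction < 0.5 become match states; emissions
are Laplace-smoothed column counts (pseudocount 1); insert states emit the
background (smoothed overall residue frequencies); transitions are
estimated from the training sequences' state paths with pseudocounts on
structurally allowed moves. Scoring is the forward algorithm in log space,
reported in bits against the background model; the default mode is local
(free entry at any match state with uniform weight $1/k$, free exit after
any match state, background-emitting flanks that cancel in the log-odds),
since real contaminant reads are fragments. A Viterbi (best-path) variant
is available and is never above the forward score. The inner recursions
are compiled (Rcpp); they are verified against exhaustive path enumeration
on small profiles to $10^{-9}$ in log space.

**Absolute vs competitive thresholding** was a genuinely open design
point. An absolute threshold (flag records scoring ≥ `threshold_bits`,
default 0) works when the contaminant family is far from the target taxon:
at saturated divergence the pipeline test separates the two origins
cleanly with a 50-bit threshold. But at moderate divergence (say 30% of sites) target sequences themselves
score well above 0 bits against a contaminant profile, because any
related sequence has positive log-odds under a profile of its relatives.
`screen_contaminants()` therefore accepts an optional `null_hmm` (a
profile of the *target* family); the score becomes
bits(contaminant) − bits(null), asking which family the record resembles
more. The test suite shows this separates two families diverged at 0.5
substitutions/site with zero errors over 50 records.

# The synthetic-data generator

`simulate_dataset()` draws a uniform-random root and evolves genus,
species and individual lineages along star phylogenies under the K80
process, using the exact closed-form site-substitution probabilities (so
the transition/transversion ratio κ is honored at any branch length).
Branch lengths are in expected substitutions per site. Defaults —
`genus_branch = 0.15`, `inter_branch = 0.05`, `intra_branch = 0.005`,
`kappa = 2`, `seq_length = 300` — put conspecific variation near 1% and
congeneric divergence near 10%, the regime in which barcoding studies
operate, and `seq_length ≥ 100` guarantees fixtures pass the default
length filter. Determinism: every simulation call derives a named
substream seed (`substream_seed()`) and restores the caller's RNG state,
so the same seed is byte-reproducible and adding pipeline stages never
perturbs existing fixtures.

Star topologies are a deliberate simplification: they keep every expected
pairwise divergence analytically known (sister species are separated by
exactly `2*inter_branch + 2*intra_branch` expected substitutions/site),
which is what parameter-recovery tests need. The generator does **not**
emulate real data's rate variation among sites or lineages, indels,
alignment uncertainty, recombination or incomplete lineage sorting —
so passing tests demonstrate correctness of the *computations*, not that
any particular real marker will show a gap.
`plant_cross_species_identicals()` injects the one failure mode the
identification arithmetic needs (shared haplotypes across species), and
`simulate_contaminants()` produces a diverged family for the screen.

# Numerical choices and problem sizes

- Distances and metrics are exact floating-point computations; tests
  compare the implementation to independent oracles at $10^{-12}$
  (distances), $10^{-9}$ (HMM log-space), and exactly (counts, rates).
- Identification fixtures use `intra_branch = 0.02` with sequences of
  ≥ 500 bp so that all haplotypes are globally unique (asserted, not
  assumed); the planted-truth arithmetic presupposes it.
- The test suite and acceptance script run on deliberately small problem
  sizes chosen as the package's own verification scale: families of 4–5
  genera for pipeline runs, 20 replicates for gap-detection frequency,
  100 sister pairs at 10 kb for parameter recovery, 50 records for the
  screen. All complete in minutes on one CPU.

# Known limitations

- K2P assumes equal base frequencies and a shared rate across sites; no
  gamma rate variation or other substitution models are offered.
- The signed-rank normal approximation is inaccurate far from the tails
  (see the accuracy region above).
- BLAST1 here is a true Smith–Waterman best hit, not a heuristic BLAST
  re-implementation; on very large reference sets it is slower than a
  seeded search would be.
- The profile HMM has no position-specific insert emissions and no
  explicit model-surgery (map) step; training expects a trustworthy
  alignment.
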