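# barcodeval

Tools for evaluating candidate DNA barcode markers — short standardized
DNA regions such as ITS2, ITS, rbcL, matK or psbA-trnH — for their power
to discriminate species. Intended for molecular ecologists and taxonomists
who need to decide, before committing to a marker, whether it separates
the species of a taxon well enough for reliable specimen identification.

## What it computes

Marker evaluation rests on four quantitative pillars, all implemented and
tested here:

**Genetic distance.** Pairwise divergence under the Kimura 2-parameter
(K2P) model, which weights transitions (A↔G, C↔T) and transversions
separately. With *P* and *Q* the proportions of aligned sites showing a
transition and a transversion (sites with gaps or ambiguity codes are
excluded pairwise),

    d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

**The barcoding gap.** Six divergence summaries contrast intra-specific
variation with inter-specific divergence: the pooled average intra-specific
distance, θ (the mean of per-species means, removing unequal-sampling
bias), and the average coalescent depth (mean of per-species maxima);
against the pooled average inter-specific distance within genera, θ′
(the mean of per-genus means), and the mean smallest inter-specific
distance. A usable barcode shows inter ≫ intra.

**Marker comparison.** Markers are compared by the Wilcoxon signed-rank
test on paired per-genus mean inter-specific distances: W+ and W− from
midranks of the non-zero differences, and the two-sided p-value from the
normal approximation z = (W+ − n(n+1)/4) / √(n(n+1)(2n+1)/24) without
continuity correction (an exact-enumeration method is available for
n ≤ 25).

**Identification success.** Every record is queried against the reference
set by two methods — BLAST1 (best local-alignment hit) and nearest
distance (minimal K2P) — and a query counts as identified only if *all*
optimal references are conspecific; ties spanning species are failures.
Success rates are reported at species and genus level, and markers can be
combined by the traffic-light rule (a sample is identified if any member
marker identifies it). A profile-HMM screen (match/insert/delete
architecture, forward-algorithm log-odds in bits) can remove
contaminant-like sequences, e.g. fungal reads in a plant ITS2 set, before
analysis.

A seeded K2P sequence simulator generates taxonomically structured
datasets (family → genera → species → individuals on star phylogenies)
with known truth, so every stage is testable end to end without external
data.

## Worked example

```r
library(barcodeval)

# K2P distance for 100 aligned sites with 10 transitions, 5 transversions
site <- count_site_patterns(list(
  seq_a = strrep("A", 100),
  seq_b = paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))))
k2p_distance(site)
#> [1] 0.1701812

# a simulated marker: 4 genera x 3 species x 3 individuals, 300 bp
cfg <- sim_config(n_genera = 4, species_per_genus = 3,
                  individuals_per_species = 3, seq_length = 300, seed = 42)
sim <- simulate_dataset(cfg, marker = "ITS2")
ds  <- barcode_dataset(sim$records)
ds
#> barcode_dataset: marker ITS2, 36 records, 12 species, 4 genera

d <- distance_matrix(ds, mode = "pre-aligned")
round(unlist(intraspecific_metrics(d, ds)[
  c("avg_intra", "theta", "avg_coalescent_depth")]), 6)
#>            avg_intra                theta avg_coalescent_depth
#>             0.008780             0.008780             0.011227
round(unlist(interspecific_metrics(d, ds)[
  c("avg_inter", "theta_prime", "min_inter")]), 6)
#>   avg_inter theta_prime   min_inter
#>    0.109843    0.109843    0.091408

evaluate_identification(ds, method = "distance", d = d)
#> identification_report: distance, self-inclusive, 36 queries
#>   species-level success: 100.0%
#>   genus-level success:   100.0%

# comparing two markers from paired per-genus mean inter-specific distances
wilcoxon_signed_rank(c(0.112, 0.094, 0.071, 0.130, 0.083, 0.101),
                     c(0.041, 0.017, 0.026, 0.049, 0.013, 0.008))
#> Wilcoxon signed-rank (normal-approx): W+ = 21, W- = 0, n = 6, p = 0.02771 [first > second]
```

Reading the numbers: the mean distance between individuals of the same
species (0.0088) sits an order of magnitude below the smallest
inter-specific distance per genus (0.0914) — a clear barcoding gap — and
every one of the 36 queries is assigned to its true species. (With equally
many individuals per species the pooled average and θ coincide exactly;
they separate under unequal sampling.) The signed-rank call says the first
marker's per-genus divergences exceed the second's in all six genera
(W+ = 21, W− = 0), two-sided p ≈ 0.028.

The full pipeline — filtering, distances, divergence metrics, signed-rank
comparison, identification, combinations, optional contaminant screen,
all written as TSV/JSON with provenance — runs via `run_full_evaluation()`
or the command-line wrapper `inst/scripts/barcodeval.R`
(subcommands `filter`, `summarize`, `distances`, `metrics`, `wilcoxon`,
`identify`, `combine`, `screen`, `simulate`, `run-all`).

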