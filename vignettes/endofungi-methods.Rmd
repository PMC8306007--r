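---
title: "Models and methods behind endofungi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind endofungi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements, the choices that were genuinely open, and what the synthetic
community generator does and does not emulate. It states no numbers that
the test suite or `scripts/acceptance.R` do not themselves compute.

## The analysis pipeline

The package targets amplicon surveys of plant endophytic fungi with a
crossed design: several host species, several organs (stem, leaf, root),
several replicate plots. The canonical design carried through examples and
tests is 5 hosts × 3 organs × 3 plots with one host lacking leaf samples
(42 samples), a few hundred OTUs, and a common rarefaction depth near
40,000 reads.

Stages: read filtering (total-count and taxonomy filters), rarefaction,
alpha diversity and group tests, Bray–Curtis/NMDS/ANOSIM/PERMANOVA,
compositional summaries, the d′/2DP preference framework, and Spearman
co-occurrence networks.

## Filtering conventions

* `filter_low_count_otus(min_total = 10)` removes OTUs whose **total**
  reads across all samples are below the threshold. "Fewer than 10 reads"
  is read as a total, not per-sample, rule: the filter precedes
  rarefaction, and a total-count rule is the standard practice for
  removing likely-artifactual OTUs at that stage.
* `select_abundant_otus(min_reads = 1000)` uses a **strict** inequality
  (exactly 1000 reads is removed). The cutoff is applied to the rarefied
  ("normalized") table in the shipped pipeline, because the abundant set
  feeds analyses that assume library-size effects have been removed; both
  the boundary and the stage are caller-controllable.
* Orientation of input tables is fixed as OTUs-in-rows. A transposed file
  is accepted only via an explicit argument, never guessed from shape: a
  square-ish table cannot be disambiguated reliably, and silent guessing
  is worse than an error.
* OTUs missing from the taxonomy are treated as non-fungal and dropped
  with a message — the conservative reading when a kingdom cannot be
  confirmed.

## Rarefaction and alpha diversity

`rarefy_table()` performs a single uniform draw without replacement per
sample (the behavior of MOTHUR's subsample command), seeded and
reproducible. A single draw, rather than a multi-draw average, keeps the
output an integer table that downstream presence/absence analyses can
consume; the rarefaction-curve function provides replicate averaging where
the mean is wanted. Shannon diversity is reported in natural-log units and
evenness as Pielou's J = H / ln(S_obs), undefined (NA) when S_obs ≤ 1.
The curve machinery is validated against the closed-form hypergeometric
expectation for richness (the same quantity `vegan::rarefy` computes).

Kruskal–Wallis uses the tie-corrected H with a χ² reference (k − 1 dof);
an all-identical input is reported as H = 0, p = 1 rather than an error.
Welch pairwise tests report raw two-sided p-values for every unordered
pair — the convention of the field's group-comparison figures — with BH
q-values alongside, since all-pairs testing at raw p is anticonservative.

## Beta diversity and permutation tests

Bray–Curtis is computed by `vegan::vegdist`; NMDS by `vegan::monoMDS`
(Kruskal stress-1, primary tie treatment) wrapped with explicit random
restarts, the best of which is returned. ANOSIM (Clarke's R) and one-way
PERMANOVA (Anderson's pseudo-F and R²) are implemented in-package so that
their permutation machinery is fully controllable: the p-value convention
is (count + 1)/(n_perm + 1) with ties counted in the rejection region, and
`n_perm = "exact"` enumerates all n! relabelings for small n, which the
test suite compares against brute-force oracles (and against
`vegan::anosim`/`vegan::adonis2` as independent cross-checks of the
statistics). Only the one-factor design is offered: the target study
tests host and organ separately, and a multi-factor distance-based model
would exceed what the downstream interpretation uses. A degenerate
all-zero distance matrix is reported as R² = 0, p = 1.

Note a reporting subtlety: with few samples, permutations that preserve
the group partition tie with the observed statistic, so the attainable
p floor of ANOSIM under perfect separation is the partition probability,
not 1/(n_perm + 1).

## The preference framework (d′, standardized d′, 2DP)

The species-level matrix counts, for each host (or organ) category, the
samples in which each abundant fungus occurs. d′ follows the
Kullback–Leibler construction: interaction proportions against partner
availabilities taken from the matrix's own row marginals, rescaled by the
divergence of a fungus interacting only with the rarest partner
(d_max = ln(1/q_min)), with d_min = 0. The constrained integer minimum
used by some implementations is deliberately not reproduced: it is
algorithmic rather than closed-form, and the permutation standardization
cancels any affine convention to first order — which is also why the
standardized quantities, not raw d′, carry the inference. The
implementation is verified against an independently coded oracle on an
exhaustive sweep of small integer matrices.

Permutations shuffle the row-factor labels across **all** samples jointly
(sample contents intact). For the host analysis in the unbalanced
canonical design this lets organ signal leak into the host null; a
stratified mode (`stratify_by = "organ"`) is provided for that concern,
but the global shuffle is the default because it matches the plain
reading of "shuffling the species labels". Tails are one-sided upper
(preference = more specialized/more frequent than chance); two-sided is a
flag. Cells whose permutation sd is zero (e.g. a fungus present in every
sample, whose category counts no shuffle can change) are returned as NA
with a reason code and excluded from the FDR family — never ±Inf. FDR is
Benjamini–Hochberg within each family (fungi d′; categories d′; 2DP
cells).

The printed thresholds used in strong-pair summaries (e.g. 2DP > 2.7 for
hosts, > 2.2 for organs) are data-dependent conventions of the source
study design, so they are plain user parameters here.

## Co-occurrence networks

Spearman ρ between relative-abundance profiles of abundant OTUs, p from
the t-approximation on n − 2 dof; an edge requires |ρ| > 0.5 **and**
p < 0.01 (both strict). Negative correlations are kept — mutual-exclusion
edges are biologically meaningful — with a positive-only flag. No
multiple-testing correction is applied to edges by default, matching the
field's (liberal) convention; a BH mode exists. OTUs present in fewer
than 3 samples are excluded before correlation: they cannot support a
rank correlation.

Topology follows NetworkAnalyzer definitions: density 2E/(N(N−1)), mean
degree, mean local clustering (degree < 2 contributes 0), degree
centralization (N/(N−2))(k_max/(N−1) − density), characteristic path
length averaged over **connected pairs only** (thresholded networks are
usually disconnected), and heterogeneity as the coefficient of variation
of degrees using the population sd (that choice reproduces the closed
forms, e.g. 0.75 for a 5-node star). MCODE is the Bader–Hogue algorithm
with the published defaults (node score cutoff 0.2, 2-core requirement,
haircut on, fluff off); module score = density × size. Keystones are the
top-degree nodes with deterministic tie-breaking (abundance, then OTU
id).

## The synthetic community generator

`generate_community()` draws per-sample compositions as
softmax(baseline + host + organ + interaction + block latent), then counts
as Dirichlet-multinomial at a lognormal, lower-clamped depth. It emulates:
the crossed, slightly unbalanced design; a lognormal rank-abundance
profile (baseline sd 2 gives a realistic abundant-OTU fraction at the
default depth); host/organ-dependent composition; planted specialists
(expected abundance outside the target scaled by 1 − exclusivity);
correlated OTU blocks sharing a latent factor with loading √ρ; and
overdispersed counts (Dirichlet concentration 200 by default, Inf =
multinomial). Depths default to mean 60,000 clamped at 40,000 so
rarefaction to the ~39,948-read scale of the canonical design stays
meaningful. A fixed seed yields byte-identical output; the seed feeds
separate substreams for design, latent factors, sampling and taxonomy so
the phases do not interleave.

Deliberate design choices:

* **Block members are abundant.** Correlated blocks model co-varying taxa
  that the network stage can actually see (networks are built on abundant
  OTUs only), so block members are placed at the upper end of the
  baseline profile unless baselines are supplied explicitly.
* **Compositional closure is real and kept.** A strongly co-varying
  abundant block necessarily induces rank correlation among the remaining
  relative abundances (they share the complementary total). The generator
  does not hide this; consequently recovery tests judge planted blocks
  against the background distribution rather than demanding that every
  planted pair beat every background pair. This mirrors a known
  limitation of threshold-based Spearman networks on compositions, which
  the implemented method shares with its field.
* The taxonomy simulator assigns class/order labels with Dothideomycetes/
  Pleosporales given the largest prior mass, as a realistic label
  distribution for desert endophyte communities; labels carry no
  dynamics.

What the generator does **not** emulate: sequence-level error, chimeras,
phylogenetic signal among OTUs, spatial/plot autocorrelation (plots are
pure replicates), temporal dynamics, and taxonomy-linked abundance
structure. Tests passing on this generator therefore demonstrate the
statistical machinery — calibration under exchangeable nulls, power
against planted effects — not robustness to upstream bioinformatic
artifacts.

## Validation strategy and problem sizes

The test suite pairs every nontrivial statistic with an independent
oracle coded from first principles (loop-based d′; Gower-trace PERMANOVA;
exhaustive permutation enumeration; rank-then-Pearson Spearman;
closed-form topology on stars/cliques/cycles). Calibration tests run the
generator with all effect sds at zero — 200 replicate communities of 60
OTUs at depth ~2,000 with 199 permutations per test — and check type-I
error at α = 0.05 against binomial 99% bounds; these sizes are the
package's choice of a problem small enough to replicate densely while
keeping every design cell occupied. Recovery tests plant 10 exclusive
specialists per replicate (50 replicates, 1,499 permutations, so that the
BH-adjusted permutation floor is attainable within the cell family), a
star-structured hub, and correlated blocks of sizes 8 and 5; the worked
acceptance script runs the full pipeline at the canonical scale (337
OTUs, depth ≈ 60,000, 999–1,000 permutations).

## Known limitations

* Spearman-threshold networks inherit compositional bias; SparCC-style
  compositionality-aware inference is out of scope.
* Edge p-values use the t-approximation, approximate at n ≈ 12–15; a
  permutation mode exists but is slower.
* The d′ rescaling uses the unconstrained d_min = 0; raw d′ values can
  differ in scale (not in standardized form) from implementations using
  the constrained integer minimum.
* One-factor PERMANOVA/ANOSIM only; no strata-restricted permutations by
  plot in the default path (the design treats plots as exchangeable
  replicates).
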