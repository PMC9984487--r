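---
title: "Methods: polymer null models, Hi-C normalization and ZOI statistics for the Igh locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polymer null models, Hi-C normalization and ZOI statistics for the Igh locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighconform)
```

# Scope

`ighconform` implements the computational layer used to relate the 3D
conformation of the mouse immunoglobulin heavy-chain (Igh) locus to V(D)J
recombination outcomes: a confined self-avoiding polymer ensemble serving
as a null model for chromatin contacts; Knight–Ruiz (KR) balancing,
replicate concordance, quantile normalization and difference maps for
binned Hi-C matrices; virtual 4C viewpoint profiles with dual-replicate
peak calling; classification of three-color DNA FISH alleles into nine
spatial configurations; 3C crosslinking-frequency normalization; and
regional ("zone of influence", ZOI) statistics on V~H~ gene-usage tables.
Because the corresponding experimental data live in external repositories,
the package ships seeded generators that emulate every input's statistical
structure, and the whole pipeline is exercised against those.

# Coordinate conventions

Internally every interval is 0-based, half-open, BED-compatible. Printed
coordinates ("chr12:114182511-114183025") are treated as 1-based inclusive,
so that printed span arithmetic (a 515 bp deletion, a 758 kb probe
separation computed 5'-start to 5'-start) reproduces exactly. Matrices are
binned at 10 kb, the working Hi-C resolution; bins anchor at the region
start by default, and the cooler-style reader honours the file's own bin
table instead.

One deliberate non-reconciliation: the locus is described both by the
printed bounds chr12:113,215,000–116,045,000 (a 2.83 Mb span) and by a
3.31 Mb / 331-monomer parameterization. The two are inconsistent, so the
package accepts the analysis region and the bead count as independent
inputs and never silently derives one from the other.

# The confined self-avoiding polymer null

The null ensemble consists of chains of tangent hard spheres: one bead per
10 kb of chromatin, bead diameter 51 nm, bond length exactly one diameter
(the bond geometry is otherwise unspecified in the source protocol; fixed
bonds are the simplest choice consistent with tangent spheres). A chain is
feasible when no two non-bonded beads overlap and every bead lies wholly
inside a confinement sphere; "wholly" (centre within $R - d/2$) is our
reading of "reside within". Two beads are in contact when their centres
are $\le 80$ nm apart, inclusive.

The confinement radius derives from a measured nuclear volume scaled to
the locus at constant base-pair density:
$V_\mathrm{locus} = V_\mathrm{nucleus} \cdot L_\mathrm{locus} / L_\mathrm{genome}$.
The genome length is a **required** argument (`scale_locus_volume()`,
`confinement_radius_nm()`): published "scaled volume" figures cannot be
reproduced without knowing the genome size that was assumed, and the
quantity changes the confinement density materially. Throughout our own
fixtures we use $2.73\times10^9$ bp, the approximate length of the GRCm38
primary assembly. For a pro-B nuclear volume of 213 µm³ and a 3.31 Mb
locus this gives a confinement radius of
`r round(confinement_radius_nm(213, 3.31e6, 2.73e9), 1)` nm and a bead
volume fraction near 9%.

## Sampling scheme

Chains are grown sequentially (Rosenbluth sampling): at each step 40 trial
directions are drawn uniformly on the sphere, the feasible ones counted,
one feasible direction chosen uniformly, and the chain weight multiplied
by the feasible fraction. Weighted averages over such chains are unbiased
estimates of expectations under the uniform distribution over all feasible
chains — the property the package tests directly, comparing the weighted
end-to-end and bond-angle distributions of short chains against a plain
rejection sampler (Kolmogorov–Smirnov distance below 0.02 at 50,000
draws).

For locus-scale chains (331 beads at 9% density) the raw Rosenbluth
weights degenerate (effective sample size ~1%), so ensembles are grown as
a sequential Monte Carlo population: when the effective sample size falls
below half the population (`resample_threshold = 0.5`), chains are
resampled systematically by weight and the weights reset. Chains whose
growth dead-ends carry zero weight and are culled at the next resampling
pass; a final pass guarantees every returned chain is complete. Resampling
leaves estimates unbiased but correlates chains through shared ancestry,
which matters for error estimation (below). Setting
`resample_threshold = 0` recovers fully independent chains with restart-on
-dead-end semantics.

Desk defaults are 2,000 chains of 331 beads (seconds of CPU); the
production-scale recipe — 300,000 chains of 2,000 beads, locus-sized
windows drawn by `subsegment_ensemble()` — is the same code at cluster
cost.

## Error estimation and the shape of the decay curve

`distance_decay()` reports block-of-chains standard errors. With
resampling enabled, ancestral collapse adds a population-wide variance
component that block means cannot see, so block SEs understate the true
seed-to-seed spread; the acceptance checks therefore estimate errors
across independently seeded replicate ensembles instead.

Two genuine physical features of the uniform confined ensemble are worth
flagging because naive monotonicity checks trip over them: (i) the
contact frequency at the largest separations rises again — end beads are
less screened and the last stratum contains only end pairs (the rejection
oracle reproduces this); (ii) under strong confinement the curve flattens
to a plateau set by the confinement volume. The package asserts the
scientifically meaningful form of distance decay: no adjacent-separation
increase beyond three replicate-ensemble standard errors, plus a strongly
negative rank trend over the decay-dominated range.

# Hi-C normalization

`kr_balance()` is a port of the Knight–Ruiz inner–outer Newton iteration
with a damped Sinkhorn fallback, run to a row-sum coefficient of variation
of $10^{-6}$ (cap 3,000 iterations); zero-marginal bins (optionally a
bottom quantile) are masked, not balanced. Tests require agreement with an
independent Sinkhorn iteration run to convergence.

Replicate concordance uses the stratum-adjusted correlation coefficient:
Pearson correlation per diagonal stratum, combined with weights
proportional to stratum size times the geometric mean of the two stratum
standard deviations. The exact weighting is documented rather than
load-bearing — SCC is used as the merge gate (> 0.9), and a featureless
power-law matrix scores ~0 between its own Poisson replicates because all
within-stratum variation is noise; concordance above the gate requires
genuine structure (domains, stripes, dots), which the synthetic locus
provides.

Quantile normalization maps the unmasked upper-triangle cells at
separation $\ge 2$ bins (bonded neighbours are always in contact in the
null and are excluded; configurable) onto the sorted null values, ties
receiving the mean of the target values they span. Zeros are ordinary
values. When cardinalities differ, linear interpolation of the target
quantile function is available behind a flag. The operation is
rank-preserving and idempotent, and tie-averaging preserves the target
total, so two replicates normalized to one null carry identical aggregate
signal regardless of sequencing depth — the property asserted by
regressing replicate differences on separation (slope CI covering zero).
Whether the source protocol applied quantile normalization to raw or
KR-balanced counts is unstated; the package defaults to raw merged counts
for difference maps and KR-balanced matrices for virtual 4C, both
configurable.

## Reading difference maps

Difference maps subtract two quantile-normalized matrices (pro-B minus
reference in the motivating design). A caveat the synthetic experiments
make explicit: against the steeply decaying polymer null, distal cells map
to small target values while separation-2–4 cells occupy the large ones,
so rank and tie noise near the diagonal dominates the extreme difference
values. A strong distal planted dot lands around the 98th percentile of
the difference distribution rather than at the maximum; with a flat,
continuous normalization target the same dot is the locus-wide maximum
(top 0.1%). Difference maps against the polymer null are therefore best
read structurally (domains, stripes, dot neighbourhoods), not by ranking
single cells.

# Virtual 4C

A viewpoint profile is the matrix row at the viewpoint bin (row mean when
the viewpoint spans several bins), smoothed by a 30 kb window sliding in
10 kb steps — a 3-bin box filter truncated at the edges. Peaks are called
per percentile (top 15% and 25%): a bin is called iff it is strictly above
the per-replicate percentile threshold in **both** biological replicates.
The percentile population is the viewpoint's own smoothed profile within
the analyzed region (per replicate); the viewpoint bin and its immediate
neighbours are excluded from population and calls. Strict inequality means
flat profiles yield no calls. Calls depend only on ranks, hence are
invariant under monotone transforms applied to both replicates.

Because the profile population necessarily contains the distance-decay
flank, the top quartile of any decaying profile includes near-viewpoint
bins; "no false positives" can only be meaningful away from that flank.
The closed-loop experiment therefore places the viewpoint near the region
edge, plants three 5× dots at 250–450 kb, and scores (i) sensitivity —
all anchors called in the top 25% in both replicates — and (ii)
specificity as zero calls among *clear-background* bins, defined from the
noiseless expected matrix as bins at or below its own deterministic 60th
profile percentile, anchor footprints excluded. Near-threshold bins, which
flip by Poisson noise in any percentile scheme, are scored as neither.
Sensitivity is 100/100 simulations with a clean background at the study
settings (expected count 400 at one-bin separation, decay exponent −1).

# FISH configuration classification

Pairwise distances between the three probe signals are banded at
$\le 0.30$ µm (contact), $(0.30, 0.50]$ µm (intermediate) and
$> 0.50$ µm (far); the printed bands "<0.3 / 0.31–0.5 / >0.5" leave
(0.30, 0.31) undefined, and distances reported to 0.01 µm motivate the
closed-left reading that makes the bands exhaustive. The nine published
configurations (three-way overlap; three beads-on-a-string middles; three
pure pairwise contacts; all-intermediate; all-far) plus an explicit
`OTHER` — triples matching none, e.g. mixed intermediate/far with no
contact — partition every non-negative triple; the suite verifies the
partition on the full 0.01 µm grid over $[0, 1.2]^3$ and agreement with an
independently written predicate evaluator on 100,000 random triples.
Beads-on-a-string requires the long side merely to exceed the contact
threshold; whether pure pairwise configurations require the two open sides
to exceed 0.5 µm or only 0.3 µm is unstated, and the weaker reading is the
default (`pair_noncontact = "mid"` switches). Genotype comparisons use
per-category two-tailed 2×2 chi-square tests (Fisher's exact test when an
expected count falls below 1), distances are compared with two-tailed
Mann–Whitney U tests, and compaction curves plot mean spatial distance
against genomic separation computed 5'-start to 5'-start, the convention
that reproduces the printed 758 kb Eμ–E~VH~1 spacing.

# 3C and ZOI statistics

Relative crosslinking frequency is
$X = (S_\mathrm{Igh}/S_\mathrm{GD})_\mathrm{sample} /
(S_\mathrm{Igh}/S_\mathrm{GD})_\mathrm{control}$, which pins the
gene-desert reference at 1; the formula is exactly scale-invariant and
equals 1 whenever sample ratios match control ratios.

Usage fold changes are $(\mathrm{KO}+\varepsilon)/(\mathrm{WT}+\varepsilon)$
with $\varepsilon = 0.5$ applied only when a count is zero (printed
non-zero ratios are unperturbed); genes at zero in both genotypes are
flagged and excluded. Gene-to-bin aggregation assigns every gene to each
10 kb bin it overlaps; read counts are split proportionally to overlap so
bin totals conserve table totals (for the sub-bin-sized V~H~ genes the two
conventions coincide — the 87-genes-into-82-bins fixture is reproduced
exactly). The ZOI is supplied as an interval, never hard-coded (its
published definition is biological). `zoi_test()` is a two-tailed
Mann–Whitney U comparison of fold changes inside versus outside the ZOI,
applied per gene by default (per bin available); its p-values are
uniform under a null generator and reach >99% power at $\alpha = 0.01$
for a halved-usage ZOI at the study scale (87 genes, ~20 in the ZOI,
negative-binomial dispersion 10, depth 200).

# Synthetic data: what it emulates and what it does not

* **Hi-C**: expected counts follow
  $\Lambda_{ij} = \mathrm{depth}\cdot\max(|i-j|,1)^{\gamma}
  (1 + \textstyle\sum \mathrm{features})$ with $\gamma = -1$ (a typical
  mammalian decay; not taken from any measurement of this locus), plus
  multiplicative stripe/dot/domain features; replicates are independent
  Poisson draws. Defaults: depth 100 expected counts at one-bin
  separation; `igh_like_features()` provides a fixed nested-domain /
  stripe / corner-dot layout echoing the locus phenomenology. Real Hi-C
  adds mappability structure, translocations and overdispersion the
  generator does not model, so passing tests demonstrate algorithmic
  correctness, not robustness to artefacts.
* **FISH**: alleles are drawn per configuration category, distances
  sampled inside the defining bands subject to the triangle inequality,
  embedded with a uniform random rotation, jittered isotropically
  (σ = 0.02 µm) with jitter rejected if it would change the category.
  404 alleles per genotype matches the experimental scale. Chromatic
  aberration and segmentation error are not modelled.
* **Usage tables**: WT counts are negative binomial (dispersion 10)
  around lognormal per-gene baselines; the KO multiplies expected counts
  by `zoi_effect` inside the ZOI. Twenty of 87 genes are placed in the
  ZOI by default, mirroring the clustering of the proximal V~H~ families;
  uniform placement over 3.31 Mb would leave a 335 kb ZOI with too few
  genes for a meaningful rank test.
* **3C panels**: lognormal multiplicative noise split across the four
  signals so the recovered $X$ has exactly the stated coefficient of
  variation.

# Numerical choices and degenerate inputs

Symmetry is enforced within $10^{-8}$ relative and matrices re-symmetrized
by averaging; raw/KR/quantile kinds must be non-negative, difference maps
may not be. Dense-TSV round trips are bit-exact (17 significant digits).
KR masks zero-marginal bins and refuses fewer than two balanced bins.
SCC skips strata with fewer than 3 pairs and errors when none remain.
Percentile calls use `quantile(type = 7)` and strict inequality, so ties
are never called. Degenerate polymer geometries (a confinement sphere too
tight to continue growth) fail with explicit errors rather than returning
partial ensembles; importance-weight collapse below 1% effective sample
size warns, or errors in strict mode.

# Problem sizes used by the shipped checks

The test-suite and acceptance script run entirely on synthetic inputs at
desk scale, chosen to make each statistical property measurable with
comfortable margins: 2,000 × 331-bead ensembles for the exact physical
invariants, four independently seeded 500-chain ensembles for decay
errors, 50,000 draws for the sampler-uniformity KS checks, 100 seeded
simulations for virtual 4C recovery, 1,000 null draws for ZOI calibration
and 200 for power, and 100,000 random triples plus the full 0.01 µm grid
for the FISH classifier.

# Known limitations

* The SMC ensemble trades independence for effective sample size; users
  needing strictly independent chains should set `resample_threshold = 0`
  and accept the weight degeneracy at locus scale.
* Quantile normalization against a discrete desk-scale null carries
  tie-block granularity into the normalized values; production-scale
  nulls (hundreds of thousands of chains) reduce this.
* The percentile peak caller is intentionally faithful to its published
  description; it measures relative prominence within a profile, not
  statistical significance of individual contacts.
* No read-level processing, TAD/compartment calling, loop-extrusion
  simulation, or image processing is included; those are out of scope by
  design.
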