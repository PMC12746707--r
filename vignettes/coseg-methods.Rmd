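---
title: "Models and design choices in coseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in coseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coseg)
```

`coseg` collects the statistical machinery needed to evaluate a compound
(two-locus) inheritance hypothesis in a nuclear family: an exact
co-segregation probability for two linked loci, identity-by-descent (IBD)
segment detection from a family-scale multi-sample VCF, population-frequency
tiers with ACMG/AMP evidence combination, a network-randomization null for
gene–gene functional proximity, and the tally statistics used to score a
larval injection experiment. A synthetic-data module generates every input
the pipeline consumes, so all of it is testable offline. This vignette
explains the models, the tunable parameters, and the places where the design
was genuinely open and a choice had to be made.

## Two-locus co-segregation probability

Consider a nuclear family with $n$ genotyped children and a transmitting
parent whose two haplotypes are phased across loci $A$ and $B$ on the same
chromosome, separated by genetic distance $d$ (cM). Under no crossover
interference the Haldane mapping function gives the recombination fraction

$$r = \tfrac{1}{2}\left(1 - e^{-2d/100}\right) \in [0, 0.5).$$

A child inherits one of the two parental haplotypes with equal probability,
and carries a *specific* haplotype intact at both loci with probability
$(1-r)/2$. For a labelled configuration — a subset $C$ of children expected
to carry haplotype 1 at both loci, the complement expected to carry
haplotype 2 — meioses are independent, so

$$P = \left(\frac{1-r}{2}\right)^{n},$$

independent of $|C|$. `pattern_probability()` evaluates this closed form;
`simulate_meioses()` is a Monte-Carlo oracle that re-derives the same
quantity from simulated meioses (uniform haplotype at $A$, Bernoulli($r$)
crossover to $B$) with a binomial standard error.

Design choices:

* **Phase labelling.** The default probability is for the specific labelled
  assignment (haplotype 1 to $C$). `phase_agnostic = TRUE` doubles it to
  score the unlabelled bipartition; the labelled form is the default because
  that is the quantity a phased pedigree analysis computes.
* **Reporting precision.** Percentages are reported half-up to two decimals.
  For the worked four-child example at $d = 4.5093$ cM the closed form gives
  $5.2398\%$; a summary that prints $5.25\%$ is consistent with this value
  at the reporting precision, and a tolerance of $\pm 0.02$ percentage
  points is used when comparing against such rounded summaries.
* **Distance source.** `segregation_config()` accepts either precomputed cM
  positions or a distance; positions interpolated from a genetic map through
  `locus_cm_position()` give identical results by construction.

## Genetic maps

A genetic map is a per-chromosome table of (bp, cM) anchors; positions are
interpolated linearly. Three conventions are fixed here: the representative
point of a locus interval is its **midpoint** (maps report one cM value per
gene and do not state the convention); positions outside the anchored range
are **clamped** to the terminal anchor with a warning, because linear
extrapolation can produce negative genetic positions; and the cM column is a
cumulative position, not a recombination rate. Real interpolated gene
positions (e.g. 196.1223 and 200.6316 cM on chromosome 3) are treated as
inputs, not recomputed, since the underlying map is external.

## IBD segment detection

Input is a multi-sample VCF restricted to biallelic SNVs, with `GT`, `DP`,
`GQ` and `AD` per sample, plus a 6-column pedigree. Site filters mirror
standard family-WGS practice: per-sample read depth $> 14$ and genotype
quality $> 30$ (strict inequalities, applied to **every** pedigree member —
the stricter of the per-site/per-sample readings), Mendelian consistency for
every parent–child link, and minimal allelic imbalance, quantified as a het
alt-read fraction in $[0.25, 0.75]$ (a conventional heuristic; the bound is
configurable). Failures are reported as per-site reasons, never errors.

For a sibling pair, a site is *informative* when at least one parent is
heterozygous and each sib's maternally and paternally transmitted alleles
are uniquely resolvable from the four genotypes; double-heterozygous
configurations with heterozygous children are ambiguous and dropped (an
optional allele-depth tie-break resolves them by taking the better-supported
allele, off by default — it is a heuristic, not an inference).

A parental transmission is *shared* when both sibs received the same allele
from a heterozygous parent. The collapsed per-site state (`IBD0/1/2`) is
called only when **both** parental transmissions are observed. At biallelic
sites this has a consequence worth stating plainly: inside a true IBD1
region no site can demonstrate both a shared and an unshared transmission
simultaneously, so a segmenter driven by the collapsed state would never see
IBD1 support. Segment detection therefore operates on the two per-parent
share tracks separately — on noiseless data each track is exact and
piecewise constant, with change points at crossovers. Within a track,
shared sites support a run and unshared sites close it; runs shorter than
`min_sites = 5` supporting sites or interrupted by gaps larger than
`max_gap_bp = 1e6` are discarded or split (neither value is externally
specified; these defaults suit family WGS marker densities and are plain
arguments). The two track interval sets are then combined: positions covered
by one track are `IBD1`, by both `IBD2`. Segments are reported 1-based
inclusive internally and written 0-based half-open in the BED-like output.

## Population frequency and ACMG/AMP combination

Allele frequencies are exact ratios AC/AN, reported to three significant
figures. Tiers follow the conventional thresholds: very rare
($\mathrm{AF} < 10^{-4}$), rare ($10^{-4}$–$10^{-3}$), common
($> 10^{-3}$); the interval descriptions overlap at the boundaries, which
are assigned to the closed middle tier. Evidence combination implements the
standard pathogenic-side ACMG/AMP rules (very strong / strong / moderate /
supporting, combined by the published tables) with anything short of Likely
Pathogenic reported as VUS; benign-side codes are rejected rather than
silently ignored. Qualifiers such as "tendency toward LP" are annotations,
not classes. Population records are plain data inputs — no live database
access.

## Network-randomization null

The observed statistic for a node is its mean weighted shortest-path
distance to the seed genes (a seed excludes itself from its own average).
Two open points are resolved as follows and kept configurable:

* **Weight transform.** Association weights are converted to edge lengths as
  $1/w$, so stronger associations are shorter; the transform is a single
  injectable function.
* **Averaging target.** "Average shortest-path distance for each node" is
  read as the mean over the *seed genes*; averaging over all nodes would
  make per-node proximity significance meaningless.

The null preserves each node's exact degree and the exact multiset of edge
weights: topology is rewired by repeated degree-preserving double-edge swaps
(10× the edge count by default) and the weights are then permuted over the
rewired edges. The raw p-value is the plain proportion of simulations with a
simulated distance $\le$ the observed one — it can be exactly 0; an
optional $(r+1)/(n+1)$ estimator exists but is off by default. Draws in
which a node is disconnected contribute $+\infty$ (never $\le$ a finite
observation) and are counted, keeping `n_sim` as the denominator. Batching
(`n_sim = 1000` in batches of 200 by default) is purely an execution
detail: results are bit-identical for any batch size under one seed.
Benjamini–Hochberg adjustment is appended across nodes; the call threshold
for "notably proximal" genes is raw $p < 0.01$, strict.

## Phenotype statistics

Larvae are classified from six feature flags. Severe features: cardiac
edema, severe bidirectional tail malformation, severe jaw malformation,
cleft-like facial defect, severe axis defect. Moderate abnormalities:
non-inflated or partially inflated swim bladder, mild tail curvature, jaw
protrusion or mild asymmetry. `strong` requires two or more severe features;
`medium` one or more moderate abnormalities; a larva with exactly one severe
feature and no moderate abnormality falls between the published definitions
and is assigned to `medium` (the conservative choice; classification is then
monotone in severity). Percentages are rounded half-up to one decimal,
matching the printed style. Group comparisons use Pearson's chi-square
without continuity correction by default (a flag enables Yates); expected
cells below 1 annotate the result rather than suppressing it. Angle
comparisons use the tie-corrected Kruskal–Wallis test.

## Synthetic data

The generators produce inputs with the statistical structure the analysis
assumes, and only that structure:

* **Families.** One 100 Mb chromosome with a uniform 1 cM/Mb map and 8000
  biallelic sites at founder allele frequency 0.5 — a conservative subset of
  the informative-marker density of real WGS. Crossovers per meiosis are
  Poisson with mean equal to the map length in Morgans and are placed
  uniformly **on the cM scale**, which is what "no interference" means
  operationally on a genetic map. Child haplotypes are exact parental
  mosaics, so the true IBD tiling is available from the recorded crossovers
  (`true_ibd_segments()`).
* **Reads.** The noiseless model (`depth_model = "fixed"`) writes every call
  at the configured depth with clean allele splits and maximal GQ; the
  Poisson model draws depth, binomial allele depths, and a simple monotone
  GQ in depth penalized by imbalance. No attempt is made to emulate a real
  caller — only the filter thresholds matter downstream.
* **Networks.** An Erdős–Rényi background (mean degree 4) with a planted
  dense, high-weight module containing both seed genes; stray components are
  attached so distances are finite. Truth labels mark module membership.
* **Phenotypes.** Class mixtures per group follow the printed seven-group
  design (e.g. 0.657/0.257/0.086 for the combined-mutant group, $n = 152$);
  feature combinations are drawn by rejection sampling against the
  classifier itself, keeping generator and classifier decoupled.
* **Angles.** Per-group Gaussians truncated to $(0, 180)$ degrees with
  $n = 20$ per condition; group means 60–72° with a common 5° SD, in the
  published direction of effect (wider angles in mutant groups).

What the generators deliberately do **not** emulate: linkage disequilibrium
among founder sites, population demography, read-level artefacts, caller
biases, scale-free network topology. Passing tests on synthetic data
therefore demonstrate correctness of the algorithms under the stated model,
not robustness to every property of real data.

## Numerical and testing conventions

Every stochastic function is a pure function of its seed. Monte-Carlo
checks compare at three binomial standard errors. The test suite exercises
the study-scale configurations directly: the meiosis engine at $2\times
10^5$ simulated families, IBD recovery over 20 simulated sib pairs
(expecting $\ge 90\%$ of true IBD1+IBD2 length recovered and segment ends
within one informative inter-site gap of the truth), null-calibration over
500 replicates (uniformity of the empirical p-value), and planted-module
detection over 20 generator seeds at 1000 simulations in batches of 200 on
200-node networks — sizes chosen so the full suite runs on a single CPU in
a few minutes while keeping the Monte-Carlo tolerances meaningful.

## Known limitations

* IBD detection targets one nuclear family; it is not an HMM caller and
  does not phase by imputation, handle the X chromosome specially, or scale
  to cohorts.
* The co-segregation model covers two loci and one transmitting parent;
  no interference models, no LOD scores.
* The collapsed per-site IBD state is intentionally conservative at
  biallelic sites (see above); consumers who need per-site calls inside
  IBD1 regions should use the per-parent share columns.
* The ACMG engine implements the pathogenic side only, as a deterministic
  rule table — not a Bayesian point system.
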