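---
title: "Hybrid class inference on triangle plots: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid class inference on triangle plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trihybrid)
```

## The estimators

Given two designated parental groups, `select_aims()` computes for every
biallelic SNP the sample allele frequency in each group (non-missing
allele copies only, counts divided once so the fractions are exact) and
the difference δ = |p̂₁ − p̂₂|. Sites with δ at or above the threshold are
ancestry-informative markers (AIMs). Per individual, over its non-missing
AIM genotypes:

- hybrid index `h` = (number of P2-associated alleles) / (2 × sites),
- interclass heterozygosity `H` = (heterozygous sites) / (sites).

Both are undefined (`NA`) only when every AIM genotype is missing.
`perc_missing` reports the missing fraction so that noisy individuals
can be flagged on the plot.

**Orientation.** One parental group must sit at each end of `[0, 1]`.
The choice is arbitrary; this package fixes `p2 = 1` and records the
orientation in the triangle-table metadata, so results are stable across
runs and swapping the labels simply reflects the plot.

**Threshold semantics.** The δ threshold is inclusive (δ ≥ t, compared
with a `1e-12` tolerance): a threshold of 1 retains exactly the fixed
differences, which would be impossible with a strict inequality.
Consequently AIM sets are nested as the threshold decreases, which the
suite checks as a monotonicity property. Whether other implementations
treat the threshold strictly is not asserted here; ours is documented
behavior, not a parity claim.

**Missing data.** Half-called diploid genotypes (`./1`) are treated as
fully missing. A half call carries a defined allele, but counting one
allele copy at a site would put individuals on different denominators
for `h` (allele copies) and `H` (sites), biasing both; dropping the call
keeps the two estimators on the same per-site footing. Multiallelic
records, indels and spanning deletions are excluded outright — the
method is defined on biallelic SNPs only — and positions stay 1-based as
in the VCF.

**Per-site minimum.** `min_alleles` (default 2, i.e. one genotyped
individual per parental group) controls when a parental frequency is
considered defined at all. The default is permissive by design: the
sample-size machinery below exists precisely to show what small parental
samples do to δ.

## The Hardy-Weinberg engine

On fixed-difference AIMs, `h` equals an individual's genome-wide
frequency of the P2-associated allele and `H` its genome-wide
heterozygote frequency. For a cross between individuals with genome-wide
frequencies `hA` and `hB` (mean `m`, between-parent variance
`s2 = ((hA − hB)/2)^2`), the expected offspring genotype frequencies are

$$E[p_{11}] = m^2 - \sigma^2,\quad
  E[p_{12}] = 2m(1-m) + 2\sigma^2,\quad
  E[p_{22}] = (1-m)^2 - \sigma^2.$$

The variance enters with the opposite sign to the classical Wahlund
deficit: differing parents create *excess* offspring heterozygosity.
Algebraically `p11 = hA·hB` and `p22 = (1−hA)(1−hB)`, so the components
are nonnegative and sum to one for any inputs in the unit square, and
`p12` can never fall below the equal-parent value `2m(1−m)` — which is
why no cross under HWE produces offspring below the curve
`y = 2x(1−x)`. Equal-parent crosses reduce to the textbook HWE formula.
These are asserted as property sweeps over a dense grid, not just at the
canonical points.

`class_expectations()` iterates this engine along the canonical
pedigrees rather than hard-coding coordinates; the halving law (the
n-th backcross sits at offset `2^-(n+1)` with heterozygosity `2^-n`)
comes out of the iteration and is cross-checked in the tests against an
independent two-haplotype Mendelian simulation at 10^5 unlinked sites
(agreement within 3 Monte-Carlo standard errors). After four backcross
generations the expectations (0.03125, 0.0625) are already hard to
distinguish from a parental individual — a genuine interpretive limit of
triangle plots, not an estimator defect.

`enumerate_space(g)` accumulates every (h, H) point reachable within
`g` generations starting from the two parental states. Matings are
allowed with individuals from *any* earlier generation, including the
parentals — without that, backcrosses could never arise. Whether a
stricter generation-adjacency rule changes the reachable set is left
open; the inclusive interpretation is documented, and every enumerated
point is verified to lie in the closed triangle. Points are
deduplicated at `1e-12`; hybrid indices are dyadic rationals
(`k / 2^g`), so exact collisions are the norm rather than the
exception. The default cap of 8 generations guards against the
quadratic pair growth; 6 generations (the conventional overlay cloud)
yields a few hundred points in milliseconds.

`classify_point()` uses a `1e-9` tolerance: points within it of the
curve are reported `on_curve`, beyond the bounding lines
`outside_lines`, below the curve `below_curve`. Individuals below the
curve are the diagnostically interesting ones — no HWE cross can put
them there, so an excess suggests drift, selection or nonrandom mating.

## What the simulator emulates — and what it does not

`simulate_parental_pools()` draws two populations at unlinked sites:
a configurable number of true fixed differences (frequency 0 in P1, 1 in
P2) plus sites whose per-population frequencies come from a Beta
spectrum (default uniform, giving a broad spread of true δ). Genotypes
are two binomial allele copies at the population frequency — i.e.
within-population HWE. Defaults are 20 individuals per parental pool and
20 individuals per hybrid class, the conventional design for this kind
of validation; the depth experiments use 500 fixed-difference sites, and
the pedigree cross-checks 10^5, sizes at which the binomial standard
errors make the assertions sharp.

`make_hybrid_classes()` constructs F1s by drawing one allele from each
parent at every site, F2s by pairing each F1 with a different F1
(a cyclic shift guarantees distinct partners), and first-generation
backcrosses by pairing each F1 with a randomly chosen parental
individual. `downsample_depth()` draws `depth` alleles *with
replacement* from a genotype's two copies and recodes heterozygous only
if both alleles appear — the natural reading of per-site allele
sampling; sampling without replacement from sequenced fragments would
need a fragment-count model the package deliberately does not have.
There is no sequencing-error, mutation or gene-conversion model, so
only true heterozygotes can be miscalled, always toward homozygosity,
with survival probability `1 − 2^(1−d)` at depth `d` — the closed form
the tests pin the simulator against.

Real data differ from this generator in ways that bound what passing
tests can show: real loci are linked (estimates over few RAD loci are
noisier than the unlinked binomial math suggests), allele-frequency
spectra are shaped by demography rather than a Beta, depth varies across
sites and individuals, and genotyping error is not purely
depth-driven. The package's validation claims are therefore statements
about the estimators under their own model, plus the qualitative
phenomena (false fixed differences under small parental samples,
heterozygosity attenuation with depth, depth-invariance of the hybrid
index in expectation) that do carry over.

`subsample_parentals()` relabels the parental individuals it drops as
`"<label>_excluded"` rather than deleting them: they keep being scored,
which is exactly the situation of an unassigned true parental in an
empirical dataset, and the false-fixed-difference analysis needs them in
the table.

## Error metrics

Accuracy is `1 − |mean(obs) − expected| / expected`, reported as a
percentage and deliberately unclamped — a grossly wrong class mean goes
negative rather than saturating at 0. It refuses `expected = 0`
(parental heterozygosity) and directs callers to the mean absolute
error, which is defined there. Precision is the mean Euclidean distance
of each estimate from the class centroid: 2-D on the triangle plot by
default (its units are plot distance), per-axis on request; the two
disagree and are reported separately rather than mixed.

For the parental-misassignment analysis, hybrid indices are folded
(`h > 0.5` becomes `1 − h`) before log-fold-change so that negative
values always mean "shifted toward the nearest parental extreme". The
log is natural and the zero-handling epsilon defaults to `1e-6`; the
base only rescales the statistic and the epsilon is exposed, since
neither choice is canonical.

## Numerical and interface choices

- Frequencies are exact count ratios; δ comparisons use a `1e-12`
  tolerance; genotype-frequency conservation is asserted at `1e-12`.
- Undefined estimates serialize as `NA` in the TSV; rows are never
  silently dropped, and an individual with 100% missing AIMs keeps its
  row with `perc_missing = 100`.
- Every stochastic operation takes an explicit seed (one global RNG
  stream per call); the CLI auto-generates and logs a seed when none is
  given, so any run can be reproduced from its log.
- The triangle plot draws points exactly at their table coordinates;
  jitter is off by default, cosmetic only, and seed-controlled when
  enabled. The boundary is computed analytically — the generation-6
  point cloud is an optional overlay, never a substitute for the exact
  curve.

## Limitations

Diploid genotypes only (no genotype likelihoods, no imputation, no
BCF/CRAM); no F_ST-based or model-based marker ranking; no LD pruning;
no Bayesian interpopulation-ancestry estimates or credible intervals.
The enumeration engine is strictly neutral HWE — selection, drift,
mutation and linkage are out of scope by construction, which is what
makes departures from the triangle interpretable.
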