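---
title: "Singleton-density selection scans: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Singleton-density selection scans: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdscan)
```

## The problem

Very recent positive selection — on the order of the last hundred
generations — barely moves the haplotype-based statistics (iHS, XP-EHH)
that detect classical sweeps. What it does move is the genealogy's *tip
branches*: when a derived allele has risen rapidly, the haplotypes that
carry it descend from a recent expansion and their terminal branches are
short. Singletons (variants seen on exactly one haplotype in a dataset)
arise on tip branches, so haplotypes carrying a recently risen allele are
locally **singleton-poor**. A singleton-density score (SDS) turns this into
a per-variant statistic: for each individual, measure the distance from a
test variant to the nearest singleton that individual carries on either
side, and contrast the implied singleton intensity between haplotypes
carrying the derived versus the ancestral allele.

`sdscan` implements this scan for phased multi-dataset WGS panels together
with the three enrichment analyses that typically accompany it — derived
allele frequency (DAF) heterogeneity across geographic subpopulations,
selection scores inside archaic-introgression tracts, and selection
enrichment in trait-associated variant sets — plus a seeded generator that
emulates the statistical structure of all of these inputs, so the entire
pipeline can be exercised and calibrated without access-restricted cohort
data.

## The gap likelihood

For individual $i$ with genotype split $(n_{\mathrm{anc}}, n_{\mathrm{der}})$,
$n_{\mathrm{anc}} + n_{\mathrm{der}} = 2$, each haplotype is modelled as an
independent Poisson singleton process with intensity $\lambda_a$
(ancestral-carrying) or $\lambda_d$ (derived-carrying) per bp. The nearest
singleton distance on one side of the test variant is then exponential with
the summed rate $\lambda(i) = n_{\mathrm{anc}} \lambda_a +
n_{\mathrm{der}} \lambda_d$, and the total flanking gap $g_i$ (upstream +
downstream distance) is Gamma with shape 2 and rate $\lambda(i)$:

$$
\ell(\lambda_a, \lambda_d) \;=\; \sum_i \bigl[\, 2 \log \lambda(i)
  \;-\; \lambda(i)\, g_i \,\bigr].
$$

The raw score is $\log\hat\lambda_a - \log\hat\lambda_d$: positive when
derived haplotypes are singleton-poor, i.e. under a recent rise of the
derived allele. Homozygote-only data give the closed form
$\hat\lambda = 1/\overline{g}$ per class; with heterozygotes the
likelihood is concave and each coordinate update has a closed-form
positive quadratic root, so the optimizer is an exact coordinate ascent
(convergence when the log-likelihood moves by less than `1e-10`, at most
200 iterations, rates capped to $[10^{-12}, 10^{12}]$ per bp — hitting a
cap skips the variant with a reason code).

This likelihood is deliberately simpler than the original SDS, which
calibrates Gamma shape parameters per frequency bin from an explicit
demographic model. That calibration needs an external demography and the
original authors' scripts; here the DAF-bin standardization (below) absorbs
the frequency-dependent scale instead. This is the package's one
substantive modelling deviation, and the null-calibration and
parameter-recovery suites exist to show it behaves: on neutral panels the
final z is standard normal with a calibrated 5% tail, and a planted
selected locus is recovered far in the upper tail.

Censoring: individuals lacking a flanking singleton on either side within
the chromosome arm are dropped from the likelihood rather than imputed to
the arm boundary; variants closer than one median gap to an arm end are
skipped entirely (their gap distribution is censoring-biased). A variant is
scored only if, after censoring, at least `min_class_count = 10`
individuals carry an ancestral haplotype and at least 10 a derived one.

## From raw scores to genome-wide P-values

Raw scores are computed separately per chromosome arm and per dataset, then
standardized within DAF bins per dataset: bin width 0.005 where DAF < 0.1
or > 0.9, width 0.01 in between, bins half-open, bins holding fewer than
`min_occupancy = 20` scores merged with their nearest neighbour. Within a
bin, scores are centred and scaled by the *population* SD (so a two-score
bin $\{-1, 1\}$ maps to $\{-1, 1\}$). Variants scored in **all** datasets
are meta-analyzed with weights $w_i = \sqrt{n_i}$:

$$
z_{\mathrm{meta}} \;=\; \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}},
$$

then re-standardized once genome-wide (a single mean/SD — not per bin; the
re-normalization is a global correction for residual scale) to the final z,
with two-tailed $P = 2\Phi(-|z|)$ and the conventional genome-wide
significance flag at $P < 5 \times 10^{-8}$.

## Singleton filters

Two filters precede scoring, both flag-only (no catalog entry is ever
deleted, so provenance is auditable): an exclusion mask for regions where
calling is unreliable (centromere-like intervals, supplied as BED), and a
density filter that computes singleton counts in 20-kbp half-overlapping
windows (step 10 kbp, tiled from 0 over every window intersecting an
analyzable arm, *empty windows included* in the mean/SD) and removes
entries in any window whose count strictly exceeds mean + 4 SD. The
one-sided high tail is intentional: pileups are the footprint of calling
artifacts. A singleton covered by two windows is removed if *either* is
over threshold. Private doubletons (derived allele twice, both copies in
one individual) are treated exactly as singletons throughout: the gap model
sees them as one event at one position on one individual.

Interpretation choices the filter documentation pins down: windows tile per
chromosome (not per arm), and window statistics pool all windows within a
dataset genome-wide. Both are defensible readings of the usual "+4 SD"
description; they are defaults, exposed as parameters.

## Coordinates

Variant positions are 1-based (VCF convention); all intervals — masks,
tracts, density windows — are 0-based half-open (BED convention). A single
membership helper owns the off-by-one: 1-based position $p$ is inside
$[s, e)$ iff $p - 1 \in [s, e)$. Ancestral-allele annotations are assumed
to be on the reference strand; sites whose ancestral allele matches neither
REF nor ALT are dropped and counted, never guessed, and multi-allelic
records are excluded so polarity stays well defined.

## The enrichment procedures

**DAF heterogeneity.** For a subpopulation × {derived, ancestral} allele
count table, the index is Pearson's $\chi^2 / N$ — zero for identical
frequencies, one for complete separation, and bounded by 1 for any number
of subpopulations (Cramér, df = 1). The null for a focal variant is the
empirical set of indices of all scored variants within ±0.005 of its pooled
DAF (widened symmetrically if fewer than `min_null = 100` variants, and
flagged); the one-tailed P is the add-one exceedance probability with ties
counting against enrichment, and fold change is the observed index over the
null mean. The pooled DAF indexes the bin because it is the only frequency
defined for every cohort.

**Introgression tracts.** The mean final z of variants inside a tract set
is compared with a null built by *rotating* the tract set along the
concatenated chromosomes in 10,000 systematic increments of 0.01% of the
total length, wrap-around tracts splitting in two. Variants never move, so
the local autocorrelation of the z field is preserved — this is the point
of rotation over naive resampling. The two-sided P centres the observed
mean at the mean of the null means, which makes the test exact for the
systematic rotation family; the schedule is deterministic, so no seed is
involved. Rotations covering zero variants are excluded and counted.
Masked regions stay in the coordinate system (compacting them is a
documented alternative, off by default).

**Trait variant sets.** Genome-wide final z values are rank-normalized
($z'_i = \Phi^{-1}((r_i - 0.5)/M)$, average ranks for ties), each trait
variant is mapped to itself if scored or else to the scored variant with
maximal phased-haplotype $r^2 > 0.5$ within 1 Mbp (variants mapping to the
same proxy collapse to one; unmapped variants are dropped and counted), and
$S = \sum z'^2$ is referred to $\chi^2_k$. The $\chi^2_k$ reference assumes
independence among a trait's variants, which LD violates; the statistic is
reported as is, matching standard practice, and this caveat is the reason
the locus-removal sensitivity rerun exists: removing the few
genome-wide-significant loci and recomputing ranks shows which trait
signals are driven by a single selected region. Bonferroni flags use the
fixed threshold $\alpha / n_{\mathrm{tests}}$; the sensitivity rerun uses
Benjamini–Hochberg q-values.

## What the generator emulates — and what it does not

`simulate_panel()` produces phased panels whose *statistical* structure
matches what the scan consumes: several datasets of unequal size; common
variants at configurable DAFs with independently assigned haplotypes;
singletons as per-haplotype Poisson processes at rate `lambda0`, thinned by
`rho < 1` inside a selected-locus window on haplotypes carrying the derived
core allele; a fraction of rare events emitted as private doubletons; and,
inside selected windows only, haplotype-block copying (`ld_copy_prob`) that
gives window variants $r^2 \approx$ `ld_copy_prob`$^2$ with the core — the
only linkage in the generator, there so LD-proxy lookup and trait-set
enrichment have real structure to find.

The class-specific Poisson rates are exactly the process the simplified
likelihood assumes, so parameter recovery is exact in expectation — that is
a design decision, not an accident: it lets the test suite separate
"the statistics are implemented correctly" from "the model fits real
genomes". What the generator deliberately does **not** emulate: coalescent
genealogies and demography, recombination, background LD outside selected
windows, mutation-rate heterogeneity, and calling error. Passing
calibration here therefore validates the machinery, not the adequacy of
the Gamma(2) gap model on real data.

Regional allele-frequency structure is generated by the Balding–Nichols
model: per region, the derived frequency is drawn from
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ around the pooled $p$, with
counts binomial given cohort sizes. Selection's footprint on geography is
emulated as an inflated drift parameter for selected variants (default
×10), which is sufficient to power the heterogeneity test without modelling
frequency trajectories.

## Defaults and why

* **Dataset sizes (1276, 492, 466)** and **regional cohort proportions**
  (seven regions, 7910 / 10,907 / 95,272 / 9390 / 26,160 / 15,818 / 5719 of
  171,176) mirror the study design the package emulates.
* **Drift F = 0.0047** is the observed differentiation between the two
  major population clusters (main islands vs. Okinawa) in that design; it
  is the natural scale for "realistic" regional heterogeneity.
* **`lambda0 = 5e-5` singletons/bp/haplotype** makes an individual's
  flanking gap about 10 kbp per side, so desk-scale arms of a few Mbp hold
  hundreds of scorable variants with negligible censoring. Real genomes
  have sparser singletons and proportionally longer gaps; the score is
  scale-free in this rate, so the choice affects runtime, not validity.
* **Selected-window half-width 50–100 kbp on Mbp-scale toy genomes** keeps
  window variants a small fraction of all scored variants. This matters:
  window variants inherit the core's DAF (through block copying) and pile
  into the same standardization bins, so an over-represented window drags
  its own bin mean upward and dilutes the signal — a fixture-scale artifact
  to manage, since in a real genome selected windows are ≪ 1% of scored
  variants.
* **Scan and filter parameters** (20-kbp windows, +4 SD, MAF ≥ 0.01, bin
  widths 0.005/0.01, $5\times10^{-8}$, ±0.005 heterogeneity bins, 10,000
  rotations at 0.01%, $r^2 > 0.5$, $\alpha = 0.05$) are the field-standard
  values and are all exposed in `run_config()`.

## Problem sizes used by the test and acceptance suites

The calibration suite scans a neutral panel of three datasets of 200
samples with ~2400 common variants on a 10-Mbp genome; the
parameter-recovery suite runs 20 seeded replicates of three datasets of 500
samples with 1500 common variants on a 5-Mbp genome and a single selected
locus (ρ = 0.2, DAF 0.5, 50-kbp half-width); the type-I suites use 1000
simulated sets. These sizes were chosen once as the smallest designs at
which the checked properties are statistically meaningful (e.g. a 99.9th
percentile needs >1000 neutral variants; a tail-fraction check at ±0.01
needs >2000 scores).

The recovery suite runs the generator with block copying disabled
(`ld_copy_prob = 0`): the experiment contrasts the selected core with
*neutral* variants, and copied window variants are not neutral — they carry
real signal and, because they inherit the core's DAF, they crowd into the
core's own standardization bins and dilute it (the fixture-scale artifact
described under defaults). With copying off, the core is the only
non-neutral variant and its recovered z reflects the depletion signal
alone. The LD-dependent suites (proxy lookup, trait enrichment, locus
removal) keep copying on, since LD is the very structure they test.

## Numerical and degenerate-input choices

Ties in rank normalization get average ranks (hence identical $z'$).
Monomorphic contingency tables return index 0 by convention; subpopulations
with zero alleles are dropped with a warning. A bin whose scores are all
identical standardizes to 0. Empty trait sets and variant-free tract sets
are reported with reason codes or informative errors rather than NAs.
All generators are pure functions of `(config, seed)`; pipeline stages
derive sub-seeds by stable hashing of (run seed, stage name), so toggling
one stage never shifts another's random stream, and the rotation
permutation needs no seed at all.

## Known limitations

* The Gamma(2) gap likelihood ignores demography; absolute raw scores are
  not comparable to the original SDS values and only the standardized,
  meta-analyzed z is interpretable.
* The $\chi^2_k$ trait reference ignores LD between a trait's variants.
* The heterogeneity null conditions only on DAF, not on local LD or
  genotyping cohort.
* The generator's linkage model (block copying) produces rectangular LD
  blocks, not decaying LD; proxy-search behaviour beyond the window is
  untested against realistic LD decay.
* Arm-end censoring discards information rather than modelling it; variants
  near arm boundaries are simply not scored.

## A worked micro-example

```{r example, eval = FALSE}
cfg <- sim_config(
  seed = 7, layout = toy_layout(1, 2.5e6, 2),
  sample_sizes = c(120, 120, 120), n_common = 800,
  selected = tibble::tibble(chrom = "chr1", pos = 1250000L, daf = 0.5,
                            rho = 0.2, half_width = 5e4)
)
run <- run_pipeline(run_config(sim = cfg, iterations = 1000), "scan_run")
dplyr::filter(run$sds, significant)
autoplot(run$sds)
autoplot(run$introgression)
```
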