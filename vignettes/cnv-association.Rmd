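---
title: "Segment-based CNV case/control association: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-based CNV case/control association: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrscan)
```

This vignette is the package's account of its science: the statistical
procedure, the assumptions behind each stage, the parameters that matter
and their defaults, what the synthetic-cohort generator does and does not
emulate, and the design choices made where the method description leaves
the design open.

## The association model

The unit of evidence is the probe-level carrier table. For a fixed CNV type
(deletion: copy number < 2; duplication: copy number > 2), a sample
*carries* a probe if at least one of its calls of that type spans the probe
position (1-based inclusive on both sides). At each probe this gives a 2×2
table — `a` carrier cases of `n1`, `c` carrier controls of `n2` — tested
with the Fisher exact test. The default is the one-sided upper
hypergeometric tail (enrichment in cases), which is the convention under
which published CNVR p-values at these group sizes reproduce exactly; a
two-sided test by the point-probability rule is available via
`sided = "two"` and coincides with the one-sided value for the sparse
tables this scan produces.

Three rules turn probe tests into region tests:

1. **Prefilter.** Only probes with `a >= 3` case carriers are kept.
   `min_nominal_case_count(n1, n2)` shows why 3: it is the smallest case
   count whose best-case table (all carriers in cases, none in controls)
   reaches nominal p < 0.05 — at 63/145, p(2 vs 0) ≈ 0.091 while
   p(3 vs 0) ≈ 0.027. The implied minimum case frequency is
   3/63 = 4.76%, the CNV analogue of a minor-allele-frequency cutoff.
2. **Collapse.** Retained probes of one type are swept left to right;
   a probe joins the current region while it is on the same chromosome,
   `< 1 Mb` from the previous retained probe, and within ±1 log10 unit of
   its p-value. Probes with zero carriers in both groups are dropped first
   — their p = 1 would otherwise bridge unrelated regions.
3. **Represent and correct.** A region's p is its member minimum, reported
   at the *anchor* probe (the leftmost minimizer) together with that
   probe's carrier counts, so the printed p is exactly the Fisher p of the
   printed counts. The experiment-wide threshold is Bonferroni:
   `fwer / (n_deletion_regions + n_duplication_regions)`; 20 + 69 regions
   at FWER 0.05 give 0.05/89 = 5.62 × 10⁻⁴.

Deletions and duplications are scanned fully independently and a region is
never of mixed type. Because region counts (not probe counts) set the
correction, and because the prefilter conditions on *case* carriers, the
procedure is not a textbook Bonferroni: see *Known limitations*.

### Open design points and how they were fixed

* **Band comparison.** "Comparable significance (±1 log p)" can be read
  against the previous retained probe (chained) or against the running
  region minimum. Both are implemented (`band_mode`); chained is the
  default because it is the simpler sweep — a monotone drift of more than
  one decade total then stays in one region, while `"region_min"` splits
  it. On sparse carrier data the two rarely differ, because member probes
  of a true CNVR share a carrier set and hence a p-value.
* **Anchor counts vs union counts.** Carrier counts at the anchor probe are
  the primary report; union counts over the whole region span
  (`*_carriers_union`) are emitted alongside, since a wide region can touch
  more samples than any single probe.
* **Ties.** Equal member p-values anchor at the leftmost probe; a gap of
  exactly 1 Mb splits (the proximity rule is strict).

## Sample quality control

Four per-sample metrics drive inclusion, with the standard array-CNV
thresholds (all strict): genotyping call rate > 0.98, LRR standard
deviation < 0.3, |GCWF| < 0.02, CNV count < 100. The LRR SD and GCWF
conditions are jointly required by default; `lrr_gcwf_logic = "or"` accepts
either one instead, for compatibility with pipelines that apply the looser
disjunctive reading. Exclusions are labelled with the first failing
criterion in the order call rate, LRR SD, GCWF, CNV count.

**GCWF.** The GC wave factor quantifies slow intensity waviness that tracks
local GC content. The package computes it as the slope of window-median
LRR regressed on window GC fraction (1 Mb windows, autosomes), multiplied
by the SD of window GC — i.e. the LRR shift associated with a one-SD change
in local GC. A perfectly flat sample gives exactly 0, and typical wavy
samples land on the 0.01–0.05 scale of the 0.02 threshold. This captures
the waviness intent with a transparent statistic rather than a fitted
genomic-wave model; a precomputed per-sample value can be supplied instead.

**Relatedness.** `estimate_ibd()` is the classic allele-frequency-based
method-of-moments estimator: observed identity-by-state 0/1/2 counts are
equated to their expectations under IBD 0/1/2 given per-probe allele
frequencies, solved for Z0/Z1/Z2, clipped to [0, 1], renormalized, and
summarized as PI_HAT = Z2 + Z1/2. No small-sample bias correction is
applied — the estimator is used only against the 0.30 cutoff, far from the
regime where the correction matters. Pairs above the cutoff are resolved by
`flag_related()`: iteratively drop the sample in the most flagged pairs
(so a duplicate hub, e.g. B in an A–B, B–C chain, is removed alone),
preferring the lower call rate, then the lexicographically later id. Which
member of a pair the original pipelines dropped is generally undocumented;
this rule is a deterministic choice, not a reconstruction.

**Population structure.** PCA uses the genotype-PCA convention: per-probe
standardization by mean and `sqrt(p(1-p))`, then SVD; monomorphic probes
are dropped, missing genotypes mean-imputed. LD pruning (`ld_prune()`,
window 50 probes, step 5, r² ≤ 0.2 — common practice, configurable) runs
first. Component signs are arbitrary; only separations are meaningful.

## The CNV caller

`viterbi_call()` is a deliberately simplified stand-in for trained
SNP-array callers, faithful in kind: five copy-number states (0–4, no
copy-neutral-LOH state), Gaussian LRR emissions with means
(−3.5, −0.66, 0, 0.40, 0.68), BAF emissions as a genotype-band mixture —
band positions k/cn for k = 0..cn, binomial weights in the probe's
population B-allele frequency, band SD 0.03, a 1% uniform outlier
component, and pure uniform for copy number 0 (no genotype signal) — and
distance-dependent transitions whose off-diagonal mass is scaled by
`1 − exp(−gap/d0)`, d0 = 100 kb, so state changes get cheaper across large
probe gaps. The LRR state SDs default to (1.0, 0.25, 0.18, 0.20, 0.22):
wide for homozygous deletions, where the signal is noise-dominated,
narrowest for diploid. Runs of non-diploid Viterbi states at least
`min_probes = 3` long become calls spanning first to last probe; X/Y are
excluded by default to avoid ploidy handling. The decoder is exact —
tested against exhaustive path enumeration on small instances — and calls
within a sample never overlap, since they are runs of one state path.
Numerical equivalence with any specific trained caller is a non-goal; the
role of this module is to make the simulator-to-association path a real
end-to-end pipeline.

## The synthetic-cohort generator

`cohort_spec()` defaults describe the cohort the pipeline targets: 63
cases, 145 controls; background CNVs per subject Poisson with means 75.2
(cases) and 64.1 (controls); background lengths log-normal with median
50 kb and σ_log = 1; 27% of background events deletions (~1:2.7
deletion:duplication, the reported per-subject burden ratio); a probe grid
of 2 chromosomes × 25 Mb at 4 kb spacing (12,500 probes — Omni-Express-like
density on a desk-scale genome that runs the full pipeline in seconds).
Causal regions are spiked per group either at Bernoulli carrier
frequencies or with exact forced counts. Realism knobs default to mild
imperfection: boundary jitter SD of 1 probe, 1% false-positive and 5%
false-negative causal-call rates. Every draw comes from a named substream
of the mandatory master seed, so outputs are byte-reproducible and stages
can be regenerated independently.

What the generator does *not* emulate: linkage disequilibrium between
probes, chip-specific probe coordinates or real gene content (annotation
fixtures are hand-written intervals), batch structure, and — critically —
genome scale. Compressing a genome's CNV burden onto 50 Mb inflates
per-locus carrier frequency roughly 60-fold relative to a real 3 Gb
genome. Tests passing on these cohorts therefore demonstrate the
correctness of the machinery (carrier logic, exact tests, collapsing,
thresholding, caller recovery), not calibration on real chip data.

**The deterministic spike-in reproduction.** The package's reference
end-to-end check constructs a cohort with exactly 8/63 case and 1/145
control carriers of one deletion region, clean calls (no jitter, no call
noise, no background), and verifies that the scan flags exactly that
region with p = 0.000347 below the derived threshold. Background is
omitted deliberately: with forced counts and clean calls the outcome is
fully determined, so the check is exact for every seed, whereas Poisson
background would make "exactly one flagged region" a stochastic event.

**Null calibration cohorts.** The family-wise false-flag check runs the
scan on 200 seeded cohorts with *equal* background rates in both groups
and no causal regions, asking how often any region beats the derived
threshold. These cohorts use 4 chromosomes × 25 Mb at 12 background CNVs
per subject — chosen to reproduce the sparsity regime of a real scan
(roughly 0.1–1% of probes passing the ≥3-case prefilter, and region
counts of the order of tens, comparable to the 89 tests of a genome-wide
analysis) rather than the burden-profile regime of the default fixture.
The measured rate is ~0.05, within the ≤ 0.10 bound.

## Known limitations

* **Min-p regions with case-conditioned prefiltering are not exactly
  Bonferroni-calibrated.** The region p is a minimum over member probes,
  and the ≥3-case prefilter selects case-enriched tables before counting
  tests. At realistic CNV sparsity member probes of a region share their
  carrier set, the minimum is close to every member, and the procedure is
  near-calibrated (the measured null family-wise rate above). But when
  per-locus carrier frequency is high — dense CNV data, or a small
  simulated genome carrying a full genome's burden — regions aggregate
  many distinct carrier sets, the minimum is taken over effectively many
  tests, and the procedure becomes anti-conservative. Interpret scans of
  dense data accordingly.
* **Burden comparisons** (`cohort_profile()`) use a Welch t-test on
  per-subject counts (pooled available via `var_equal = TRUE`): group
  sizes differ, so equal variances are not assumed. Count data are not
  Gaussian; at these group sizes the t-test on counts is the field's
  convention and adequate.
* **Annotation** reports the cytoband of the region *start*; regions
  crossing a band boundary keep the start band and are flagged
  `multi_band`. Gene lists are alphabetical, comma-joined on output.
* **Reported means vs recomputed means.** One decimal place is used for
  per-subject means in rendered tables. Note that a total-CNV mean printed
  as the sum of separately rounded deletion and duplication means can
  differ from the rounded quotient by one unit in the last place; the
  package always reports the quotient.
* The rawcnv confidence field is parsed and carried but never used by the
  statistics.

## Problem sizes used by the test suite

All suite fixtures are generated in code at run time. The heavier checks
use: 12,500-probe default cohorts for end-to-end scans; 2,000-probe
chromosomes × 100 seeded replicates for HMM recovery (≥90% reciprocal
overlap of a 20-probe deletion, ≥95% of replicates); 8,000–10,000 probes
for IBD recovery (duplicate ≥ 0.95, parent-offspring within [0.4, 0.6],
unrelated < 0.1, |mean bias| < 0.02); 25,000-probe genomes × 200 seeded
cohorts for the null family-wise rate; and exhaustive 5⁷-path enumeration
for Viterbi optimality. These sizes are the package's choice of
desk-scale problems on which every property is decidable in seconds to a
couple of minutes.
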