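---
title: "Screening trio genomes for uniparental disomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening trio genomes for uniparental disomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(updscreen)
```

## The problem

Uniparental disomy (UPD) is the inheritance of both homologs of a chromosome
(or of a chromosomal segment) from a single parent, usually through meiotic
nondisjunction. Isodisomy (UPiD) — two copies of one parental homolog —
renders the affected chromosome homozygous and can unmask recessive variants
carried heterozygously by one parent, which makes it directly relevant to
rare-disease diagnostics. Heterodisomy (UPhD) — both homologs of one parent —
preserves heterozygosity and is mainly of interest for imprinted regions.

Given jointly genotyped whole-genome data for a mother–father–proband trio,
UPD leaves a characteristic fingerprint at *informative* sites, positions
where the parents are homozygous for different alleles (AA × BB). Under
biparental inheritance the child must be AB there. Under UPD of either kind
the child's genotype is instead identical to the disomic parent's, a
Mendelian error. `updscreen` turns this fingerprint into per-chromosome
calls, segmental candidate regions, and cohort-level reports.

## The screen

Sites are restricted to common biallelic SNVs: population minor allele
frequency ≥ 0.4 (`filter_config()$maf_min`), which maximizes the density of
informative configurations — at allele frequency 0.5 about one site in eight
is informative. Individual genotype calls need depth in 15–100 reads and
genotype quality ≥ 15; a failing call is set missing for that sample only,
so a site with a filtered parent genotype still contributes to metrics that
do not require that parent. These defaults are exposed in
`filter_config()`.

Two metrics are computed per chromosome (`chromosome_stats()`):

* **AB percentage** (`pct_ab`): of informative sites with a non-missing
  proband genotype, the percentage where the proband is heterozygous.
  The complementary percentages `pct_match_mother` / `pct_match_father`
  count identity with each parent; the larger of the two is the
  **uniparental skew**. The three quantities partition the informative
  sites, so `pct_ab + pct_match_mother + pct_match_father = 100`.
* **Heterozygosity** (`pct_het`): heterozygous proband calls as a percentage
  of all non-missing proband calls on the chromosome.

`classify_chromosome()` applies the decision rule: skew > 90 % with
heterozygosity < 10 % is isodisomy; skew > 90 % with heterozygosity > 30 %
is heterodisomy. All comparisons are strict: a value exactly
at a threshold never triggers the call.
A skewed chromosome with heterozygosity between 10 % and 30 % is reported
`ambiguous_skewed` rather than forced into either class — the rule defines
only the two extremes, and an intermediate value on real data would warrant
manual review (mosaicism, segmental mixtures and quality artefacts can all
produce it). Parent of origin is the argmax of the two match percentages
(`disomy_direction()`); an exact tie is `undetermined`, never an arbitrary
parent — with skew above 90 % a tie cannot occur.

Two advisory guards surround the rule. Chromosomes with fewer than
`min_nonmissing = 1000` usable proband genotypes or fewer than
`min_informative = 100` informative sites are `insufficient_data`: with 100
informative sites the binomial standard error of a percentage is at most
5 points, still comfortably away from the 90/10/30 thresholds, while a
higher floor would start discarding chromosomes on the sparse panels this
package is routinely run on (a 2,000-site panel yields roughly 150–250
informative sites per chromosome after filters, fewer under consanguinity).
Unskewed chromosomes with heterozygosity above `het_excess_min = 60 %` get a
`het_excess_flag` — well above the ~50 % ceiling expected at MAF ≥ 0.4 under
Hardy–Weinberg, this is the trisomy signature (a trisomic chromosome is
called heterozygous wherever the three alleles are not identical), and it is
advisory only: excess heterozygosity is not UPD.

The X chromosome is screened only in female probands; a male proband carries
a single maternal X, so the trio logic does not apply there.

## Segmental events and deletions

Partial UPD affects an interval rather than the whole chromosome.
`scan_partial()` anchors a window of `window_size = 5` Mb at every
Mendelian-error genotype and retains windows with at least `min_errors`
Mendelian errors whose informative-site heterozygosity is ≤ 10 %. Windows
extend forward from the anchor only; since every error inside a true event
anchors its own window and overlapping retained windows are merged
(`merge_windows()`, half-open intervals: abutting windows merge, a gap of
one base does not), leftward extent is recovered by the merge. Windows with
no informative site are not retained — low heterozygosity cannot be
confirmed there.

A hemizygous deletion mimics isodisomy in genotypes: callers report the
remaining allele as a homozygous diploid call, producing the same
Mendelian-error runs. It does not mimic isodisomy in read depth.
`resolve_region()` therefore compares mean proband depth across the region
with the genome-wide mean (`genome_mean_coverage()`, computed from
pre-filter depths so the depth filter cannot bias the baseline): only
regions strictly above 90 % of genome-wide coverage remain candidate partial
UPD; the rest are deletions.

The `min_errors = 50` default is calibrated to WGS common-SNV density, where
a 5 Mb window holds thousands of panel sites. On the deliberately sparse
synthetic panels used throughout this package's tests (2,000 sites per
chromosome, ~10–50 sites per Mb), a 5 Mb window holds only ~50–200 sites, of
which a deletion makes roughly a quarter Mendelian-inconsistent. The
study-scale tests and the acceptance script therefore run the scan with
`min_errors = 10`: far above the genotype-error background (expected < 1
Mendelian error per chromosome at error rate 3 × 10⁻⁴, so a 10-error window
cannot arise by noise) and below the ~13+ expected inside a deletion at that
density. The same proportional reasoning applies when running the screen on
any panel much sparser than WGS.

When a chromosome already carries a whole-chromosome call, the window scan
on it is suppressed (an isodisomic chromosome is one giant error region);
the suppression is recorded on the `upd_screen` object. Ordering the two
screens this way keeps segmental output free of redundant whole-chromosome
echoes.

## The synthetic generator

Patient-level trio genomes of the kind this screen targets cannot be
redistributed, so the package ships a first-class simulator used by every end-to-end test.
`simulate_site_panel()` draws positions uniformly without replacement and
allele frequencies uniformly in [0.4, 0.6]; `simulate_trio()` draws two
explicit parental haplotypes per site from Hardy–Weinberg proportions and
then applies one inheritance event per chromosome:

* `upid_*` duplicates one (per-site randomly chosen) homolog of the parent;
* `uphd_*` transmits the parent's genotype wholesale;
* `partial_upid` applies the isodisomy rule inside a half-open interval;
* `deletion` transmits a single allele inside the interval, reported as a
  homozygous diploid call with expected depth halved — exactly the behaviour
  that makes the coverage check necessary;
* `trisomy_like` forces heterozygous calls at rate 0.75, the probability
  that a trisomic site carries both alleles at allele frequency 0.5;
* `autozygous(f)` makes both parents share one transmitted haplotype at a
  fraction *f* of sites: heterozygosity drops by the factor (1 − *f*)
  without any uniparental skew, because a shared-haplotype site can never be
  informative. This emulates consanguinity, the main benign mimic of low
  heterozygosity.

Genotype errors replace a call with one of the two other diploid genotypes,
uniformly — the simplest model producing both false heterozygotes and false
homozygotes. The default rate 3 × 10⁻⁴ is calibrated so that isodisomic
chromosomes show parent matching near 99.97 %, as observed on isodisomic
chromosomes in clinical WGS trios, where the residual deviation from 100 %
reflects sequencing and genotype-calling error; it is a package
calibration, not a measured quantity. Depths are negative binomial (`mean_depth = 30`,
`size = 20`); a configurable 1 % of genotype-quality values fall below the
GQ filter. Sites are independent — no linkage, no recombination, no SNP
density heterogeneity — which is acceptable because the screen uses no
linkage information, but it means the simulator says nothing about methods
that do (e.g. haplotype-based IBD detection). Male probands get no X
records; the father's X is emulated as a hemizygous-as-homozygous call at
full depth (X-specific coverage is not modelled). Real joint-genotyped VCFs
additionally contain multi-allelic records, indels and depth waves that the
generator omits; passing tests therefore demonstrate the screen's logic, not
robustness to every artefact of a production pipeline.

## Cohort reporting

`upd_cohort()` aggregates screens, computes per-chromosome five-number
summaries of both metrics, and flags outliers with a Tukey rule hardened for
near-degenerate distributions: a proband is flagged when its `pct_ab` falls
below `Q1 − max(1.5 · IQR, 5)` percentage points (both tails for
`pct_het`). On sparse panels most probands sit at exactly 100 % AB, the IQR
collapses to zero, and the bare Tukey fence would flag every
single-genotype-error wobble; the 5-point floor separates that wobble
(≪ 1 point at error rate 3 × 10⁻⁴) from real events (whole-chromosome UPD
drives `pct_ab` to ~0; a 30–40 Mb deletion drops it by 10–20 points). The
flags are discovery aids — the authoritative calls come from the thresholds.
`prevalence()` renders event counts as the conventional "1 in N" string with
N rounded to the nearest integer: 3 isodisomies among 164 trios is
"1 in 55".

## Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` validate planted-event recovery
on a cohort of 164 trios at 2,000 sites per chromosome (46,000 sites per
trio), with one maternal chromosome-1 UPiD, two paternal chromosome-2 UPiD,
one maternal chromosome-15 UPhD, 40 Mb and 30 Mb deletions on chromosomes 4
and 14, one trisomy-like chromosome 21, and three consanguineous probands
(autozygous fraction 0.25). All planted events are recovered with correct
type and parent, deletions resolve as deletions, and the `pct_ab` outlier
list contains exactly the AB-suppressing planted events. Unit tests check
the site classifier against a brute-force transmission oracle on all 64
genotype patterns and the window scan against exhaustive evaluation on
random instances.

## Known limitations

* Mosaic UPD is out of scope: the metrics assume a single clonal genotype
  per site, and intermediate skew from mosaicism will at best surface as
  `ambiguous_skewed`.
* Segmental resolution is bounded by the window size (5 Mb by default) and
  by panel density; breakpoints are not refined below window resolution.
* The coverage baseline is the mean per-site depth at panel sites, a proxy
  that tracks, but is not identical to, pipeline-computed genome-wide
  coverage metrics.
* Direction percentages count genotype identity at informative sites only;
  proband-missing informative sites are excluded from the denominator.
* The prevalence strings describe the screened cohort; they are not
  population estimates.
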