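# updscreen

Uniparental disomy (UPD) screening of whole-genome sequenced
mother–father–proband trios, for rare-disease genomics: isodisomy renders a
whole chromosome homozygous and can unmask recessive variants carried by one
parent, so flagging it focuses variant analysis and changes genetic
counselling (recurrence risk is negligible, unlike biallelic inheritance).

## The method

At *informative* sites — parents homozygous for different alleles
(AA × BB) — a biparentally inheriting child must be AB. For each chromosome,
over common biallelic SNVs (population MAF ≥ 0.4; genotype depth 15–100,
GQ ≥ 15), the screen computes:

* `pct_ab` — % of informative sites where the proband is AB, and its
  complements `pct_match_mother` / `pct_match_father` (genotype identity
  with each parent); `skew = max(pct_match_mother, pct_match_father)`;
* `pct_het` — % heterozygous calls among all non-missing proband calls.

Decision rule per chromosome:

| skew      | pct_het    | call                      |
|-----------|------------|---------------------------|
| > 90 %    | < 10 %     | `upid` (isodisomy)        |
| > 90 %    | > 30 %     | `uphd` (heterodisomy)     |
| > 90 %    | 10–30 %    | `ambiguous_skewed`        |
| ≤ 90 %    | > 60 %     | `het_excess_flag` (advisory; trisomy signature) |

Parent of origin is the argmax match percentage. Segmental events are found
by 5 Mb windows anchored at Mendelian-error genotypes (retained when the
window holds enough errors and ≤ 10 % heterozygosity at its informative
sites); merged candidate regions are resolved as **partial UPD** only when
mean proband depth exceeds 90 % of the genome-wide mean — below that they
are hemizygous deletions, which mimic isodisomy in genotypes but not in
coverage. Autosomes are screened for all probands; the X only for females.

Because patient-level trio genomes cannot be redistributed, the package
includes a first-class synthetic trio generator (Hardy–Weinberg parental
haplotypes; per-chromosome isodisomy, heterodisomy, segmental events,
deletions, trisomy-like excess heterozygosity, consanguinity; genotype-error
and depth/GQ noise) used by all end-to-end tests.

## Worked example

Simulate a trio with maternal isodisomy of chromosome 1 and screen it:

```r
library(updscreen)

panel <- simulate_site_panel(2000, seed = 7)          # 23 chromosomes
sim <- simulate_trio(panel,
                     sim_scenario(list(`1` = "upid_maternal"), seed = 8),
                     proband_sex = "female", proband_id = "P1")
scr <- upd_screen(sim$trio)
scr
#> UPD screen of proband P1 (female): 23 chromosome(s) screened
#>   chr1   upid             parent=mother    skew=100.00% het=0.00%
#>   no candidate regions

scr$calls[scr$calls$chrom %in% c("1", "2"),
          c("chrom", "n_informative", "pct_ab", "pct_match_mother",
            "pct_het", "call", "parent")]
#>  chrom n_informative pct_ab pct_match_mother pct_het call         parent
#>      1           223   0.00         100.0000    0.00 upid         mother
#>      2           228  99.56           0.4386   51.14 none not_applicable
```

Chromosome 1 shows the isodisomy fingerprint: every informative-site
genotype identical to the mother's (`skew` 100 %) with heterozygosity
collapsed to 0 %, while a biparental chromosome sits near 100 % AB and ~50 %
heterozygosity. `upd_cohort(list_of_screens)` aggregates trios into
per-chromosome boxplot summaries, outlier flags and `"1 in N"` prevalence
strings; `export_trio()` / `export_cohort()` write TSV/JSON/BED reports.

Real data enters through `load_trio("trio.vcf", "trio.ped")` (VCF v4.2 with
GT/DP/GQ and an allele-frequency INFO field or external site list, plus a
6-column PED naming the trio).

A command-line interface wraps the same functions:

```sh
exec/updscreen simulate --scenario scenario.yaml --seed 42 --out-prefix sim/trio
exec/updscreen run --vcf sim/trio.vcf --ped sim/trio.ped --out-dir report
exec/updscreen cohort --manifest trios.tsv --out-dir cohort_report
```

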