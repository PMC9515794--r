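Package: updscreen
Title: Uniparental Disomy Screening of Whole-Genome Sequenced Trios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects whole-chromosome and segmental uniparental disomy (UPD)
    from jointly genotyped mother-father-proband trios. Restricts to common
    biallelic SNVs, applies per-genotype depth and quality filters, computes
    per-chromosome AB-genotype percentages at informative (AA x BB) sites and
    chromosome-level heterozygosity, classifies isodisomy and heterodisomy
    with parent of origin, scans Mendelian-error-anchored 5 Mb windows for
    segmental events, and separates hemizygous deletions from partial UPD by
    read-depth ratio. Includes a synthetic trio generator with per-chromosome
    inheritance scenarios (isodisomy, heterodisomy, segmental events,
    deletions, trisomy-like excess heterozygosity, parental consanguinity)
    for end-to-end validation, cohort-level summaries with outlier flagging,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
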