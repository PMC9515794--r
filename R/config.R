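#' Site and genotype filter configuration
#'
#' Defaults are the screen's standard settings: common biallelic SNVs
#' (population minor allele frequency >= 0.4), per-genotype depth within
#' 15..100 reads and genotype quality >= 15. A genotype call failing the
#' depth/GQ filters is set missing for that sample only; a site failing the
#' MAF or SNV filters is removed entirely.
#'
#' @param maf_min Minimum population minor allele frequency, in `[0, 0.5]`.
#' @param depth_min,depth_max Per-genotype read-depth bounds (inclusive).
#' @param gq_min Minimum genotype quality.
#' @param snv_only Keep only biallelic single-nucleotide variants.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.4, depth_min = 15, depth_max = 100,
                          gq_min = 15, snv_only = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, depth_min <= depth_max,
            depth_min >= 0, gq_min >= 0, is.logical(snv_only))
  structure(list(maf_min = maf_min, depth_min = depth_min,
                 depth_max = depth_max, gq_min = gq_min,
                 snv_only = isTRUE(snv_only)),
            class = "filter_config")
}

#' Whole-chromosome classification thresholds
#'
#' A chromosome is called isodisomic (UPiD) when uniparental skew exceeds
#' `skew_min` percent and heterozygosity is below `upid_het_max` percent;
#' heterodisomic (UPhD) when skew exceeds `skew_min` with heterozygosity above
#' `uphd_het_min`. Skewed chromosomes whose heterozygosity falls between the
#' two bounds are reported `ambiguous_skewed`. Chromosomes with too few usable
#' sites are `insufficient_data`; unskewed chromosomes with heterozygosity
#' above `het_excess_min` get an advisory `het_excess_flag` (the trisomy
#' signature).
#'
#' @param skew_min Minimum uniparental skew, percent (strict `>`).
#' @param upid_het_max Maximum heterozygosity for UPiD, percent (strict `<`).
#' @param uphd_het_min Minimum heterozygosity for UPhD, percent (strict `>`).
#' @param min_informative Minimum informative sites with a non-missing proband
#'   genotype for a chromosome to be classifiable.
#' @param min_nonmissing Minimum non-missing proband genotypes per chromosome.
#' @param het_excess_min Advisory heterozygosity-excess bound, percent.
#' @return A list of class `classify_thresholds`.
#' @export
classify_thresholds <- function(skew_min = 90, upid_het_max = 10,
                                uphd_het_min = 30, min_informative = 100,
                                min_nonmissing = 1000, het_excess_min = 60) {
  stopifnot(upid_het_max < uphd_het_min, skew_min > 50, skew_min <= 100,
            min_informative >= 1, min_nonmissing >= 1)
  structure(list(skew_min = skew_min, upid_het_max = upid_het_max,
                 uphd_het_min = uphd_het_min,
                 min_informative = min_informative,
                 min_nonmissing = min_nonmissing,
                 het_excess_min = het_excess_min),
            class = "classify_thresholds")
}

#' Segmental (partial) UPD window-scan parameters
#'
#' Each chromosome is scanned with windows of `window_size` bp anchored at
#' Mendelian-error genotypes. A window is retained when it contains at least
#' `min_errors` Mendelian errors and proband heterozygosity at its informative
#' sites is at most `het_max_pct` percent. Merged candidate regions are
#' resolved as partial UPD only when mean proband depth exceeds `ratio_min`
#' of the genome-wide mean (strict `>`); otherwise they are deletions.
#'
#' @param window_size Window length in bp.
#' @param min_errors Minimum Mendelian-error count per retained window.
#' @param het_max_pct Maximum proband heterozygosity at informative sites in a
#'   retained window, percent.
#' @param ratio_min Coverage-ratio threshold separating deletions from
#'   partial UPD.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(window_size = 5e6, min_errors = 50,
                        het_max_pct = 10, ratio_min = 0.9) {
  stopifnot(window_size >= 1, min_errors >= 1, het_max_pct >= 0,
            het_max_pct <= 100, ratio_min > 0)
  structure(list(window_size = window_size, min_errors = min_errors,
                 het_max_pct = het_max_pct, ratio_min = ratio_min),
            class = "scan_params")
}

#' Full screen configuration
#'
#' Bundles the filter settings, whole-chromosome thresholds and window-scan
#' parameters, plus the name of the allele-frequency source.
#'
#' @param filter A [filter_config()].
#' @param thresholds A [classify_thresholds()].
#' @param scan A [scan_params()].
#' @param af_source INFO-field name carrying the population alternate-allele
#'   frequency (default `"AF"`), or a path to a TSV site list
#'   (chrom, pos, ref, alt, af).
#' @param seed Optional integer seed echoed into outputs.
#' @return A list of class `upd_config`.
#' @export
upd_config <- function(filter = filter_config(),
                       thresholds = classify_thresholds(),
                       scan = scan_params(),
                       af_source = "AF", seed = NULL) {
  stopifnot(inherits(filter, "filter_config"),
            inherits(thresholds, "classify_thresholds"),
            inherits(scan, "scan_params"))
  structure(list(filter = filter, thresholds = thresholds, scan = scan,
                 af_source = af_source, seed = seed),
            class = "upd_config")
}

#' Read a screen configuration from YAML
#'
#' Any block or field absent from the file keeps its default; unknown fields
#' are an error so typos do not silently fall back to defaults.
#'
#' @param path YAML file with optional blocks `filter`, `thresholds`, `scan`
#'   and scalars `af_source`, `seed`.
#' @return A [upd_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("filter", "thresholds", "scan", "af_source", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  fill <- function(ctor, given) {
    if (is.null(given)) return(ctor())
    ok <- names(formals(ctor))
    bad <- setdiff(names(given), ok)
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    do.call(ctor, given)
  }
  upd_config(filter = fill(filter_config, y$filter),
             thresholds = fill(classify_thresholds, y$thresholds),
             scan = fill(scan_params, y$scan),
             af_source = if (is.null(y$af_source)) "AF" else y$af_source,
             seed = y$seed)
}

#' Write a screen configuration as YAML
#'
#' The written file round-trips through [read_config()].
#'
#' @param config A [upd_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "upd_config"))
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

config_as_list <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

#' @export
print.upd_config <- function(x, ...) {
  cat(yaml::as.yaml(config_as_list(x)))
  invisible(x)
}
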