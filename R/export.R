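.region_bed_lines <- function(regions, proband = NULL) {
  if (!nrow(regions)) return(character())
  name <- paste0(regions$resolution, ":", regions$parent)
  if (!is.null(regions$proband)) name <- paste0(regions$proband, ":", name)
  paste(paste0("chr", regions$chrom),
        sprintf("%.0f", regions$start - 1), sprintf("%.0f", regions$end - 1),
        name, regions$n_mendelian_errors, sep = "\t")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a per-trio screen report
#'
#' Writes a per-chromosome TSV (proband, chrom, n_informative, pct_ab,
#' pct_match_mother, pct_match_father, pct_het, call, parent), a full JSON
#' report (calls, regions, genome depth, suppressed chromosomes and the
#' resolved configuration), and a BED of candidate regions (0-based
#' half-open, name `resolution:parent`, score = Mendelian-error count).
#'
#' @param screen An [upd_screen()] object.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_trio <- function(screen, out_dir) {
  stopifnot(inherits(screen, "upd_screen"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(out_dir, screen$proband)

  tsv <- paste0(stem, ".chromosomes.tsv")
  cols <- c("chrom", "n_nonmissing", "n_informative", "pct_ab",
            "pct_match_mother", "pct_match_father", "pct_het", "call",
            "parent")
  .write_tsv(cbind(proband = screen$proband, screen$calls[, cols]), tsv)

  js <- paste0(stem, ".report.json")
  jsonlite::write_json(
    list(proband = screen$proband, sex = screen$sex,
         genome_depth = as.list(screen$genome_depth),
         calls = screen$calls, regions = screen$regions,
         suppressed_scan = screen$suppressed_scan,
         accounting = screen$accounting,
         config = config_as_list(screen$config)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  bed <- paste0(stem, ".regions.bed")
  writeLines(.region_bed_lines(screen$regions), bed)

  invisible(c(chromosomes = tsv, report = js, regions = bed))
}

#' Export a cohort report
#'
#' Writes the cohort per-chromosome table (`cohort.chromosomes.tsv`, one row
#' per proband x screened chromosome), plot data sufficient to redraw the
#' per-chromosome AB%/heterozygosity boxplots (`cohort.boxplot_data.tsv`),
#' the JSON summary (five-number summaries, outliers, tallies, prevalence),
#' and a BED of all candidate regions.
#'
#' @param cohort An [upd_cohort()] object.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "upd_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tsv <- file.path(out_dir, "cohort.chromosomes.tsv")
  cols <- c("proband", "chrom", "n_nonmissing", "n_informative", "pct_ab",
            "pct_match_mother", "pct_match_father", "pct_het", "call",
            "parent")
  .write_tsv(cohort$table[, cols], tsv)

  box <- file.path(out_dir, "cohort.boxplot_data.tsv")
  .write_tsv(cohort$table[, c("proband", "chrom", "pct_ab", "pct_het")], box)

  js <- file.path(out_dir, "cohort.summary.json")
  jsonlite::write_json(
    list(n_trios = cohort$n_trios, n_upid = cohort$n_upid,
         n_uphd = cohort$n_uphd,
         prevalence_upid = cohort$prevalence_upid,
         prevalence_upd = cohort$prevalence_upd,
         summaries = cohort$summaries, outliers = cohort$outliers,
         tally = cohort$tally,
         outlier_rule = list(iqr_mult = cohort$iqr_mult,
                             min_fence = cohort$min_fence)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  bed <- file.path(out_dir, "cohort.regions.bed")
  writeLines(.region_bed_lines(cohort$regions), bed)

  invisible(c(chromosomes = tsv, boxplot_data = box, summary = js,
              regions = bed))
}
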