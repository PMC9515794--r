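#' Screen one trio for uniparental disomy
#'
#' Runs the full per-trio screen: applies the site/genotype filters (unless
#' the trio is already filtered), computes the chromosome metrics, classifies
#' every screened chromosome (autosomes, plus X for female probands), and on
#' chromosomes without a whole-chromosome UPD call runs the
#' Mendelian-error-anchored window scan, merges retained windows and resolves
#' each merged region as partial UPD or deletion by coverage ratio. The
#' window scan is suppressed on chromosomes already carrying a
#' whole-chromosome call; suppressed chromosomes are recorded.
#'
#' @param trio A `trio_genotypes` data frame from [load_trio()] or
#'   [simulate_trio()].
#' @param config A [upd_config()].
#' @return An object of class `upd_screen`: a list with `proband`, `sex`,
#'   `calls` (per-chromosome data frame joining [chromosome_stats()] and the
#'   call), `regions` (resolved [resolve_region()] rows), `suppressed_scan`
#'   (chromosomes where the scan was skipped), `genome_depth` (named mean
#'   depth per trio member), `accounting`, and the `config` used.
#' @seealso [upd_cohort()] to aggregate screens, [export_trio()] to write
#'   reports.
#' @export
#' @examples
#' panel <- simulate_site_panel(300, grch38_lengths(c("21", "22")), seed = 1)
#' sim <- simulate_trio(panel, sim_scenario(list(`21` = "upid_maternal"),
#'                                          seed = 1))
#' scr <- upd_screen(sim$trio,
#'                   upd_config(thresholds = classify_thresholds(
#'                     min_informative = 10, min_nonmissing = 50)))
#' scr$calls[scr$calls$call != "none", c("chrom", "call", "parent")]
upd_screen <- function(trio, config = upd_config()) {
  stopifnot(inherits(trio, "trio_genotypes"), inherits(config, "upd_config"))
  if (!isTRUE(attr(trio, "filtered")))
    trio <- apply_filters(trio, config$filter)

  sex <- attr(trio, "proband_sex")
  chroms <- screened_chromosomes(sex)
  gdepth <- vapply(c("mother", "father", "proband"), function(r)
    tryCatch(genome_mean_coverage(trio, r), error = function(e) NA_real_),
    numeric(1))

  stats <- do.call(rbind, lapply(chroms, chromosome_stats, trio = trio))
  calls <- do.call(rbind, lapply(seq_len(nrow(stats)), function(i)
    classify_chromosome(stats[i, ], config$thresholds, sex)))
  calls <- cbind(calls, stats[, setdiff(names(stats), "chrom"),
                              drop = FALSE])
  rownames(calls) <- NULL

  whole <- calls$call %in% c("upid", "uphd", "ambiguous_skewed")
  suppressed <- character()
  regions <- list()
  sp <- config$scan
  for (i in seq_len(nrow(calls))) {
    ch <- calls$chrom[i]
    w <- scan_partial(trio, ch, window_size = sp$window_size,
                      min_errors = sp$min_errors,
                      het_max_pct = sp$het_max_pct)
    if (!nrow(w)) next
    if (whole[i]) {
      suppressed <- c(suppressed, ch)
      next
    }
    merged <- merge_windows(w)
    for (j in seq_len(nrow(merged))) {
      regions[[length(regions) + 1L]] <- resolve_region(
        merged[j, ], trio, genome_mean_depth = gdepth[["proband"]],
        ratio_min = sp$ratio_min)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions)
             else data.frame(chrom = character(), start = numeric(),
                             end = numeric(), n_mendelian_errors = integer(),
                             n_informative = integer(), pct_het = numeric(),
                             mean_depth = numeric(),
                             coverage_ratio = numeric(),
                             resolution = character(), parent = character(),
                             stringsAsFactors = FALSE)
  rownames(regions) <- NULL

  structure(list(proband = attr(trio, "proband_id"), sex = sex,
                 calls = calls, regions = regions,
                 suppressed_scan = suppressed,
                 genome_depth = gdepth,
                 accounting = attr(trio, "accounting"),
                 config = config),
            class = "upd_screen")
}

#' @export
print.upd_screen <- function(x, ...) {
  cat(sprintf("UPD screen of proband %s (%s): %d chromosome(s) screened\n",
              x$proband, x$sex, nrow(x$calls)))
  hits <- x$calls[!x$calls$call %in% c("none", "insufficient_data"), ,
                  drop = FALSE]
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits)))
      cat(sprintf("  chr%-3s %-16s parent=%-9s skew=%.2f%% het=%.2f%%\n",
                  hits$chrom[i], hits$call[i], hits$parent[i],
                  hits$skew[i], hits$pct_het[i]))
  } else cat("  no whole-chromosome findings\n")
  if (nrow(x$regions)) {
    for (i in seq_len(nrow(x$regions)))
      cat(sprintf(
        "  region chr%s:%.0f-%.0f %s (parent=%s, coverage ratio %.2f, %d Mendelian errors)\n",
        x$regions$chrom[i], x$regions$start[i], x$regions$end[i],
        x$regions$resolution[i], x$regions$parent[i],
        x$regions$coverage_ratio[i], x$regions$n_mendelian_errors[i]))
  } else cat("  no candidate regions\n")
  if (length(x$suppressed_scan))
    cat("  window scan suppressed on chr",
        paste(x$suppressed_scan, collapse = ", "),
        " (whole-chromosome call present)\n", sep = "")
  invisible(x)
}

#' @export
summary.upd_screen <- function(object, ...) {
  tab <- table(factor(object$calls$call,
                      levels = c("none", "upid", "uphd", "ambiguous_skewed",
                                 "het_excess_flag", "insufficient_data")))
  out <- list(proband = object$proband, sex = object$sex,
              call_counts = tab,
              n_regions = nrow(object$regions),
              genome_depth = object$genome_depth,
              median_pct_het = stats::median(object$calls$pct_het,
                                             na.rm = TRUE),
              median_pct_ab = stats::median(object$calls$pct_ab,
                                            na.rm = TRUE))
  class(out) <- "summary.upd_screen"
  out
}

#' @export
print.summary.upd_screen <- function(x, ...) {
  cat(sprintf("UPD screen summary - proband %s (%s)\n", x$proband, x$sex))
  cat(sprintf("  median heterozygosity %.2f%%, median AB%% %.2f%%\n",
              x$median_pct_het, x$median_pct_ab))
  cat(sprintf("  proband genome mean depth %.2fx\n",
              x$genome_depth[["proband"]]))
  cat("  calls:", paste(sprintf("%s=%d", names(x$call_counts),
                                as.integer(x$call_counts)),
                        collapse = " "), "\n")
  cat(sprintf("  candidate regions: %d\n", x$n_regions))
  invisible(x)
}

#' @export
as.data.frame.upd_screen <- function(x, ...) {
  cbind(proband = x$proband, sex = x$sex, x$calls,
        stringsAsFactors = FALSE)
}

#' Plot the per-chromosome screen metrics of one trio
#'
#' Two base-graphics panels: AB-genotype percentage at informative sites and
#' proband heterozygosity, by chromosome. Isodisomy drives both towards zero;
#' heterodisomy only the AB percentage; trisomy raises heterozygosity.
#'
#' @param x An `upd_screen` object.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.upd_screen <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- ifelse(x$calls$call %in% c("upid", "uphd", "ambiguous_skewed"),
                 "firebrick",
                 ifelse(x$calls$call == "het_excess_flag", "orange", "grey70"))
  graphics::barplot(x$calls$pct_ab, names.arg = x$calls$chrom, col = cols,
                    ylim = c(0, 100), ylab = "AB genotypes (%)",
                    main = paste("Proband", x$proband), las = 2, ...)
  graphics::barplot(x$calls$pct_het, names.arg = x$calls$chrom, col = cols,
                    ylim = c(0, 100), ylab = "heterozygosity (%)", las = 2,
                    ...)
  invisible(x)
}
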