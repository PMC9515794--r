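#' Aggregate trio screens into a cohort report
#'
#' Collects the per-chromosome metrics of every screened proband, computes
#' per-chromosome five-number summaries of the AB-genotype percentage and of
#' heterozygosity, flags distributional outliers, tallies calls by type and
#' parent, and derives cohort prevalence strings.
#'
#' Outlier rule: for `pct_ab`, a proband is flagged when its value falls below
#' `Q1 - max(1.5 * IQR, min_fence)` for that chromosome; for `pct_het`, when
#' it falls outside either fence. The `min_fence` floor (default 5 percentage
#' points) keeps the Tukey rule meaningful when a chromosome's distribution
#' is nearly degenerate (most probands at exactly 100% AB), where a bare
#' `1.5 * IQR` fence of width zero would flag single-genotype-error wobble.
#' Outlier flags are advisory discovery aids; the authoritative calls come
#' from [classify_chromosome()].
#'
#' @param screens List of [upd_screen()] objects (>= 1).
#' @param iqr_mult Tukey fence multiplier.
#' @param min_fence Minimum fence width, percentage points.
#' @return An object of class `upd_cohort`: `table` (per proband x chromosome
#'   metrics and calls), `summaries` (per chromosome x metric five-number
#'   summary), `outliers` (proband, chrom, metric, value), `tally`
#'   (call x parent counts), `regions` (all candidate regions with proband),
#'   `n_trios`, `n_upid`, `n_uphd`, and `prevalence` strings for UPiD and for
#'   all whole-chromosome UPD.
#' @export
upd_cohort <- function(screens, iqr_mult = 1.5, min_fence = 5) {
  stopifnot(length(screens) >= 1,
            all(vapply(screens, inherits, TRUE, "upd_screen")))
  tab <- do.call(rbind, lapply(screens, as.data.frame))
  rownames(tab) <- NULL

  metrics <- c("pct_ab", "pct_het")
  chroms <- unique(tab$chrom)
  summaries <- do.call(rbind, lapply(chroms, function(ch) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- tab[[m]][tab$chrom == ch]
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE,
                           names = FALSE)
      data.frame(chrom = ch, metric = m, n = sum(!is.na(v)),
                 min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summaries) <- NULL

  outliers <- list()
  for (ch in chroms) {
    rows <- tab$chrom == ch
    for (m in metrics) {
      v <- tab[[m]][rows]
      if (all(is.na(v))) next
      q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
      fence <- max(iqr_mult * (q[2] - q[1]), min_fence)
      low <- !is.na(v) & v < q[1] - fence
      flag <- if (m == "pct_ab") low
              else low | (!is.na(v) & v > q[2] + fence)
      if (any(flag))
        outliers[[length(outliers) + 1L]] <- data.frame(
          proband = tab$proband[rows][flag], chrom = ch, metric = m,
          value = v[flag], stringsAsFactors = FALSE)
    }
  }
  outliers <- if (length(outliers)) do.call(rbind, outliers)
              else data.frame(proband = character(), chrom = character(),
                              metric = character(), value = numeric(),
                              stringsAsFactors = FALSE)
  rownames(outliers) <- NULL

  tally <- as.data.frame(table(call = tab$call, parent = tab$parent),
                         stringsAsFactors = FALSE)
  tally <- tally[tally$Freq > 0, ]
  names(tally)[3] <- "n"
  rownames(tally) <- NULL

  regions <- do.call(rbind, lapply(screens, function(s) {
    if (!nrow(s$regions)) return(NULL)
    cbind(proband = s$proband, s$regions, stringsAsFactors = FALSE)
  }))
  if (is.null(regions))
    regions <- data.frame(proband = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_mendelian_errors = integer(),
                          n_informative = integer(), pct_het = numeric(),
                          mean_depth = numeric(), coverage_ratio = numeric(),
                          resolution = character(), parent = character(),
                          stringsAsFactors = FALSE)
  rownames(regions) <- NULL

  n_trios <- length(screens)
  n_upid <- sum(tab$call == "upid")
  n_uphd <- sum(tab$call == "uphd")
  structure(list(table = tab, summaries = summaries, outliers = outliers,
                 tally = tally, regions = regions,
                 n_trios = n_trios, n_upid = n_upid, n_uphd = n_uphd,
                 prevalence_upid = prevalence(n_trios, n_upid),
                 prevalence_upd = prevalence(n_trios, n_upid + n_uphd),
                 iqr_mult = iqr_mult, min_fence = min_fence),
            class = "upd_cohort")
}

#' Cohort prevalence as "1 in N"
#'
#' `N` is the cohort size divided by the event count, rounded to the nearest
#' integer (164 trios with 3 events gives "1 in 55").
#'
#' @param n_trios Number of trios screened (> 0).
#' @param n_events Number of events observed (>= 0).
#' @return Character string `"1 in N"`, or `"0 events in n_trios"` when no
#'   event was seen.
#' @export
#' @examples
#' prevalence(164, 3)
prevalence <- function(n_trios, n_events) {
  stopifnot(length(n_trios) == 1, length(n_events) == 1, n_events >= 0)
  if (n_trios <= 0) stop("n_trios must be positive")
  if (n_events == 0) return(sprintf("0 events in %d", n_trios))
  sprintf("1 in %d", round(n_trios / n_events))
}

#' @export
print.upd_cohort <- function(x, ...) {
  cat(sprintf("UPD cohort screen: %d trios, %d chromosome records\n",
              x$n_trios, nrow(x$table)))
  cat(sprintf("  whole-chromosome UPiD: %d (prevalence %s)\n",
              x$n_upid, x$prevalence_upid))
  cat(sprintf("  whole-chromosome UPhD: %d (all UPD: %s)\n",
              x$n_uphd, x$prevalence_upd))
  cat(sprintf("  candidate regions: %d (%d deletion, %d partial UPD)\n",
              nrow(x$regions), sum(x$regions$resolution == "deletion"),
              sum(x$regions$resolution == "partial_upd")))
  ab <- x$outliers[x$outliers$metric == "pct_ab", , drop = FALSE]
  cat(sprintf("  AB%% outliers: %d", nrow(ab)))
  if (nrow(ab))
    cat(" [", paste(sprintf("%s:chr%s", ab$proband, ab$chrom),
                    collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.upd_cohort <- function(object, ...) {
  object$call_table <- stats::xtabs(n ~ call + parent, data = object$tally)
  class(object) <- "summary.upd_cohort"
  object
}

#' @export
print.summary.upd_cohort <- function(x, ...) {
  class(x) <- "upd_cohort"
  print(x)
  cat("\nCalls by type and parent:\n")
  print(x$call_table)
  cat("\nPer-chromosome AB% five-number summaries:\n")
  print(x$summaries[x$summaries$metric == "pct_ab", ], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.upd_cohort <- function(x, ...) x$table

#' Cohort boxplots of the two screen metrics
#'
#' Per-chromosome boxplots of the AB-genotype percentage and of proband
#' heterozygosity across the cohort, the discovery view in which UPD events
#' appear as extreme low-AB outliers.
#'
#' @param x An `upd_cohort` object.
#' @param metric `"pct_ab"`, `"pct_het"` or `"both"`.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.upd_cohort <- function(x, metric = c("both", "pct_ab", "pct_het"), ...) {
  metric <- match.arg(metric)
  ms <- if (metric == "both") c("pct_ab", "pct_het") else metric
  if (length(ms) == 2) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 2, 1))
    on.exit(graphics::par(op))
  }
  labs <- c(pct_ab = "AB genotypes (%)", pct_het = "heterozygosity (%)")
  for (m in ms) {
    f <- factor(x$table$chrom, levels = unique(x$table$chrom))
    graphics::boxplot(x$table[[m]] ~ f, xlab = "", ylab = labs[[m]],
                      las = 2, ...)
  }
  invisible(x)
}
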