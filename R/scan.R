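#' Scan a chromosome for segmental UPD candidate windows
#'
#' Evaluates one window of `window_size` bp anchored at every Mendelian-error
#' site: the window `[p, p + window_size)` is retained when it contains at
#' least `min_errors` Mendelian-error sites and proband heterozygosity at its
#' informative sites (non-missing proband) is at most `het_max_pct` percent.
#' Windows containing no informative site are not retained, since low
#' heterozygosity cannot be confirmed there.
#'
#' @param trio A `trio_genotypes` data frame (typically filtered).
#' @param chromosome Chromosome label.
#' @param window_size Window length in bp (default 5 Mb).
#' @param min_errors Minimum Mendelian-error count per window.
#' @param het_max_pct Maximum proband heterozygosity at the window's
#'   informative sites, percent.
#' @return Data frame of retained windows: `chrom`, `start`, `end` (1-based
#'   half-open), `n_errors`, `n_informative`, `pct_het`. Empty when no window
#'   qualifies.
#' @export
scan_partial <- function(trio, chromosome, window_size = 5e6,
                         min_errors = 50, het_max_pct = 10) {
  ch <- norm_chrom(chromosome)
  d <- trio[trio$chrom == ch, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_errors = integer(), n_informative = integer(),
                      pct_het = numeric(), stringsAsFactors = FALSE)
  if (!nrow(d)) return(empty)
  if (is.unsorted(d$pos)) stop("sites must be sorted by position")

  sc <- classify_site(d$gt_mother, d$gt_father, d$gt_proband)
  err_pos <- d$pos[which(sc$mendelian_error)]
  if (!length(err_pos)) return(empty)

  inf <- sc$informative & !is.na(d$gt_proband)
  inf_pos <- d$pos[inf]
  inf_het_cum <- c(0, cumsum(d$gt_proband[inf] == 1L))

  # half-open [p, p+W): counts via findInterval on sorted positions
  count_between <- function(pos_sorted, lo, hi) {
    findInterval(hi - 0.5, pos_sorted) - findInterval(lo - 0.5, pos_sorted)
  }
  starts <- err_pos
  ends <- starts + window_size
  n_err <- count_between(err_pos, starts, ends)
  i_lo <- findInterval(starts - 0.5, inf_pos)
  i_hi <- findInterval(ends - 0.5, inf_pos)
  n_inf <- i_hi - i_lo
  n_het <- inf_het_cum[i_hi + 1L] - inf_het_cum[i_lo + 1L]
  pct_het <- ifelse(n_inf > 0, 100 * n_het / n_inf, NA_real_)

  keep <- n_err >= min_errors & n_inf > 0 & pct_het <= het_max_pct
  keep <- !is.na(keep) & keep
  data.frame(chrom = rep(ch, sum(keep)), start = starts[keep], end = ends[keep],
             n_errors = n_err[keep], n_informative = n_inf[keep],
             pct_het = pct_het[keep], stringsAsFactors = FALSE)
}

#' Merge overlapping half-open intervals
#'
#' Returns the minimal sorted set of disjoint half-open intervals whose union
#' of positions equals the input union; overlapping and abutting intervals
#' (`end == next start`) merge, intervals separated by at least one position
#' do not. Idempotent.
#'
#' @param windows Data frame with `start` and `end` columns (half-open), e.g.
#'   from [scan_partial()]; any other columns are dropped.
#' @return Data frame with `start`, `end` (and `chrom` if present and unique).
#' @export
merge_windows <- function(windows) {
  if (!nrow(windows))
    return(data.frame(start = numeric(), end = numeric()))
  stopifnot(all(windows$end > windows$start))
  chrom <- unique(windows$chrom)
  if (length(chrom) > 1L) stop("merge_windows expects a single chromosome")
  o <- order(windows$start, windows$end)
  s <- windows$start[o]; e <- windows$end[o]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  res <- data.frame(start = out_s, end = out_e)
  if (length(chrom) == 1L && !is.null(chrom)) res <- cbind(chrom = chrom, res)
  res
}

#' Resolve a candidate region as partial UPD or deletion
#'
#' Compares mean proband read depth over the region's sites with the
#' genome-wide mean: only regions with coverage ratio strictly above
#' `ratio_min` (default 0.9, i.e. >90% of genome-wide coverage) are candidate
#' partial UPD; lower coverage indicates a hemizygous deletion, which mimics
#' isodisomy in genotypes but not in depth. Parent of origin is taken from
#' genotype matching at the region's informative sites.
#'
#' @param region List or one-row data frame with `chrom`, `start`, `end`
#'   (1-based half-open).
#' @param trio A `trio_genotypes` data frame.
#' @param genome_mean_depth Genome-wide mean proband depth (reads), e.g. from
#'   [genome_mean_coverage()].
#' @param ratio_min Coverage-ratio threshold (strict `>`).
#' @return A one-row data frame of class `candidate_region`: `chrom`,
#'   `start`, `end`, `n_mendelian_errors`, `n_informative`, `pct_het`,
#'   `mean_depth`, `coverage_ratio`, `resolution` (`"partial_upd"` or
#'   `"deletion"`), `parent` (`"mother"`, `"father"` or `"undetermined"`).
#' @export
resolve_region <- function(region, trio, genome_mean_depth, ratio_min = 0.9) {
  stopifnot(genome_mean_depth > 0)
  ch <- norm_chrom(region$chrom)
  d <- trio[trio$chrom == ch & trio$pos >= region$start &
              trio$pos < region$end, , drop = FALSE]
  if (!nrow(d) || all(is.na(d$dp_proband)))
    stop("no proband depth in region ", ch, ":", region$start, "-", region$end)

  sc <- classify_site(d$gt_mother, d$gt_father, d$gt_proband)
  inf <- sc$informative & !is.na(d$gt_proband)
  n_mm <- sum(sc$proband_match[inf] == "mother")
  n_mf <- sum(sc$proband_match[inf] == "father")
  parent <- if (n_mm == n_mf) "undetermined"
            else if (n_mm > n_mf) "mother" else "father"
  n_inf <- sum(inf)
  pct_het <- if (n_inf > 0)
    100 * sum(sc$proband_match[inf] == "biparental_het") / n_inf
  else NA_real_

  mean_depth <- mean(d$dp_proband, na.rm = TRUE)
  ratio <- mean_depth / genome_mean_depth
  out <- data.frame(
    chrom = ch, start = region$start, end = region$end,
    n_mendelian_errors = sum(sc$mendelian_error, na.rm = TRUE),
    n_informative = n_inf, pct_het = pct_het,
    mean_depth = mean_depth, coverage_ratio = ratio,
    resolution = if (ratio > ratio_min) "partial_upd" else "deletion",
    parent = parent, stringsAsFactors = FALSE)
  class(out) <- c("candidate_region", "data.frame")
  out
}
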