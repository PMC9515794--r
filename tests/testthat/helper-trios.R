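# Builders and independent brute-force oracles shared across the suite.

# Construct a trio table directly from genotype vectors (codes 0/1/2/NA).
make_trio <- function(gm, gf, gp, pos = seq_along(gm) * 1000, chrom = "1",
                      dp = 30, dp_proband = dp, gq = 99, af = 0.5,
                      sex = "female", id = "T1", chrom_lengths = NULL) {
  n <- length(gm)
  df <- data.frame(
    chrom = rep_len(norm_chrom(chrom), n), pos = pos,
    ref = rep_len("A", n), alt = rep_len("G", n), af = rep_len(af, n),
    gt_mother = as.integer(gm), gt_father = as.integer(gf),
    gt_proband = as.integer(gp),
    dp_mother = rep_len(dp, n), dp_father = rep_len(dp, n),
    dp_proband = rep_len(dp_proband, n),
    gq_mother = rep_len(gq, n), gq_father = rep_len(gq, n),
    gq_proband = rep_len(gq, n),
    stringsAsFactors = FALSE)
  updscreen:::new_trio_genotypes(
    df, samples = c(mother = "M", father = "F", proband = "P"),
    proband_sex = sex, proband_id = id, chrom_lengths = chrom_lengths)
}

# Random trio over one chromosome: iid genotypes, optional missingness.
random_trio <- function(n, chrom_len = n * 2000, p_missing = 0,
                        chrom = "1", dp = 30) {
  pos <- sort(sample.int(chrom_len, n))
  g <- function() {
    x <- sample(0:2, n, replace = TRUE)
    if (p_missing > 0) x[runif(n) < p_missing] <- NA_integer_
    as.integer(x)
  }
  make_trio(g(), g(), g(), pos = pos, chrom = chrom, dp = dp,
            chrom_lengths = stats::setNames(chrom_len, norm_chrom(chrom)))
}

# Brute-force transmission oracle for one genotype triple.
oracle_classify_site <- function(gm, gf, gp) {
  alleles <- function(g) switch(g + 1L, 0L, 0:1, 1L)
  err <- if (any(is.na(c(gm, gf, gp)))) NA else {
    possible <- unique(as.vector(outer(alleles(gm), alleles(gf), `+`)))
    !(gp %in% possible)
  }
  informative <- !is.na(gm) && !is.na(gf) &&
    ((gm == 0L && gf == 2L) || (gm == 2L && gf == 0L))
  match <- "not_applicable"
  if (informative && !is.na(gp)) {
    match <- if (gp == 1L) "biparental_het"
             else if (gp == gm) "mother" else "father"
  }
  list(informative = informative, mendelian_error = err,
       proband_match = match)
}

# Exhaustive window evaluation: every Mendelian-error-anchored window,
# evaluated by direct subsetting.
oracle_scan <- function(trio, chrom, window_size, min_errors, het_max_pct) {
  d <- trio[trio$chrom == norm_chrom(chrom), , drop = FALSE]
  sc <- classify_site(d$gt_mother, d$gt_father, d$gt_proband)
  anchors <- d$pos[which(sc$mendelian_error)]
  rows <- list()
  for (p in anchors) {
    inw <- d$pos >= p & d$pos < p + window_size
    n_err <- sum(sc$mendelian_error[inw], na.rm = TRUE)
    inf <- inw & sc$informative & !is.na(d$gt_proband)
    n_inf <- sum(inf)
    if (n_inf == 0) next
    pct <- 100 * sum(d$gt_proband[inf] == 1L) / n_inf
    if (n_err >= min_errors && pct <= het_max_pct)
      rows[[length(rows) + 1L]] <- data.frame(
        start = p, end = p + window_size, n_errors = n_err,
        n_informative = n_inf, pct_het = pct)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(start = numeric(), end = numeric(), n_errors = integer(),
                  n_informative = integer(), pct_het = numeric())
}

# Union-of-points oracle for half-open interval merging (small coordinates).
oracle_merge <- function(starts, ends) {
  pts <- sort(unique(unlist(Map(function(s, e) seq(s, e - 1), starts, ends))))
  brk <- c(0, which(diff(pts) > 1), length(pts))
  data.frame(start = pts[brk[-length(brk)] + 1],
             end = pts[brk[-1]] + 1)
}

# Interval overlap helpers (half-open).
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / (max(e1, e2) - min(s1, s2))
}

overlaps <- function(s1, e1, s2, e2) min(e1, e2) > max(s1, s2)

# Shared small chromosome set for fast simulations.
small_lengths <- function(chroms = c("21", "22")) grch38_lengths(chroms)

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_script <- function() {
  path <- file.path(system.file(package = "updscreen"), "exec", "updscreen")
  if (!file.exists(path)) path <- file.path(system.file(package = "updscreen"),
                                            "..", "..", "exec", "updscreen")
  normalizePath(path, mustWork = FALSE)
}

run_cli <- function(args) {
  out <- suppressWarnings(
    system2(rscript_bin(), c(cli_script(), args),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
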