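# Which child genotypes are consistent with one allele transmitted from each
# parent. consistent[m+1, f+1, c+1], genotype codes 0/1/2.
.transmission_table <- local({
  arr <- array(FALSE, dim = c(3, 3, 3))
  alleles <- list(0L, 0:1, 1L)  # alleles transmissible by genotype 0, 1, 2
  for (m in 0:2) for (f in 0:2)
    for (am in alleles[[m + 1]]) for (af in alleles[[f + 1]])
      arr[m + 1, f + 1, am + af + 1] <- TRUE
  arr
})

#' Classify one site of a trio
#'
#' Vectorized over sites. A site is *informative* when the parents are
#' homozygous for different alleles (AA x BB): the only genotype consistent
#' with biparental inheritance in the child is then AB. A *Mendelian error*
#' is a proband genotype impossible under transmission of one allele from
#' each parent (any missing genotype gives `NA`, never an error). At
#' informative sites `proband_match` records whether the proband genotype is
#' identical to the mother's, the father's, or is the biparental heterozygote;
#' everywhere else it is `not_applicable`.
#'
#' @param g_mother,g_father,g_proband Integer genotype codes (0 = hom-ref,
#'   1 = het, 2 = hom-alt, `NA` = missing), recycled to a common length.
#' @return A data frame with logical `informative`, logical `mendelian_error`
#'   (`NA` when any member is missing) and character `proband_match` in
#'   `{"mother", "father", "biparental_het", "not_applicable"}`.
#' @export
#' @examples
#' classify_site(0L, 2L, 0L)  # informative site, proband matches mother
classify_site <- function(g_mother, g_father, g_proband) {
  n <- max(length(g_mother), length(g_father), length(g_proband))
  gm <- rep_len(as.integer(g_mother), n)
  gf <- rep_len(as.integer(g_father), n)
  gp <- rep_len(as.integer(g_proband), n)

  complete <- !is.na(gm) & !is.na(gf) & !is.na(gp)
  mendelian_error <- rep(NA, n)
  mendelian_error[complete] <-
    !.transmission_table[cbind(gm[complete], gf[complete], gp[complete]) + 1L]

  informative <- !is.na(gm) & !is.na(gf) &
    ((gm == 0L & gf == 2L) | (gm == 2L & gf == 0L))

  proband_match <- rep("not_applicable", n)
  at <- informative & !is.na(gp)
  proband_match[at & gp == 1L] <- "biparental_het"
  proband_match[at & gp != 1L & gp == gm] <- "mother"
  proband_match[at & gp != 1L & gp == gf] <- "father"

  data.frame(informative = informative, mendelian_error = mendelian_error,
             proband_match = proband_match, stringsAsFactors = FALSE)
}

#' Per-chromosome screening metrics
#'
#' Computes the two chromosome-level screen metrics and the parent-of-origin
#' tallies for one chromosome: proband heterozygosity (`pct_het`, percentage
#' of heterozygous calls among non-missing proband genotypes) and the
#' AB-genotype percentage at informative sites (`pct_ab`), together with the
#' percentages of informative sites where the proband genotype is identical
#' to the mother's (`pct_match_mother`) or the father's (`pct_match_father`).
#' `skew` is the larger of the two match percentages (uniparental skewing).
#' Percentages with an empty denominator are `NA` (undefined), never 0.
#'
#' @param trio A `trio_genotypes` data frame.
#' @param chromosome Chromosome label (with or without `chr` prefix).
#' @return A one-row data frame of class `chromosome_stats` with columns
#'   `chrom`, `n_nonmissing`, `n_het`, `pct_het`, `n_informative`, `n_ab`,
#'   `pct_ab`, `n_match_mother`, `n_match_father`, `pct_match_mother`,
#'   `pct_match_father`, `skew`, `n_mendelian_errors`. At informative sites
#'   with a non-missing proband genotype,
#'   `n_ab + n_match_mother + n_match_father = n_informative`.
#' @export
chromosome_stats <- function(trio, chromosome) {
  ch <- norm_chrom(chromosome)
  d <- trio[trio$chrom == ch, , drop = FALSE]
  gp <- d$gt_proband
  sc <- classify_site(d$gt_mother, d$gt_father, gp)

  n_nonmissing <- sum(!is.na(gp))
  n_het <- sum(gp == 1L, na.rm = TRUE)
  inf <- sc$informative & !is.na(gp)
  n_informative <- sum(inf)
  n_ab <- sum(sc$proband_match[inf] == "biparental_het")
  n_mm <- sum(sc$proband_match[inf] == "mother")
  n_mf <- sum(sc$proband_match[inf] == "father")

  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  pct_mm <- pct(n_mm, n_informative)
  pct_mf <- pct(n_mf, n_informative)

  out <- data.frame(
    chrom = ch, n_nonmissing = n_nonmissing, n_het = n_het,
    pct_het = pct(n_het, n_nonmissing),
    n_informative = n_informative, n_ab = n_ab,
    pct_ab = pct(n_ab, n_informative),
    n_match_mother = n_mm, n_match_father = n_mf,
    pct_match_mother = pct_mm, pct_match_father = pct_mf,
    skew = if (n_informative > 0) max(pct_mm, pct_mf) else NA_real_,
    n_mendelian_errors = sum(sc$mendelian_error, na.rm = TRUE),
    stringsAsFactors = FALSE)
  class(out) <- c("chromosome_stats", "data.frame")
  out
}

#' Parent of origin of a disomic chromosome
#'
#' Returns the parent whose genotypes the proband matches most often at
#' informative sites, with the match percentage; an exact tie is reported as
#' `undetermined` rather than an arbitrary parent.
#'
#' @param stats A [chromosome_stats()] row.
#' @return A list with `parent` (`"mother"`, `"father"` or `"undetermined"`)
#'   and `percentage`.
#' @export
disomy_direction <- function(stats) {
  if (is.na(stats$n_informative) || stats$n_informative == 0L)
    stop("direction undefined: zero informative sites on chromosome ",
         stats$chrom)
  if (stats$pct_match_mother == stats$pct_match_father)
    return(list(parent = "undetermined",
                percentage = stats$pct_match_mother))
  if (stats$pct_match_mother > stats$pct_match_father)
    list(parent = "mother", percentage = stats$pct_match_mother)
  else
    list(parent = "father", percentage = stats$pct_match_father)
}

#' Classify a chromosome as UPD
#'
#' Pure rule over the chromosome metrics: a chromosome with uniparental skew
#' above `skew_min` is isodisomic (`upid`) when heterozygosity is below
#' `upid_het_max`, heterodisomic (`uphd`) when above `uphd_het_min`, and
#' `ambiguous_skewed` in between. Chromosomes below the site-count floors are
#' `insufficient_data`, as is the X of a male proband (never screened).
#' Unskewed chromosomes with heterozygosity above `het_excess_min` receive an
#' advisory `het_excess_flag` (trisomy signature); everything else is `none`.
#'
#' @param stats A [chromosome_stats()] row.
#' @param thresholds A [classify_thresholds()].
#' @param proband_sex `"female"` or `"male"`.
#' @return A one-row data frame of class `chromosome_call` with `chrom`,
#'   `call` in `{none, upid, uphd, ambiguous_skewed, insufficient_data,
#'   het_excess_flag}` and `parent` in `{mother, father, not_applicable}`.
#' @export
classify_chromosome <- function(stats, thresholds = classify_thresholds(),
                                proband_sex = c("female", "male")) {
  proband_sex <- match.arg(proband_sex)
  th <- thresholds
  call <- "none"
  parent <- "not_applicable"

  if (norm_chrom(stats$chrom) == "X" && proband_sex == "male") {
    call <- "insufficient_data"
  } else if (stats$n_nonmissing < th$min_nonmissing ||
             stats$n_informative < th$min_informative ||
             is.na(stats$skew) || is.na(stats$pct_het)) {
    call <- "insufficient_data"
  } else if (stats$skew > th$skew_min) {
    call <- if (stats$pct_het < th$upid_het_max) "upid"
            else if (stats$pct_het > th$uphd_het_min) "uphd"
            else "ambiguous_skewed"
    parent <- disomy_direction(stats)$parent
  } else if (stats$pct_het > th$het_excess_min) {
    call <- "het_excess_flag"
  }

  out <- data.frame(chrom = stats$chrom, call = call, parent = parent,
                    stringsAsFactors = FALSE)
  class(out) <- c("chromosome_call", "data.frame")
  out
}
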