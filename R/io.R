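# genotype code <-> VCF GT string
.gt_string <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}

.gt_code <- function(s) {
  s <- gsub("|", "/", s, fixed = TRUE)
  out <- rep(NA_integer_, length(s))
  out[s %in% c("0/0")] <- 0L
  out[s %in% c("0/1", "1/0")] <- 1L
  out[s %in% c("1/1")] <- 2L
  out
}

#' Write a trio as a multi-sample VCF
#'
#' Emits a VCF v4.2 with `GT:DP:GQ` per sample and the population
#' alternate-allele frequency in the INFO `AF` field, using GRCh38-style
#' `chr`-prefixed contig names. Sample columns appear in mother, father,
#' proband order under the names stored on the trio. The file round-trips
#' through [load_trio()] without loss.
#'
#' @param trio A `trio_genotypes` data frame (see [simulate_trio()]).
#' @param path Output path (`.vcf`; plain text).
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(trio, path) {
  stopifnot(inherits(trio, "trio_genotypes"))
  if (is.unsorted(order(chrom_rank(trio$chrom), trio$pos)))
    stop("trio table must be sorted by (chromosome, position)")
  s <- attr(trio, "samples")
  lens <- attr(trio, "chrom_lengths")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=updscreen",
    if (!is.null(lens))
      sprintf("##contig=<ID=chr%s,length=%.0f>", names(lens), lens),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", s[["mother"]], s[["father"]], s[["proband"]]),
          collapse = "\t")
  )
  fmt_sample <- function(role) {
    sprintf("%s:%d:%d", .gt_string(trio[[paste0("gt_", role)]]),
            as.integer(trio[[paste0("dp_", role)]]),
            as.integer(trio[[paste0("gq_", role)]]))
  }
  body <- if (nrow(trio)) {
    paste(paste0("chr", trio$chrom), sprintf("%.0f", trio$pos), ".",
          trio$ref, trio$alt, ".", "PASS",
          sprintf("AF=%.6g", trio$af), "GT:DP:GQ",
          fmt_sample("mother"), fmt_sample("father"), fmt_sample("proband"),
          sep = "\t")
  } else character()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Write the pedigree of a trio
#'
#' Standard 6-column PED (family, individual, father, mother, sex,
#' phenotype): parents as founders, proband affected with its simulated sex.
#'
#' @param trio A `trio_genotypes` data frame.
#' @param path Output path.
#' @param family Family identifier.
#' @return `path`, invisibly.
#' @export
write_trio_ped <- function(trio, path, family = "FAM1") {
  s <- attr(trio, "samples")
  sex_code <- if (identical(attr(trio, "proband_sex"), "male")) 1L else 2L
  lines <- c(
    paste(family, s[["father"]], 0, 0, 1, 1, sep = "\t"),
    paste(family, s[["mother"]], 0, 0, 2, 1, sep = "\t"),
    paste(family, s[["proband"]], s[["father"]], s[["mother"]], sex_code, 2,
          sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write planted-event truth records as BED
#'
#' BED is 0-based half-open; internal intervals are 1-based half-open, so
#' coordinates shift by one. Columns: chrom, start, end, proband, event,
#' parent.
#'
#' @param truth Truth data frame from [simulate_trio()] / [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  lines <- if (nrow(truth)) {
    paste(paste0("chr", truth$chrom),
          sprintf("%.0f", truth$start - 1), sprintf("%.0f", truth$end - 1),
          truth$proband, truth$event,
          ifelse(is.na(truth$parent), ".", truth$parent),
          sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a trio pedigree
#'
#' Parses a 6-column PED file and resolves the one declared trio: exactly one
#' individual must have both parents present in the file.
#'
#' @param path PED file (whitespace-delimited: family, individual, father,
#'   mother, sex, phenotype).
#' @return A list with `mother`, `father`, `proband` (sample names),
#'   `proband_sex` (`"male"`/`"female"`) and `family`.
#' @export
read_ped <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"))
  ped[] <- lapply(ped, as.character)
  is_child <- ped$father %in% ped$id & ped$mother %in% ped$id &
    ped$father != "0" & ped$mother != "0"
  if (sum(is_child) != 1L)
    stop("pedigree must declare exactly one proband with both parents ",
         "present (found ", sum(is_child), ")")
  child <- ped[is_child, ]
  sex <- switch(child$sex, `1` = "male", `2` = "female",
                stop("proband sex must be 1 (male) or 2 (female)"))
  list(mother = child$mother, father = child$father, proband = child$id,
       proband_sex = sex, family = child$family)
}

#' Read a site list with population allele frequencies
#'
#' @param path TSV with columns chrom, pos, ref, alt, af (header optional,
#'   detected from the first line).
#' @return Data frame with normalized chromosome labels and a `key` column
#'   `chrom:pos:ref:alt`.
#' @export
read_site_list <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  sl <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  names(sl)[1:5] <- c("chrom", "pos", "ref", "alt", "af")
  sl$chrom <- norm_chrom(sl$chrom)
  sl$key <- paste(sl$chrom, sl$pos, sl$ref, sl$alt, sep = ":")
  sl
}

#' Load trio genotypes from a joint-genotyped VCF
#'
#' Reads a multi-sample VCF, resolves the mother/father/proband roles from a
#' pedigree, and returns per-site genotype codes, depths, genotype qualities
#' and a population alternate-allele frequency. Only biallelic SNVs are kept
#' when `snv_only` is set (multi-allelic records and indels are dropped and
#' counted). Chromosome names with and without a `chr` prefix are accepted.
#'
#' @param vcf_path VCF v4.2 path (plain or bgzipped).
#' @param pedigree PED file path, or a list as returned by [read_ped()].
#' @param af_source Name of the INFO field with the alternate-allele
#'   frequency (default `"AF"`), or the path of a TSV site list
#'   (chrom, pos, ref, alt, af) keyed by position and alleles.
#' @param snv_only Drop non-SNV and multi-allelic records.
#' @return A `trio_genotypes` data frame (see [simulate_trio()] for the
#'   layout); the number of excluded non-SNV records is recorded in the
#'   `accounting` attribute.
#' @export
load_trio <- function(vcf_path, pedigree, af_source = "AF", snv_only = TRUE) {
  if (is.character(pedigree)) pedigree <- read_ped(pedigree)
  stopifnot(all(c("mother", "father", "proband", "proband_sex") %in%
                  names(pedigree)))
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  roles <- c(mother = pedigree$mother, father = pedigree$father,
             proband = pedigree$proband)
  absent <- roles[!roles %in% vcf_samples]
  if (length(absent))
    stop("pedigree sample(s) not in VCF: ", paste(absent, collapse = ", "))

  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0L) {
    empty <- data.frame(chrom = character(), pos = numeric(),
                        ref = character(), alt = character(), af = numeric(),
                        gt_mother = integer(), gt_father = integer(),
                        gt_proband = integer(), dp_mother = numeric(),
                        dp_father = numeric(), dp_proband = numeric(),
                        gq_mother = numeric(), gq_father = numeric(),
                        gq_proband = numeric(), stringsAsFactors = FALSE)
    out <- new_trio_genotypes(empty, samples = roles,
                              proband_sex = pedigree$proband_sex,
                              proband_id = pedigree$proband)
    attr(out, "accounting") <- list(n_input = 0L, n_removed_nonsnv = 0L)
    return(out)
  }

  keep <- rep(TRUE, n_in)
  if (snv_only) {
    nt <- c("A", "C", "G", "T")
    keep <- fix$REF %in% nt & fix$ALT %in% nt & !is.na(fix$ALT)
  }
  n_nonsnv <- sum(!keep)

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))

  if (file.exists(af_source)) {
    sl <- read_site_list(af_source)
    key <- paste(norm_chrom(fix$CHROM), fix$POS, fix$REF, fix$ALT, sep = ":")
    af <- sl$af[match(key, sl$key)]
  } else {
    af <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = af_source)))
    if (all(is.na(af)))
      stop("allele-frequency INFO field '", af_source,
           "' absent or empty in VCF")
  }

  col <- function(m, role) {
    if (is.null(dim(m))) m <- matrix(m, nrow = n_in,
                                     dimnames = list(NULL, vcf_samples))
    m[keep, roles[[role]]]
  }
  df <- data.frame(
    chrom = norm_chrom(fix$CHROM[keep]),
    pos = as.numeric(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep], af = af[keep],
    gt_mother = .gt_code(col(gt_raw, "mother")),
    gt_father = .gt_code(col(gt_raw, "father")),
    gt_proband = .gt_code(col(gt_raw, "proband")),
    dp_mother = col(dp, "mother"), dp_father = col(dp, "father"),
    dp_proband = col(dp, "proband"),
    gq_mother = col(gq, "mother"), gq_father = col(gq, "father"),
    gq_proband = col(gq, "proband"),
    stringsAsFactors = FALSE)

  out <- new_trio_genotypes(df, samples = roles,
                            proband_sex = pedigree$proband_sex,
                            proband_id = pedigree$proband)
  attr(out, "accounting") <- list(n_input = n_in, n_removed_nonsnv = n_nonsnv)
  out
}

#' Apply site and genotype filters
#'
#' Sites with population minor allele frequency (`min(af, 1 - af)`) below
#' `maf_min` are removed. A genotype call with depth outside
#' `[depth_min, depth_max]` or quality below `gq_min` is set missing for that
#' sample only, so the site can stay informative for the other members.
#' Filtering is idempotent. Per-criterion removal counts are recorded in the
#' `accounting` attribute, and the pre-filter mean depth per sample is kept in
#' the `genome_depth` attribute (preserved, not recomputed, on repeated
#' application).
#'
#' @param trio A `trio_genotypes` data frame.
#' @param config A [filter_config()].
#' @return The filtered `trio_genotypes` with `filtered = TRUE`.
#' @export
apply_filters <- function(trio, config = filter_config()) {
  stopifnot(inherits(trio, "trio_genotypes"),
            inherits(config, "filter_config"))
  acct_prev <- attr(trio, "accounting")
  # keep the original record count so accounting stays conservative across
  # load_trio -> apply_filters: n_input = n_output + removed(MAF) + removed(non-SNV)
  n_input <- if (!is.null(acct_prev$n_input)) acct_prev$n_input else nrow(trio)

  gdepth <- attr(trio, "genome_depth")
  if (is.null(gdepth)) {
    gdepth <- vapply(c("mother", "father", "proband"), function(role) {
      d <- trio[[paste0("dp_", role)]]
      if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
    }, numeric(1))
  }

  nonsnv <- 0L
  if (config$snv_only && n_input) {
    nt <- c("A", "C", "G", "T")
    is_snv <- trio$ref %in% nt & trio$alt %in% nt
    nonsnv <- sum(!is_snv)
    trio <- trio[is_snv, , drop = FALSE]
  }
  maf <- pmin(trio$af, 1 - trio$af)
  low_maf <- !is.na(maf) & maf < config$maf_min
  n_maf <- sum(low_maf)
  trio <- trio[!low_maf, , drop = FALSE]

  gt_removed <- c(mother = 0L, father = 0L, proband = 0L)
  for (role in c("mother", "father", "proband")) {
    d <- trio[[paste0("dp_", role)]]
    q <- trio[[paste0("gq_", role)]]
    g <- trio[[paste0("gt_", role)]]
    fail <- (!is.na(d) & (d < config$depth_min | d > config$depth_max)) |
      (!is.na(q) & q < config$gq_min)
    gt_removed[[role]] <- sum(fail & !is.na(g))
    g[fail] <- NA_integer_
    trio[[paste0("gt_", role)]] <- g
  }

  out <- new_trio_genotypes(as.data.frame(trio),
                            samples = attr(trio, "samples"),
                            proband_sex = attr(trio, "proband_sex"),
                            proband_id = attr(trio, "proband_id"),
                            chrom_lengths = attr(trio, "chrom_lengths"),
                            filtered = TRUE)
  attr(out, "genome_depth") <- gdepth
  attr(out, "accounting") <- list(
    n_input = n_input,
    n_removed_nonsnv = nonsnv +
      (if (!is.null(acct_prev$n_removed_nonsnv)) acct_prev$n_removed_nonsnv else 0L),
    n_removed_maf = n_maf +
      (if (!is.null(acct_prev$n_removed_maf)) acct_prev$n_removed_maf else 0L),
    n_output = nrow(out),
    genotypes_set_missing = gt_removed)
  out
}

#' Genome-wide mean coverage proxy
#'
#' Arithmetic mean of per-site read depth for one trio member across all
#' loaded sites. On a filtered trio the pre-filter mean recorded by
#' [apply_filters()] is returned, so the depth filter does not bias the
#' coverage baseline used for deletion discrimination.
#'
#' @param trio A `trio_genotypes` data frame.
#' @param sample_role `"mother"`, `"father"` or `"proband"`.
#' @return Mean depth in reads.
#' @export
genome_mean_coverage <- function(trio, sample_role = c("proband", "mother",
                                                       "father")) {
  sample_role <- match.arg(sample_role)
  gdepth <- attr(trio, "genome_depth")
  if (!is.null(gdepth) && !is.na(gdepth[[sample_role]]))
    return(unname(gdepth[[sample_role]]))
  d <- trio[[paste0("dp_", sample_role)]]
  if (is.null(d) || all(is.na(d)))
    stop("no depth data for role '", sample_role, "'")
  mean(d, na.rm = TRUE)
}
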