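#' GRCh38 chromosome lengths
#'
#' Primary-assembly sequence lengths for the chromosomes the screen considers
#' (autosomes 1-22 and X), used as default coordinate bounds by the synthetic
#' trio generator and as contig headers when writing VCF.
#'
#' @param chroms Character vector of chromosome labels to return (with or
#'   without a `"chr"` prefix). Defaults to all 23.
#' @return Named numeric vector of lengths in base pairs; names are
#'   normalized labels (`"1"` ... `"22"`, `"X"`).
#' @export
#' @examples
#' grch38_lengths(c("chr1", "X"))
grch38_lengths <- function(chroms = NULL) {
  lens <- c(
    `1` = 248956422, `2` = 242193529, `3` = 198295559, `4` = 190214555,
    `5` = 181538259, `6` = 170805979, `7` = 159345973, `8` = 145138636,
    `9` = 138394717, `10` = 133797422, `11` = 135086622, `12` = 133275309,
    `13` = 114364328, `14` = 107043718, `15` = 101991189, `16` = 90338345,
    `17` = 83257441, `18` = 80373285, `19` = 58617616, `20` = 64444167,
    `21` = 46709983, `22` = 50818468, X = 156040895
  )
  if (is.null(chroms)) return(lens)
  keys <- norm_chrom(chroms)
  bad <- setdiff(keys, names(lens))
  if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  lens[keys]
}

#' Normalize chromosome labels
#'
#' Accepts `"chr1"`/`"1"` style names interchangeably and returns the bare
#' label used internally (`"1"`..`"22"`, `"X"`, `"Y"`, `"MT"`).
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
norm_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x <- toupper(x)
  x[x == "M"] <- "MT"
  x
}

# canonical screen order: autosomes then X
.chrom_order <- c(as.character(1:22), "X")

chrom_rank <- function(x) {
  r <- match(norm_chrom(x), .chrom_order)
  r[is.na(r)] <- length(.chrom_order) + 1L
  r
}

#' Chromosomes screened for a proband
#'
#' Autosomes 1-22 for male probands; autosomes plus X for female probands
#' (the X is uninformative for UPD in males, who carry a single maternal X).
#'
#' @param proband_sex `"male"` or `"female"`.
#' @return Character vector of normalized chromosome labels.
#' @export
screened_chromosomes <- function(proband_sex = c("female", "male")) {
  proband_sex <- match.arg(proband_sex)
  if (proband_sex == "female") .chrom_order else as.character(1:22)
}
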