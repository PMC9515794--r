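#' Simulate a common-SNV site panel
#'
#' Draws a panel of biallelic SNV positions per chromosome with population
#' alternate-allele frequencies uniform in `[af_low, af_high]`. The default
#' bounds emulate the screen's site selection (minor allele frequency >= 0.4),
#' which maximizes the density of informative AA x BB parental configurations.
#'
#' @param n_sites_per_chrom Number of sites on each chromosome.
#' @param chrom_lengths Named vector of chromosome lengths in bp
#'   (default [grch38_lengths()]).
#' @param af_low,af_high Bounds of the alternate-allele frequency; with
#'   `af_low >= 0.4` and `af_high <= 0.6` every site has MAF >= 0.4.
#' @param seed Optional integer seed; identical seeds give identical panels.
#' @return A data frame of class `site_panel` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `af`, sorted by (chromosome, position), positions strictly
#'   increasing within a chromosome. Chromosome lengths are kept as an
#'   attribute.
#' @export
#' @examples
#' p <- simulate_site_panel(100, grch38_lengths(c("21", "22")), seed = 1)
#' range(p$af)
simulate_site_panel <- function(n_sites_per_chrom,
                                chrom_lengths = grch38_lengths(),
                                af_low = 0.4, af_high = 0.6, seed = NULL) {
  stopifnot(n_sites_per_chrom >= 1, af_low <= af_high,
            af_low >= 0, af_high <= 1)
  if (!is.null(seed)) set.seed(seed)
  names(chrom_lengths) <- norm_chrom(names(chrom_lengths))
  short <- chrom_lengths < n_sites_per_chrom
  if (any(short))
    stop("chromosome(s) shorter than n_sites_per_chrom: ",
         paste(names(chrom_lengths)[short], collapse = ", "))
  ord <- order(chrom_rank(names(chrom_lengths)))
  chrom_lengths <- chrom_lengths[ord]
  nt <- c("A", "C", "G", "T")
  per_chrom <- lapply(names(chrom_lengths), function(ch) {
    pos <- sort(sample.int(chrom_lengths[[ch]], n_sites_per_chrom))
    ref <- sample(nt, n_sites_per_chrom, replace = TRUE)
    shift <- sample.int(3L, n_sites_per_chrom, replace = TRUE)
    alt <- nt[(match(ref, nt) - 1L + shift) %% 4L + 1L]
    data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
               af = stats::runif(n_sites_per_chrom, af_low, af_high),
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, per_chrom)
  rownames(panel) <- NULL
  attr(panel, "chrom_lengths") <- chrom_lengths
  class(panel) <- c("site_panel", "data.frame")
  panel
}

# --- scenario -----------------------------------------------------------

.event_kinds <- c("biparental", "upid_maternal", "upid_paternal",
                  "uphd_maternal", "uphd_paternal", "partial_upid",
                  "deletion", "trisomy_like", "autozygous")

normalize_event <- function(ev, chrom = "?") {
  if (is.character(ev) && length(ev) == 1L) ev <- list(kind = ev)
  if (!is.list(ev) || is.null(ev$kind))
    stop("event for chromosome ", chrom, " must be a kind string or a list with $kind")
  if (!ev$kind %in% .event_kinds)
    stop("unknown event kind '", ev$kind, "' for chromosome ", chrom)
  if (ev$kind == "partial_upid") {
    if (is.null(ev$parent) || !ev$parent %in% c("mother", "father"))
      stop("partial_upid on chromosome ", chrom, " needs parent 'mother' or 'father'")
    if (is.null(ev$start) || is.null(ev$end) || ev$start >= ev$end)
      stop("partial_upid on chromosome ", chrom, " needs start < end")
  }
  if (ev$kind == "deletion") {
    if (is.null(ev$inherited_from) || !ev$inherited_from %in% c("mother", "father"))
      stop("deletion on chromosome ", chrom, " needs inherited_from 'mother' or 'father'")
    if (is.null(ev$start) || is.null(ev$end) || ev$start >= ev$end)
      stop("deletion on chromosome ", chrom, " needs start < end")
  }
  if (ev$kind == "autozygous") {
    if (is.null(ev$fraction)) ev$fraction <- 0.25
    stopifnot(ev$fraction >= 0, ev$fraction <= 1)
  }
  ev
}

#' Declare a per-chromosome inheritance scenario
#'
#' A scenario assigns at most one inheritance event to each chromosome and
#' fixes the noise model for a simulated trio. Event kinds: `biparental`,
#' `upid_maternal` / `upid_paternal` (whole-chromosome isodisomy: two copies
#' of one homolog of that parent), `uphd_maternal` / `uphd_paternal`
#' (heterodisomy: both homologs of that parent), `partial_upid` (isodisomy
#' over a half-open interval `[start, end)`; needs `parent`, `start`, `end`),
#' `deletion` (hemizygous interval reported as homozygous diploid calls with
#' halved expected depth; needs `start`, `end`, `inherited_from`),
#' `trisomy_like` (heterozygous calls forced at `trisomy_het_rate`), and
#' `autozygous` (a fraction of sites where both parents share a transmitted
#' haplotype; optional `fraction`, default 0.25).
#'
#' @param events Named list (chromosome -> event): either a kind string or a
#'   list with `kind` plus event-specific fields.
#' @param default_event Event applied to chromosomes absent from `events`;
#'   `"biparental"` or an `autozygous` event (genome-wide consanguinity).
#' @param error_rate Per-genotype-call error probability in `[0, 0.01]`; an
#'   erroneous call is replaced by one of the two other diploid genotypes,
#'   uniformly. Default 3e-4, calibrated so isodisomic chromosomes show
#'   ~99.97% parent matching.
#' @param mean_depth Expected read depth per site (halved inside deletions).
#' @param depth_dispersion Negative-binomial size parameter for depth.
#' @param gq_fail_rate Fraction of genotype-quality values drawn below the
#'   default GQ filter (uniform on 0..14); the rest are 99.
#' @param trisomy_het_rate Probability a `trisomy_like` site is forced
#'   heterozygous. Default 0.75, the chance a trisomic site carries both
#'   alleles at allele frequency 0.5.
#' @param seed Optional integer seed used by [simulate_trio()].
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(events = list(), default_event = "biparental",
                         error_rate = 3e-4, mean_depth = 30,
                         depth_dispersion = 20, gq_fail_rate = 0.01,
                         trisomy_het_rate = 0.75, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.01, mean_depth > 0,
            depth_dispersion > 0, gq_fail_rate >= 0, gq_fail_rate <= 1,
            trisomy_het_rate >= 0, trisomy_het_rate <= 1)
  if (length(events)) {
    if (is.null(names(events)) || any(!nzchar(names(events))))
      stop("events must be a named list keyed by chromosome")
    names(events) <- norm_chrom(names(events))
    if (anyDuplicated(names(events)))
      stop("at most one event per chromosome")
    events <- mapply(normalize_event, events, names(events), SIMPLIFY = FALSE)
  }
  default_event <- normalize_event(default_event, "<default>")
  if (!default_event$kind %in% c("biparental", "autozygous"))
    stop("default_event must be biparental or autozygous")
  structure(list(events = events, default_event = default_event,
                 error_rate = error_rate, mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 gq_fail_rate = gq_fail_rate,
                 trisomy_het_rate = trisomy_het_rate, seed = seed),
            class = "sim_scenario")
}

scenario_event <- function(scenario, chrom) {
  ev <- scenario$events[[norm_chrom(chrom)]]
  if (is.null(ev)) scenario$default_event else ev
}

# --- trio container -----------------------------------------------------

new_trio_genotypes <- function(df, samples, proband_sex, proband_id,
                               chrom_lengths = NULL, filtered = FALSE) {
  ord <- order(chrom_rank(df$chrom), df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            samples = samples, proband_sex = proband_sex,
            proband_id = proband_id, chrom_lengths = chrom_lengths,
            filtered = filtered,
            class = c("trio_genotypes", "data.frame"))
}

#' @export
print.trio_genotypes <- function(x, ...) {
  s <- attr(x, "samples")
  cat(sprintf("Trio genotypes: %s sites on %d chromosome(s)\n",
              format(nrow(x), big.mark = ","),
              length(unique(x$chrom))))
  cat(sprintf("  mother=%s father=%s proband=%s (%s)%s\n",
              s[["mother"]], s[["father"]], s[["proband"]],
              attr(x, "proband_sex"),
              if (isTRUE(attr(x, "filtered"))) ", filtered" else ""))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

# draw one transmitted allele per site from a pair of homologs
.pick_allele <- function(h1, h2) {
  ifelse(stats::runif(length(h1)) < 0.5, h1, h2)
}

#' Simulate a mother-father-proband trio over a site panel
#'
#' Parental genotypes are drawn site-wise from Hardy-Weinberg proportions at
#' the panel allele frequency as two explicit homologous alleles (independent
#' across sites; the screen uses no linkage information). The proband is then
#' built per chromosome according to the scenario event, genotype errors are
#' applied independently per call, and per-sample depth and genotype-quality
#' values are attached. Male probands carry no X records.
#'
#' @param panel A [simulate_site_panel()] result (or data frame with the same
#'   columns).
#' @param scenario A [sim_scenario()].
#' @param proband_sex `"female"` or `"male"`.
#' @param proband_id Proband identifier used in truth records and reports.
#' @param sample_names Named character vector with elements `mother`,
#'   `father`, `proband`: the VCF sample names.
#' @return A list with elements `trio` (a `trio_genotypes` data frame:
#'   genotype codes 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing, plus
#'   per-sample `dp_*`/`gq_*` and the panel `af`) and `truth` (one row per
#'   planted non-biparental event: `proband`, `chrom`, `event`, `parent`,
#'   `start`, `end` (1-based half-open), `whole_chromosome`).
#' @export
simulate_trio <- function(panel, scenario = sim_scenario(),
                          proband_sex = c("female", "male"),
                          proband_id = "PROBAND",
                          sample_names = c(mother = "MOTHER",
                                           father = "FATHER",
                                           proband = "PROBAND")) {
  proband_sex <- match.arg(proband_sex)
  stopifnot(inherits(scenario, "sim_scenario"),
            all(c("mother", "father", "proband") %in% names(sample_names)))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)

  chrom_lengths <- attr(panel, "chrom_lengths")
  panel <- as.data.frame(panel)
  panel$chrom <- norm_chrom(panel$chrom)
  miss <- setdiff(names(scenario$events), unique(panel$chrom))
  if (length(miss))
    stop("scenario references chromosome(s) absent from panel: ",
         paste(miss, collapse = ", "))
  if (!is.null(chrom_lengths)) {
    for (ch in names(scenario$events)) {
      ev <- scenario$events[[ch]]
      if (!is.null(ev$start) &&
          (ev$start < 1 || ev$end > chrom_lengths[[ch]] + 1))
        stop("event interval on chromosome ", ch, " outside chromosome bounds")
    }
  }
  if (proband_sex == "male") panel <- panel[panel$chrom != "X", , drop = FALSE]

  n <- nrow(panel)
  af <- panel$af
  on_x <- panel$chrom == "X"

  m_h1 <- stats::rbinom(n, 1, af); m_h2 <- stats::rbinom(n, 1, af)
  f_h1 <- stats::rbinom(n, 1, af); f_h2 <- stats::rbinom(n, 1, af)
  # father is hemizygous on X: a single allele reported as a homozygous call
  f_h2[on_x] <- f_h1[on_x]

  # consanguinity: at a fraction of sites both parents carry (and transmit)
  # one shared haplotype; such sites can never be informative
  force_shared <- rep(FALSE, n)
  for (ch in unique(panel$chrom)) {
    ev <- scenario_event(scenario, ch)
    if (ev$kind == "autozygous") {
      idx <- which(panel$chrom == ch)
      sel <- idx[stats::runif(length(idx)) < ev$fraction]
      a <- stats::rbinom(length(sel), 1, af[sel])
      m_h1[sel] <- a; f_h1[sel] <- a
      force_shared[sel] <- TRUE
    }
  }

  tm <- .pick_allele(m_h1, m_h2)
  tf <- .pick_allele(f_h1, f_h2)
  tf[on_x] <- f_h1[on_x]
  tm[force_shared] <- m_h1[force_shared]
  tf[force_shared] <- f_h1[force_shared]

  gm <- m_h1 + m_h2
  gf <- f_h1 + f_h2
  gp <- tm + tf
  depth_mult <- rep(1, n)
  truth <- list()

  add_truth <- function(chrom, event, parent, start, end, whole) {
    truth[[length(truth) + 1L]] <<- data.frame(
      proband = proband_id, chrom = chrom, event = event,
      parent = parent, start = start, end = end,
      whole_chromosome = whole, stringsAsFactors = FALSE)
  }
  chrom_end <- function(ch) {
    if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      unname(chrom_lengths[[ch]]) + 1
    else max(panel$pos[panel$chrom == ch]) + 1
  }

  for (ch in unique(panel$chrom)) {
    ev <- scenario_event(scenario, ch)
    idx <- which(panel$chrom == ch)
    kind <- ev$kind
    if (kind == "biparental") next
    if (kind == "autozygous") {
      add_truth(ch, "autozygous", NA_character_, 1, chrom_end(ch), TRUE)
      next
    }
    if (kind %in% c("upid_maternal", "upid_paternal")) {
      par <- if (kind == "upid_maternal") "mother" else "father"
      a <- if (par == "mother") .pick_allele(m_h1[idx], m_h2[idx])
           else .pick_allele(f_h1[idx], f_h2[idx])
      gp[idx] <- 2L * a
      add_truth(ch, "upid", par, 1, chrom_end(ch), TRUE)
    } else if (kind %in% c("uphd_maternal", "uphd_paternal")) {
      par <- if (kind == "uphd_maternal") "mother" else "father"
      gp[idx] <- if (par == "mother") gm[idx] else gf[idx]
      add_truth(ch, "uphd", par, 1, chrom_end(ch), TRUE)
    } else if (kind == "partial_upid") {
      seg <- idx[panel$pos[idx] >= ev$start & panel$pos[idx] < ev$end]
      a <- if (ev$parent == "mother") .pick_allele(m_h1[seg], m_h2[seg])
           else .pick_allele(f_h1[seg], f_h2[seg])
      gp[seg] <- 2L * a
      add_truth(ch, "partial_upid", ev$parent, ev$start, ev$end, FALSE)
    } else if (kind == "deletion") {
      seg <- idx[panel$pos[idx] >= ev$start & panel$pos[idx] < ev$end]
      a <- if (ev$inherited_from == "mother") .pick_allele(m_h1[seg], m_h2[seg])
           else .pick_allele(f_h1[seg], f_h2[seg])
      gp[seg] <- 2L * a            # hemizygous reported as homozygous diploid
      depth_mult[seg] <- 0.5
      add_truth(ch, "deletion", ev$inherited_from, ev$start, ev$end, FALSE)
    } else if (kind == "trisomy_like") {
      force <- idx[stats::runif(length(idx)) < scenario$trisomy_het_rate]
      gp[force] <- 1L
      add_truth(ch, "trisomy_like", NA_character_, 1, chrom_end(ch), TRUE)
    }
  }

  apply_errors <- function(g) {
    if (scenario$error_rate == 0) return(g)
    err <- which(stats::runif(n) < scenario$error_rate)
    g[err] <- (g[err] + sample.int(2L, length(err), replace = TRUE)) %% 3L
    g
  }
  gm <- apply_errors(gm); gf <- apply_errors(gf); gp <- apply_errors(gp)

  draw_depth <- function(mult = 1) {
    stats::rnbinom(n, size = scenario$depth_dispersion,
                   mu = scenario$mean_depth * mult)
  }
  draw_gq <- function() {
    gq <- rep(99L, n)
    fail <- stats::runif(n) < scenario$gq_fail_rate
    gq[fail] <- sample(0:14, sum(fail), replace = TRUE)
    gq
  }

  df <- data.frame(
    chrom = panel$chrom, pos = panel$pos, ref = panel$ref, alt = panel$alt,
    af = af,
    gt_mother = as.integer(gm), gt_father = as.integer(gf),
    gt_proband = as.integer(gp),
    dp_mother = draw_depth(), dp_father = draw_depth(),
    dp_proband = draw_depth(depth_mult),
    gq_mother = draw_gq(), gq_father = draw_gq(), gq_proband = draw_gq(),
    stringsAsFactors = FALSE)

  trio <- new_trio_genotypes(df, samples = sample_names,
                             proband_sex = proband_sex,
                             proband_id = proband_id,
                             chrom_lengths = chrom_lengths)
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(proband = character(), chrom = character(),
                           event = character(), parent = character(),
                           start = numeric(), end = numeric(),
                           whole_chromosome = logical(),
                           stringsAsFactors = FALSE)
  list(trio = trio, truth = truth)
}

# --- cohort -------------------------------------------------------------

#' Scenario set for a study-scale synthetic cohort
#'
#' Builds per-proband scenarios for a cohort of `n_trios` trios with the
#' event mix the screen is designed to resolve: one maternal chromosome-1
#' isodisomy, two paternal chromosome-2 isodisomies, one maternal
#' chromosome-15 heterodisomy, two multi-megabase hemizygous deletions
#' (chromosomes 4 and 14, half coverage), one trisomy-like chromosome 21,
#' and three genome-wide consanguineous probands; all remaining trios are
#' biparental. Sexes follow the study split (69 female / 95 male by default).
#'
#' @param n_trios Cohort size (>= 10 so all planted events fit).
#' @param n_female Number of female probands.
#' @param autozygous_fraction Autozygous genome fraction for the three
#'   consanguineous probands.
#' @param error_rate,mean_depth,depth_dispersion Noise model shared by all
#'   trios (see [sim_scenario()]).
#' @return A list with one element per proband: `id`, `sex`, `scenario`.
#' @export
cohort_scenarios <- function(n_trios = 164, n_female = 69,
                             autozygous_fraction = 0.25,
                             error_rate = 3e-4, mean_depth = 30,
                             depth_dispersion = 20) {
  stopifnot(n_trios >= 10, n_female >= 0, n_female <= n_trios)
  mk <- function(events = list(), default_event = "biparental") {
    sim_scenario(events = events, default_event = default_event,
                 error_rate = error_rate, mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion)
  }
  planted <- list(
    mk(list(`1` = "upid_maternal")),
    mk(list(`2` = "upid_paternal")),
    mk(list(`2` = "upid_paternal")),
    mk(list(`15` = "uphd_maternal")),
    mk(list(`4` = list(kind = "deletion", start = 50e6, end = 90e6,
                       inherited_from = "mother"))),
    mk(list(`14` = list(kind = "deletion", start = 30e6, end = 60e6,
                        inherited_from = "father"))),
    mk(list(`21` = "trisomy_like")),
    mk(default_event = list(kind = "autozygous",
                            fraction = autozygous_fraction)),
    mk(default_event = list(kind = "autozygous",
                            fraction = autozygous_fraction)),
    mk(default_event = list(kind = "autozygous",
                            fraction = autozygous_fraction))
  )
  sexes <- rep(c("female", "male"), c(n_female, n_trios - n_female))
  ids <- sprintf("P%03d", seq_len(n_trios))
  lapply(seq_len(n_trios), function(i) {
    list(id = ids[i], sex = sexes[i],
         scenario = if (i <= length(planted)) planted[[i]] else mk())
  })
}

#' Simulate a cohort of trios
#'
#' Simulates every trio of a scenario set over one shared site panel using a
#' single seeded random stream, so results are reproducible from
#' `(panel, cohort, seed)`.
#'
#' @param panel A [simulate_site_panel()] result.
#' @param cohort A list as returned by [cohort_scenarios()].
#' @param seed Optional integer seed.
#' @return A list with `trios` (named list of `trio_genotypes`) and `truth`
#'   (row-bound truth records of all trios).
#' @export
simulate_cohort <- function(panel, cohort = cohort_scenarios(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(cohort, function(spec) {
    simulate_trio(panel, spec$scenario, proband_sex = spec$sex,
                  proband_id = spec$id,
                  sample_names = c(mother = paste0(spec$id, "_M"),
                                   father = paste0(spec$id, "_F"),
                                   proband = spec$id))
  })
  trios <- lapply(sims, `[[`, "trio")
  names(trios) <- vapply(cohort, `[[`, "", "id")
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  rownames(truth) <- NULL
  list(trios = trios, truth = truth)
}
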