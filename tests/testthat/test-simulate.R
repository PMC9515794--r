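test_that("site panels respect counts, bounds, ordering and determinism", {
  lens <- grch38_lengths()
  p <- simulate_site_panel(1000, lens, seed = 7)
  expect_equal(nrow(p), 23000)
  expect_true(all(p$af >= 0.4 & p$af <= 0.6))
  expect_setequal(unique(p$chrom), c(as.character(1:22), "X"))
  for (ch in c("1", "X")) {
    pos <- p$pos[p$chrom == ch]
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos >= 1 & pos <= lens[[ch]]))
  }
  expect_true(all(nchar(p$ref) == 1 & nchar(p$alt) == 1 & p$ref != p$alt))

  expect_identical(simulate_site_panel(200, small_lengths(), seed = 3),
                   simulate_site_panel(200, small_lengths(), seed = 3))

  degenerate <- simulate_site_panel(50, small_lengths(), af_low = 0.5,
                                    af_high = 0.5, seed = 1)
  expect_true(all(degenerate$af == 0.5))

  expect_error(simulate_site_panel(100, c(`1` = 50), seed = 1),
               "shorter than")
})

test_that("isodisomy duplicates one parental haplotype", {
  panel <- simulate_site_panel(1500, small_lengths(), seed = 21)
  sim <- simulate_trio(panel, sim_scenario(list(`21` = "upid_maternal"),
                                           error_rate = 0, seed = 22))
  d <- sim$trio[sim$trio$chrom == "21", ]
  # one duplicated homolog: proband homozygous at every site
  expect_true(all(d$gt_proband %in% c(0L, 2L)))
  # where the mother is homozygous her only haplotype is transmitted
  hom <- d$gt_mother %in% c(0L, 2L)
  expect_true(all(d$gt_proband[hom] == d$gt_mother[hom]))
  expect_equal(sim$truth$event, "upid")
  expect_equal(sim$truth$parent, "mother")
  expect_true(sim$truth$whole_chromosome)
})

test_that("heterodisomy transmits both homologs of one parent", {
  panel <- simulate_site_panel(1500, small_lengths(), seed = 31)
  sim <- simulate_trio(panel, sim_scenario(list(`22` = "uphd_paternal"),
                                           error_rate = 0, seed = 32))
  d <- sim$trio[sim$trio$chrom == "22", ]
  expect_identical(d$gt_proband, d$gt_father)
  expect_equal(mean(d$gt_proband == 1L), mean(d$gt_father == 1L))
})

test_that("biparental chromosomes are Mendelian-consistent at error rate 0", {
  panel <- simulate_site_panel(1200, small_lengths(), seed = 41)
  sim <- simulate_trio(panel, sim_scenario(error_rate = 0, seed = 42))
  sc <- classify_site(sim$trio$gt_mother, sim$trio$gt_father,
                      sim$trio$gt_proband)
  expect_equal(sum(sc$mendelian_error, na.rm = TRUE), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("deletions give homozygous calls at half depth inside the interval", {
  panel <- simulate_site_panel(2000, small_lengths("21"), seed = 51)
  ev <- list(`21` = list(kind = "deletion", start = 10e6, end = 30e6,
                         inherited_from = "father"))
  sim <- simulate_trio(panel, sim_scenario(ev, error_rate = 0,
                                           mean_depth = 40, seed = 52))
  d <- sim$trio
  inside <- d$pos >= 10e6 & d$pos < 30e6
  expect_true(all(d$gt_proband[inside] %in% c(0L, 2L)))
  expect_lt(mean(d$dp_proband[inside]), 0.65 * mean(d$dp_proband[!inside]))
  expect_gt(mean(d$dp_proband[inside]), 0.35 * mean(d$dp_proband[!inside]))
  # parents keep full depth
  expect_gt(mean(d$dp_father[inside]), 0.85 * mean(d$dp_father[!inside]))
  expect_false(sim$truth$whole_chromosome)
  expect_equal(c(sim$truth$start, sim$truth$end), c(10e6, 30e6))
})

test_that("trisomy-like raises heterozygosity; autozygosity lowers it without skew", {
  panel <- simulate_site_panel(2000, small_lengths(), seed = 61)
  tri <- simulate_trio(panel, sim_scenario(list(`21` = "trisomy_like"),
                                           error_rate = 0, seed = 62))$trio
  het <- function(trio, ch) {
    g <- trio$gt_proband[trio$chrom == ch]
    mean(g == 1L, na.rm = TRUE)
  }
  expect_gt(het(tri, "21"), 0.70)
  expect_lt(het(tri, "22"), 0.60)

  aut <- simulate_trio(panel,
                       sim_scenario(default_event = list(kind = "autozygous",
                                                         fraction = 0.5),
                                    error_rate = 0, seed = 63))$trio
  bip <- simulate_trio(panel, sim_scenario(error_rate = 0, seed = 63))$trio
  expect_lt(het(aut, "21"), 0.75 * het(bip, "21"))
  # no uniparental skew: informative sites stay fully heterozygous
  st <- chromosome_stats(aut, "21")
  expect_equal(st$pct_ab, 100)
  expect_equal(st$skew, 0)
})

test_that("uniparental match at informative sites tolerates genotype error", {
  panel <- simulate_site_panel(2000, small_lengths("21"), seed = 71)
  for (e in c(0, 0.001)) {
    sim <- simulate_trio(panel, sim_scenario(list(`21` = "upid_paternal"),
                                             error_rate = e, seed = 72))
    st <- chromosome_stats(sim$trio, "21")
    # expected match >= 1 - 2e; allow 4 binomial SDs below that
    n <- st$n_informative
    lower <- (1 - 2 * e) - 4 * sqrt(2 * e / max(n, 1))
    expect_gte(st$pct_match_father / 100, min(lower, 1))
    if (e == 0) expect_equal(st$pct_match_father, 100)
  }
})

test_that("simulation is deterministic and validates its inputs", {
  panel <- simulate_site_panel(300, small_lengths(), seed = 81)
  sc <- sim_scenario(list(`21` = "upid_maternal"), seed = 82)
  expect_identical(simulate_trio(panel, sc), simulate_trio(panel, sc))

  expect_error(sim_scenario(list(`21` = "upid_mother")), "unknown event kind")
  expect_error(sim_scenario(list(`21` = list(kind = "deletion", start = 5,
                                             end = 1,
                                             inherited_from = "father"))),
               "start < end")
  expect_error(sim_scenario(list(`21` = "upid_maternal",
                                 `21` = "upid_paternal")),
               "one event per chromosome")
  expect_error(simulate_trio(panel, sim_scenario(list(`5` = "upid_maternal"))),
               "absent from panel")
  bad <- sim_scenario(list(`21` = list(kind = "deletion", start = 1,
                                       end = 99e6,
                                       inherited_from = "father")))
  expect_error(simulate_trio(panel, bad), "outside chromosome bounds")
})

test_that("male probands carry no X records; females do", {
  panel <- simulate_site_panel(100, grch38_lengths(c("22", "X")), seed = 91)
  male <- simulate_trio(panel, sim_scenario(seed = 92), proband_sex = "male")
  expect_false("X" %in% male$trio$chrom)
  female <- simulate_trio(panel, sim_scenario(seed = 92),
                          proband_sex = "female")
  expect_true("X" %in% female$trio$chrom)
  # father hemizygous on X: always reported homozygous
  x <- female$trio[female$trio$chrom == "X", ]
  expect_true(all(x$gt_father %in% c(0L, 2L)))
})
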