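test_that("a clean biparental chromosome yields no windows", {
  panel <- simulate_site_panel(1500, small_lengths("21"), seed = 201)
  sim <- simulate_trio(panel, sim_scenario(error_rate = 0, seed = 202))
  expect_equal(nrow(scan_partial(sim$trio, "21")), 0)
})

test_that("a planted multi-megabase isodisomic segment is recovered", {
  # dense panel so windows carry enough informative sites and errors
  panel <- simulate_site_panel(4000, small_lengths("21"), seed = 211)
  ev <- list(`21` = list(kind = "partial_upid", parent = "mother",
                         start = 20e6, end = 26e6))
  sim <- simulate_trio(panel, sim_scenario(ev, error_rate = 0, seed = 212))
  w <- scan_partial(sim$trio, "21", min_errors = 50)
  expect_gt(nrow(w), 0)
  merged <- merge_windows(w)
  hit <- any(mapply(overlaps, merged$start, merged$end, 20e6, 26e6))
  expect_true(hit)
  jac <- max(mapply(interval_jaccard, merged$start, merged$end, 20e6, 26e6))
  expect_gte(jac, 0.5)

  # the merged candidate resolves as partial UPD at full coverage
  reg <- resolve_region(merged[which.max(merged$end - merged$start), ],
                        sim$trio, genome_mean_depth = 30)
  expect_equal(reg$resolution, "partial_upd")
  expect_equal(reg$parent, "mother")
})

test_that("windows below the error threshold are not retained", {
  # 49 Mendelian errors in one window span: nothing at min_errors = 50
  pos <- seq(1e6, 1e6 + 48 * 1000, by = 1000)
  trio <- make_trio(gm = rep(0L, 49), gf = rep(2L, 49), gp = rep(0L, 49),
                    pos = pos)
  expect_equal(nrow(scan_partial(trio, "1", min_errors = 50)), 0)
  w <- scan_partial(trio, "1", min_errors = 49)
  expect_gt(nrow(w), 0)
  expect_equal(max(w$n_errors), 49)
})

test_that("the heterozygosity filter removes windows strictly above 10%", {
  # 50 errors and exactly 10% heterozygosity at informative sites: retained
  gm <- rep(0L, 60); gf <- rep(2L, 60)
  gp <- c(rep(0L, 54), rep(1L, 6))   # 6/60 = 10%
  trio <- make_trio(gm, gf, gp, pos = seq(1e6, by = 1000, length.out = 60))
  expect_gt(nrow(scan_partial(trio, "1", min_errors = 50,
                              het_max_pct = 10)), 0)
  # 7 hets -> 11.7% > 10%: removed
  gp2 <- c(rep(0L, 53), rep(1L, 7))
  trio2 <- make_trio(gm, gf, gp2, pos = seq(1e6, by = 1000, length.out = 60))
  expect_equal(nrow(scan_partial(trio2, "1", min_errors = 50,
                                 het_max_pct = 10)), 0)
})

test_that("scan equals exhaustive window evaluation on random instances", {
  set.seed(221)
  for (rep in 1:12) {
    n <- sample(200:1500, 1)
    trio <- random_trio(n, chrom_len = n * sample(500:3000, 1),
                        p_missing = 0.05)
    W <- sample(c(1e5, 5e5, 2e6), 1)
    me <- sample(2:8, 1)
    hm <- sample(c(10, 30, 60), 1)
    got <- scan_partial(trio, "1", window_size = W, min_errors = me,
                        het_max_pct = hm)
    want <- oracle_scan(trio, "1", W, me, hm)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$n_errors, want$n_errors)
    expect_equal(got$pct_het, want$pct_het)
  }
})

test_that("raising min_errors or lowering het_max_pct never adds windows", {
  set.seed(231)
  trio <- random_trio(800, chrom_len = 4e8, p_missing = 0.05)
  base <- scan_partial(trio, "1", window_size = 2e6, min_errors = 3,
                       het_max_pct = 60)
  harder <- scan_partial(trio, "1", window_size = 2e6, min_errors = 6,
                         het_max_pct = 60)
  expect_true(all(harder$start %in% base$start))
  stricter <- scan_partial(trio, "1", window_size = 2e6, min_errors = 3,
                           het_max_pct = 30)
  expect_true(all(stricter$start %in% base$start))
  expect_lte(nrow(harder), nrow(base))
  expect_lte(nrow(stricter), nrow(base))
})

test_that("interval merging matches the union-of-points oracle", {
  # overlap unions
  m <- merge_windows(data.frame(start = c(100, 2e6), end = c(5000100, 7e6)))
  expect_equal(m$start, 100)
  expect_equal(m$end, 7e6)
  # disjoint intervals stay put
  m2 <- merge_windows(data.frame(start = c(0, 20), end = c(10, 30)))
  expect_equal(nrow(m2), 2)
  # abutting half-open intervals merge; gap of one position does not
  m3 <- merge_windows(data.frame(start = c(10, 20), end = c(20, 30)))
  expect_equal(nrow(m3), 1)
  m4 <- merge_windows(data.frame(start = c(10, 21), end = c(20, 30)))
  expect_equal(nrow(m4), 2)

  set.seed(241)
  for (rep in 1:25) {
    k <- sample(1:12, 1)
    s <- sample(1:80, k, replace = TRUE)
    e <- s + sample(1:20, k, replace = TRUE)
    got <- merge_windows(data.frame(start = s, end = e))
    want <- oracle_merge(s, e)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # idempotence
    expect_equal(merge_windows(got)[c("start", "end")],
                 got[c("start", "end")])
  }
})

test_that("coverage ratio separates deletions from partial UPD, strictly", {
  mk <- function(dp) {
    make_trio(gm = rep(0L, 20), gf = rep(2L, 20), gp = rep(0L, 20),
              pos = seq(1e6, by = 1000, length.out = 20), dp_proband = dp)
  }
  region <- list(chrom = "1", start = 1e6, end = 2e6)
  expect_equal(resolve_region(region, mk(15), 30)$resolution, "deletion")
  expect_equal(resolve_region(region, mk(30), 30)$resolution, "partial_upd")
  # ratio exactly 0.9 is not "> 0.9"
  expect_equal(resolve_region(region, mk(27), 30)$resolution, "deletion")
  expect_equal(resolve_region(region, mk(27.1), 30)$resolution,
               "partial_upd")
  r <- resolve_region(region, mk(15), 30)
  expect_equal(r$coverage_ratio, 0.5)
  expect_equal(r$parent, "mother")
  expect_equal(r$n_mendelian_errors, 20)

  empty <- mk(NA_real_)
  expect_error(resolve_region(region, empty, 30), "no proband depth")
})
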