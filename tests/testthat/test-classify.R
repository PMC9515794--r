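# Build a stats row directly so threshold logic is tested in isolation.
make_stats <- function(skew = 0, pct_het = 49, pct_ab = 100 - skew,
                       chrom = "1", n_informative = 500,
                       n_nonmissing = 2000, mother_leads = TRUE) {
  mm <- if (mother_leads) skew else 100 - pct_ab - skew
  mf <- if (mother_leads) 100 - pct_ab - skew else skew
  data.frame(chrom = chrom, n_nonmissing = n_nonmissing,
             n_het = round(n_nonmissing * pct_het / 100), pct_het = pct_het,
             n_informative = n_informative,
             n_ab = round(n_informative * pct_ab / 100), pct_ab = pct_ab,
             n_match_mother = round(n_informative * mm / 100),
             n_match_father = round(n_informative * mf / 100),
             pct_match_mother = mm, pct_match_father = mf,
             skew = max(mm, mf), n_mendelian_errors = 0,
             stringsAsFactors = FALSE)
}

test_that("whole-chromosome calls follow the skew and heterozygosity rules", {
  th <- classify_thresholds()
  # the isodisomy fingerprint: extreme skew, collapsed heterozygosity
  c1 <- classify_chromosome(make_stats(skew = 99.97, pct_het = 0.1,
                                       pct_ab = 0.03), th)
  expect_equal(c1$call, "upid")
  expect_equal(c1$parent, "mother")

  # paternal direction
  c2 <- classify_chromosome(make_stats(skew = 99.99, pct_het = 0.1,
                                       pct_ab = 0.01,
                                       mother_leads = FALSE), th)
  expect_equal(c2$call, "upid")
  expect_equal(c2$parent, "father")

  # heterodisomy: skewed but heterozygosity preserved
  c3 <- classify_chromosome(make_stats(skew = 95, pct_het = 35, pct_ab = 5),
                            th)
  expect_equal(c3$call, "uphd")

  # typical biparental values
  c4 <- classify_chromosome(make_stats(skew = 50, pct_het = 48,
                                       pct_ab = 50), th)
  expect_equal(c4$call, "none")
  expect_equal(c4$parent, "not_applicable")

  # skewed with intermediate heterozygosity: declared ambiguous, not forced
  c5 <- classify_chromosome(make_stats(skew = 95, pct_het = 20, pct_ab = 5),
                            th)
  expect_equal(c5$call, "ambiguous_skewed")
  expect_equal(c5$parent, "mother")
})

test_that("classification thresholds are strict at their boundaries", {
  th <- classify_thresholds()
  # skew exactly 90 is not "> 90"
  expect_equal(classify_chromosome(make_stats(skew = 90, pct_het = 1,
                                              pct_ab = 10), th)$call, "none")
  expect_equal(classify_chromosome(make_stats(skew = 90.01, pct_het = 1,
                                              pct_ab = 9.99), th)$call,
               "upid")
  # heterozygosity exactly 10 is not "< 10"; exactly 30 is not "> 30"
  expect_equal(classify_chromosome(make_stats(skew = 99, pct_het = 10,
                                              pct_ab = 1), th)$call,
               "ambiguous_skewed")
  expect_equal(classify_chromosome(make_stats(skew = 99, pct_het = 30,
                                              pct_ab = 1), th)$call,
               "ambiguous_skewed")
  expect_equal(classify_chromosome(make_stats(skew = 99, pct_het = 30.01,
                                              pct_ab = 1), th)$call, "uphd")
})

test_that("sparse chromosomes and the male X are insufficient data", {
  th <- classify_thresholds()
  expect_equal(classify_chromosome(make_stats(skew = 99, pct_het = 1,
                                              pct_ab = 1,
                                              n_informative = 50), th)$call,
               "insufficient_data")
  expect_equal(classify_chromosome(make_stats(n_nonmissing = 500), th)$call,
               "insufficient_data")
  x <- make_stats(skew = 99, pct_het = 1, pct_ab = 1, chrom = "X")
  expect_equal(classify_chromosome(x, th, proband_sex = "male")$call,
               "insufficient_data")
  expect_equal(classify_chromosome(x, th, proband_sex = "female")$call,
               "upid")
})

test_that("heterozygosity excess without skew is flagged, advisory only", {
  th <- classify_thresholds()
  tri <- classify_chromosome(make_stats(skew = 0, pct_het = 85,
                                        pct_ab = 100), th)
  expect_equal(tri$call, "het_excess_flag")
  expect_equal(tri$parent, "not_applicable")
  # below the advisory bound: nothing
  expect_equal(classify_chromosome(make_stats(skew = 0, pct_het = 55,
                                              pct_ab = 100), th)$call,
               "none")
})

test_that("threshold constructors reject inconsistent settings", {
  expect_error(classify_thresholds(upid_het_max = 40, uphd_het_min = 30))
  expect_error(classify_thresholds(skew_min = 40))
  expect_error(filter_config(depth_min = 50, depth_max = 10))
  expect_error(filter_config(maf_min = 0.7))
})
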