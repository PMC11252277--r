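test_that("richness counts positive entries only", {
  expect_equal(richness(c(1, 0, 3)), 2)
  expect_equal(richness(c(0, 0)), 0)
  expect_error(richness(c(-1, 2)), "non-negative")
})

test_that("Shannon index matches closed forms and is scale/permutation invariant", {
  expect_equal(shannon(c(5, 5)), log(2))
  expect_equal(shannon(c(7)), 0)
  expect_equal(shannon(c(0, 3, 0)), 0)
  expect_error(shannon(c(0, 0)), "all-zero")
  set.seed(21)
  for (i in 1:20) {
    x <- rlnorm(sample(2:30, 1))
    expect_equal(shannon(3.7 * x), shannon(x), tolerance = 1e-12)
    expect_equal(shannon(sample(x)), shannon(x), tolerance = 1e-12)
    expect_lte(shannon(x), log(length(x)) + 1e-12)
    expect_gte(shannon(x), 0)
  }
})

test_that("occurrence frequency is the fraction of occupied samples", {
  m <- community_matrix(matrix(c(1, 0, 2, 0, 0, 0, 5, 5, 5), 3, 3,
                               dimnames = list(paste0("s", 1:3),
                                               c("ta", "tb", "tc"))))
  f <- occurrence_frequency(m)
  expect_equal(unname(f), c(2 / 3, 0, 1))
  expect_error(occurrence_frequency(m, "zz"), "unknown")
})

test_that("dominance multiplies share by frequency with an inclusive threshold", {
  # two samples engineered so ta has share 0.04, frequency 0.5
  m <- community_matrix(matrix(c(8, 0, 96, 96), 2, 2,
                               dimnames = list(c("s1", "s2"), c("ta", "tb"))))
  d <- dominance(m)
  ta <- d[d$taxon_id == "ta", ]
  expect_equal(ta$relative_abundance, 0.04)
  expect_equal(ta$occurrence_frequency, 0.5)
  expect_equal(ta$dominance, 0.02)
  expect_true(ta$is_dominant)  # boundary inclusive
  expect_true(all(d$dominance <= d$relative_abundance + 1e-12))
  expect_equal(sum(d$relative_abundance), 1)
  m2 <- community_matrix(matrix(c(1, 1, 99, 99), 2, 2,
                                dimnames = list(c("s1", "s2"),
                                                c("ta", "tb"))))
  expect_false(dominance(m2)[2, "is_dominant"])  # share 0.01, f = 1
})

test_that("the most dominant fixture species is dominant at every site", {
  sm <- load_study_fixture("table4_site_means")$abundance
  d <- dominance(sm)
  top <- d[1, ]
  expect_equal(top$taxon_id, "paradileptus_elephantinus")
  expect_equal(top$occurrence_frequency, 1)
  expect_equal(top$relative_abundance, 0.195, tolerance = 0.01)
  expect_true(top$is_dominant)
})

test_that("group shares aggregate and sum to 100 percent", {
  reg <- trait_registry(c("ta", "tb", "tc"),
                        phylum = c("Ciliophora", "Ciliophora", "Heliozoa"))
  m <- community_matrix(matrix(c(10, 10, 30, 30, 20, 0), 2, 3,
                               dimnames = list(c("s1", "s2"),
                                               c("ta", "tb", "tc"))))
  gs <- group_shares(m, reg)
  expect_equal(sum(gs$percent), 100)
  expect_equal(gs$total[gs$group == "Ciliophora"], 80)
  single <- group_shares(m[, 1, drop = FALSE], reg)
  expect_equal(single$percent, 100)
})

test_that("grouped summaries use mean and n-1 standard deviation", {
  m <- community_matrix(
    matrix(c(600, 700, 400, 400, 500, 200), 3, 2,
           dimnames = list(paste0("s", 1:3), c("ta", "tb"))),
    sample_info = data.frame(sample_id = paste0("s", 1:3),
                             site = c("A", "A", "B"), month = 1:3))
  out <- summarize_by_factor(m, "site")
  a <- out[out$level == "A", ]
  expect_equal(a$mean_total, 1100)       # totals 1000 and 1200
  expect_equal(a$sd_total, sd(c(1000, 1200)))
  expect_equal(a$sd_total, 141.42, tolerance = 1e-4)
  expect_equal(out[out$level == "B", "sd_total"], NA_real_)
  expect_error(summarize_by_factor(m, "season"), "season")
})
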