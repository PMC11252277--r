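test_that("identical configs give identical campaigns", {
  c1 <- generate_campaign(campaign_config(seed = 17))
  c2 <- generate_campaign(campaign_config(seed = 17))
  expect_identical(c1$community, c2$community)
  expect_identical(c1$environment, c2$environment)
  expect_identical(c1$registry, c2$registry)
  c3 <- generate_campaign(campaign_config(seed = 18))
  expect_false(identical(unclass(c1$community), unclass(c3$community)))
})

test_that("the default campaign matches the configured design", {
  camp <- generate_campaign(campaign_config(seed = 4))
  expect_equal(dim(camp$community), c(72, 54))
  mix <- campaign_config(seed = 1)$phylum_mix
  counts <- table(camp$registry$phylum)[names(mix)]
  expect_equal(as.integer(counts), unname(mix))
  si <- sample_info(camp$community)
  expect_equal(length(unique(si$site)), 6)
  expect_equal(length(unique(si$month)), 12)
  expect_false(anyDuplicated(si[, c("site", "month")]) > 0)
  # generated output passes the data-model round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_community_matrix(camp$community, f)
  bare <- function(x) matrix(as.numeric(x), nrow(x), dimnames = dimnames(x))
  expect_equal(bare(read_community_matrix(f)), bare(camp$community))
  expect_error(campaign_config(), "seed")
  expect_error(campaign_config(seed = 1, n_species = 10), "phylum_mix")
})

test_that("count sheets invert the enumeration formula up to Poisson error", {
  camp <- generate_campaign(campaign_config(seed = 9))
  target <- camp$community[1:6, 1:10]
  sheet <- generate_count_sheets(target, seed = 1)
  expect_true(all(sheet$C[rep(unclass(target) == 0, 1)] == 0))
  back <- enumerate_count_sheet(sheet)
  back <- back[rownames(target), colnames(target)]
  nz <- unclass(target) > 1000   # cells with expected chamber count >= ~5
  if (any(nz)) {
    rel <- unclass(back)[nz] / unclass(target)[nz]
    expect_gt(cor(unclass(back)[nz], unclass(target)[nz]), 0.9)
    expect_equal(mean(rel), 1, tolerance = 0.25)
  }
  # doubling V_C halves the expected chamber count for a fixed concentration
  s1 <- generate_count_sheets(target, chamber = list(N = 100, V_C = 50,
                                                     V_T = 1000,
                                                     total_squares = 1000),
                              seed = 2)
  s2 <- generate_count_sheets(target, chamber = list(N = 100, V_C = 100,
                                                     V_T = 1000,
                                                     total_squares = 1000),
                              seed = 2)
  expect_gt(sum(s1$C), sum(s2$C) * 1.5)
})

test_that("a null campaign shows no saprobity-gradient association", {
  rhos <- vapply(1:20, function(i) {
    cfg <- campaign_config(seed = 300 + i, gradient = rep(0, 6),
                           seasonal_amplitude = 0)
    camp <- generate_campaign(cfg)
    sap <- campaign_saprobity(camp$community, camp$registry,
                              group_by = "site")
    # score against the gradient the default design would have planted
    cor(sap$SI, seq(0, 1, length.out = 6)[match(sap$group,
                                                c("I", "II", "III",
                                                  "IV", "V", "VI"))],
        method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.25)  # centred on zero
})

test_that("recovery suite scores a strong-gradient campaign as recovered", {
  camp <- generate_campaign(campaign_config(seed = 23))
  rec <- recovery_suite(camp, k_max = 2)
  expect_gt(rec$si_gradient_rho, 0.8)
  expect_true(is.logical(rec$bioenv_hit))
  expect_gte(rec$dominance_recall, 0.5)
  expect_true(all(c("saprobity", "bioenv", "dominance") %in% names(rec)))
})
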