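test_that("valence resolution follows the midpoint scale and refuses unknowns", {
  tab <- default_valence_table()
  expect_equal(resolve_valence("b", tab), 2.0)
  expect_equal(resolve_valence("a-b", tab), 2.5)
  expect_equal(resolve_valence(c("o", "o-b", "a", "p", "o-a"), tab),
               c(1.0, 1.5, 3.0, 4.0, 2.0))
  expect_error(resolve_valence("x", tab), "not in valence table")
  expect_error(resolve_valence("", tab), "empty")
})

test_that("the saprobic index is the abundance-weighted mean valence", {
  expect_equal(saprobic_index(c(3, 99, 17), rep(2, 3)), 2)
  expect_equal(saprobic_index(c(5, 5), c(1, 3)), 2)
  expect_equal(saprobic_index(c(10, 30), c(1, 3)), 2.5)
  expect_error(saprobic_index(c(0, 0), c(1, 3)), "zero classified")
  expect_error(saprobic_index(1:3, 1:2), "equal length")
})

test_that("SI is scale-invariant and bounded by contributing valences", {
  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:12, 1)
    h <- rlnorm(k); S <- sample(seq(1, 4, 0.5), k, replace = TRUE)
    si <- saprobic_index(h, S)
    expect_equal(saprobic_index(h * 10, S), si, tolerance = 1e-12)
    expect_gte(si, min(S)); expect_lte(si, max(S))
    # adding abundance to a taxon above the current index pulls it up
    j <- which.max(S)
    if (S[j] > si + 1e-9) {
      h2 <- h; h2[j] <- h2[j] + 1
      expect_gt(saprobic_index(h2, S), si)
    }
  }
})

test_that("classification reproduces the seven-band table with inclusive lower bounds", {
  tab <- default_valence_table()
  expect_equal(nrow(tab$class_bands), 7)
  expect_equal(tab$class_bands$lower[1], 1.0)
  expect_equal(tab$class_bands$class,
               c("I", "I-II", "II", "II-III", "III", "III-IV", "IV"))
  got <- classify_saprobic(2.92, tab)
  expect_equal(got$level, "a-Mesosaprobic")
  expect_equal(got$degree, "Waters strongly polluted")
  expect_equal(got$class, "III")
  expect_equal(classify_saprobic(1.0, tab)$class, "I")
  expect_equal(classify_saprobic(1.0, tab)$degree, "Non-polluted")
  expect_equal(classify_saprobic(2.3, tab)$class, "II-III")  # lower inclusive
  # every band boundary lands in its own band, upper bound in the next
  for (i in seq_len(7)) {
    b <- tab$class_bands[i, ]
    expect_equal(classify_saprobic(b$lower, tab)$class, b$class)
    expect_equal(classify_saprobic(b$upper - 1e-9, tab)$class, b$class)
  }
  expect_error(classify_saprobic(4.5, tab), "outside")
  expect_error(classify_saprobic(0.9, tab), "outside")
})

test_that("campaign assessment groups correctly and reports coverage", {
  reg <- trait_registry(c("ta", "tb", "tc"),
                        saprobity_code = c("b", "b", NA))
  m <- community_matrix(
    matrix(c(10, 20, 5, 10, 100, 100), 2, 3,
           dimnames = list(c("s1", "s2"), c("ta", "tb", "tc"))),
    sample_info = data.frame(sample_id = c("s1", "s2"),
                             site = c("A", "B"), month = 1:2))
  out <- campaign_saprobity(m, reg, group_by = "site")
  expect_equal(out$SI, c(2, 2))  # only "b" taxa contribute
  expect_equal(out$class, c("II", "II"))
  expect_equal(out$n_classified_taxa, c(2, 2))
  expect_equal(out$classified_fraction, c(15 / 115, 30 / 130))
  # uniform abundance scaling leaves every SI unchanged
  m10 <- community_matrix(unclass(m) * 10, sample_info = sample_info(m))
  expect_equal(campaign_saprobity(m10, reg, group_by = "site")$SI, out$SI)
  reg0 <- trait_registry(c("ta", "tb", "tc"))
  expect_error(campaign_saprobity(m, reg0), "saprobity code")
})
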