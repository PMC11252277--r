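test_that("sqrt transform flags itself and refuses a double transform", {
  m <- community_matrix(matrix(c(0, 4, 9, 16), 2, 2,
                               dimnames = list(c("s1", "s2"), c("ta", "tb"))))
  s <- sqrt_transform(m)
  expect_equal(unname(unclass(s)[1, ]), c(0, 3))
  expect_true(attr(s, "sqrt_transformed"))
  expect_error(sqrt_transform(s), "already")
  expect_error(sqrt_transform(matrix(-1)), "negative")
})

test_that("distance metrics match hand values and satisfy metric invariants", {
  x <- rbind(a = c(0, 3), b = c(4, 0))
  expect_equal(as.numeric(distance_matrix(x, "euclidean")), 5)
  y <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.numeric(distance_matrix(y, "bray-curtis")), 1)
  z <- rbind(a = c(2, 5), b = c(2, 5), c = c(1, 1))
  expect_equal(as.matrix(distance_matrix(z, "euclidean"))["a", "b"], 0)
  set.seed(8)
  r <- matrix(rlnorm(40), 8, 5)
  for (met in c("euclidean", "bray-curtis", "normalized-euclidean")) {
    d <- as.matrix(distance_matrix(r, met))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    if (met == "bray-curtis") expect_true(all(d >= 0 & d <= 1))
  }
  # double-zero pair under bray-curtis is defined as 0 and flagged
  rz <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  dz <- distance_matrix(rz, "bray-curtis")
  expect_equal(as.matrix(dz)["a", "b"], 0)
  expect_equal(attr(dz, "zero_pairs"), 1)
})

test_that("Ward clustering reproduces an exhaustive-agglomeration oracle", {
  set.seed(99)
  # three collinear points: the close pair merges first
  hc0 <- ward_cluster(distance_matrix(cbind(c(0, 1, 10))))
  expect_equal(sort(hc0$merge[1, ]), c(-2, -1))
  p2 <- cutree(ward_cluster(distance_matrix(rbind(c(1, 1), c(1, 1)))), k = 1)
  expect_equal(unname(p2), c(1, 1))
  for (trial in 1:60) {
    n <- sample(4:7, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    hc <- ward_cluster(distance_matrix(X))
    expect_true(all(diff(hc$height) >= -1e-9))  # no inversions
    oracle <- ward_oracle_partitions(X)
    for (k in 2:(n - 1))
      expect_true(same_partition(cutree(hc, k = k), oracle[[k]]))
  }
})

test_that("similarity cuts span the whole partition range", {
  set.seed(5)
  X <- matrix(rnorm(24), 8, 3)
  hc <- ward_cluster(distance_matrix(X))
  expect_equal(length(unique(cut_at_similarity(hc, 0))), 1)
  expect_equal(length(unique(cut_at_similarity(hc, 100))), 8)
  k50 <- length(unique(cut_at_similarity(hc, 50)))
  expect_gte(k50, 1); expect_lte(k50, 8)
  expect_error(cut_at_similarity(hc, 120), "similarity_pct")
})

test_that("newick export contains every label and balanced parentheses", {
  X <- matrix(rnorm(15), 5, 3,
              dimnames = list(paste0("t", 1:5), NULL))
  hc <- ward_cluster(distance_matrix(X))
  nw <- dendrogram_newick(hc)
  expect_true(all(vapply(paste0("t", 1:5), grepl, TRUE, x = nw)))
  expect_equal(lengths(regmatches(nw, gregexpr("\\(", nw))),
               lengths(regmatches(nw, gregexpr("\\)", nw))))
})

test_that("spearman screen matches direct rank correlation", {
  set.seed(12)
  idx <- data.frame(H = c(3, 1, 4, 1, 5))
  env <- cbind(same = c(3, 1, 4, 1, 5), rev = -c(3, 1, 4, 1, 5),
               other = c(2, 7, 1, 8, 3))
  out <- spearman_screen(idx, env)
  expect_equal(out$rho["H", "same"], 1)
  expect_equal(out$rho["H", "rev"], -1)
  expect_equal(out$rho["H", "other"],
               cor(rank(idx$H), rank(env[, "other"])))
  envc <- cbind(env, flat = rep(1, 5))
  outc <- spearman_screen(idx, envc)
  expect_true("flat" %in% outc$constant)
  expect_true(is.na(outc$rho["H", "flat"]))
})

test_that("relate recovers identity, matches the exhaustive oracle, and agrees with vegan", {
  set.seed(77)
  X <- matrix(rnorm(18), 6, 3)
  d <- distance_matrix(X)
  ident <- relate(d, d, n_perm = 199, seed = 1)
  expect_equal(ident$rho, 1)
  expect_lte(ident$p_value, 0.05)
  # 4-label instance: exhaustive enumeration equals the brute-force oracle
  X4 <- matrix(rnorm(8), 4, 2); Y4 <- matrix(rnorm(8), 4, 2)
  d1 <- distance_matrix(X4); d2 <- distance_matrix(Y4)
  mine <- relate(d1, d2, exhaustive = TRUE)
  oracle <- relate_exhaustive_oracle(d1, d2)
  expect_equal(mine$rho, oracle$rho)
  expect_equal(mine$p_value, oracle$p)
  expect_equal(mine$n_permutations, 24)
  # Monte Carlo p approaches the exact p
  mc <- relate(d1, d2, n_perm = 999, seed = 42)
  expect_lt(abs(mc$p_value - oracle$p), 0.06)
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(d1, d2, method = "spearman", permutations = 99)
  expect_equal(mine$rho, unname(vg$statistic), tolerance = 1e-10)
})

test_that("bioenv reduces to the best single variable and finds a planted driver", {
  set.seed(101)
  n <- 20
  grad <- seq(0, 2, length.out = n)
  comm <- community_matrix(
    matrix(rlnorm(n * 8, meanlog = outer(grad, seq(-1, 1, length.out = 8)),
                  sdlog = 0.1), n, 8,
           dimnames = list(paste0("s", 1:n), paste0("t", 1:8))))
  env <- environment_matrix(
    cbind(driver = grad + rnorm(n, 0, 0.01),
          noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n)))
  rownames(env) <- paste0("s", 1:n)
  env <- environment_matrix(unclass(env))
  res1 <- bioenv(comm, env, k_max = 1)
  # k_max = 1 equals the best single-variable rho by construction
  singles <- vapply(colnames(env), function(v) {
    de <- dist(scale(unclass(env))[, v, drop = FALSE])
    db <- distance_matrix(sqrt_transform(comm), "bray-curtis")
    cor(rank(as.vector(as.dist(de))), rank(as.vector(db)))
  }, numeric(1))
  expect_equal(res1$best$rho[1], max(singles), tolerance = 1e-10)
  res <- bioenv(comm, env, k_max = 3)
  expect_equal(res$n_subsets, choose(4, 1) + choose(4, 2) + choose(4, 3))
  expect_true(grepl("driver", res$best$variables[1]))
  expect_gt(res$best$rho[1], 0.8)
  # best rho is monotone non-decreasing in k_max
  expect_true(all(diff(vapply(1:3, function(k)
    max(bioenv(comm, env, k_max = k)$best$rho), numeric(1))) >= -1e-12))
  # 8 variables at k_max = 8 enumerate all 255 nonempty subsets
  env8 <- environment_matrix(matrix(rnorm(n * 8), n,
                                    dimnames = list(paste0("s", 1:n),
                                                    paste0("v", 1:8))))
  expect_equal(bioenv(comm, env8, k_max = 8)$n_subsets, 255)
  skip_if_not_installed("vegan")
  vb <- vegan::bioenv(sqrt(unclass(comm)), as.data.frame(scale(unclass(env))),
                      method = "spearman", index = "bray", upto = 3)
  # compare the achieved best correlations
  expect_equal(max(vapply(vb$models, `[[`, 0, "est")), res$best$rho[1],
               tolerance = 1e-6)
})
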