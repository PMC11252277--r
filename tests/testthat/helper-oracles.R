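# Independent brute-force oracles used to validate the implementation.

# Exhaustive Ward agglomeration: at every step merge the pair of clusters
# whose union minimises the increase in total within-cluster sum of squares.
# Returns the membership vector at every cluster count k = n..1.
ward_oracle_partitions <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  wss <- function(idx) {
    if (length(idx) == 1) return(0)
    sub <- X[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  parts <- list(seq_len(n))
  membership <- function(clusters) {
    m <- integer(n)
    for (ci in seq_along(clusters)) m[clusters[[ci]]] <- ci
    m
  }
  parts <- list()
  parts[[n]] <- membership(clusters)
  while (length(clusters) > 1) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        cost <- wss(c(clusters[[i]], clusters[[j]])) -
          wss(clusters[[i]]) - wss(clusters[[j]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    parts[[length(clusters)]] <- membership(clusters)
  }
  parts
}

# TRUE when two membership vectors describe the same set partition.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(factor(a, levels = unique(a))),
              as.integer(factor(b, levels = unique(b))))
}

# Exhaustive permutation p-value for the rank matrix correlation.
relate_exhaustive_oracle <- function(d_bio, d_env) {
  mb <- as.matrix(d_bio); me <- as.matrix(d_env)
  n <- nrow(mb)
  ut <- upper.tri(mb)
  rb <- rank(mb[ut])
  obs <- stats::cor(rb, rank(me[ut]))
  perms <- rbind(1)
  idx <- seq_len(n)
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in all_perms(v[-k]))
        out[[length(out) + 1]] <- c(v[k], rest)
    out
  }
  stat <- vapply(all_perms(idx), function(p) {
    pm <- me[p, p]
    stats::cor(rb, rank(pm[ut]))
  }, numeric(1))
  list(rho = obs, p = mean(stat >= obs - 1e-12))
}

# Tiny labelled community matrix used across tests.
toy_community <- function() {
  m <- matrix(c(10, 0, 5,
                20, 2, 0,
                30, 4, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("ta", "tb", "tc")))
  community_matrix(m, sample_info = data.frame(
    sample_id = c("s1", "s2", "s3"), site = c("I", "I", "II"),
    month = 1:3, stringsAsFactors = FALSE))
}
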