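# Square-root transform, dissimilarities, Ward clustering with
# similarity-level cuts, Spearman screens, RELATE and BIOENV.

#' Square-root transform of an abundance matrix
#'
#' Standard variance-stabilising pre-treatment before community
#' dissimilarities; damps the influence of very abundant taxa. The result
#' carries a `sqrt_transformed` flag and transforming twice is refused (a
#' double transform is almost always an accident).
#'
#' @param mat a [community_matrix()] (or plain non-negative matrix).
#' @return the element-wise square root with the flag set.
#' @export
sqrt_transform <- function(mat) {
  if (isTRUE(attr(mat, "sqrt_transformed")))
    stop("matrix is already sqrt-transformed")
  if (any(mat < 0)) stop("negative entries cannot be sqrt-transformed")
  out <- sqrt(unclass(mat))
  if (inherits(mat, "community_matrix")) {
    out <- community_matrix(out, sample_info = sample_info(mat),
                            units = attr(mat, "units"))
  }
  attr(out, "sqrt_transformed") <- TRUE
  out
}

#' Pairwise distance matrix between sample rows
#'
#' @param x numeric matrix, rows are samples.
#' @param metric one of:
#'   \describe{
#'     \item{`"euclidean"`}{ordinary Euclidean distance;}
#'     \item{`"bray-curtis"`}{\eqn{\sum |x-y| / \sum (x+y)} per pair, in
#'       `[0, 1]`; a pair of all-zero rows is defined as distance 0 and
#'       flagged via the `zero_pairs` attribute;}
#'     \item{`"normalized-euclidean"`}{Euclidean distance after centring
#'       each variable to zero mean and scaling to unit (n-1) standard
#'       deviation.}
#'   }
#' @return a `stats::dist` object with a `metric` attribute.
#' @export
distance_matrix <- function(x, metric = c("euclidean", "bray-curtis",
                                          "normalized-euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(unclass(x))
  d <- switch(metric,
    "euclidean" = stats::dist(x),
    "normalized-euclidean" = {
      sds <- apply(x, 2, stats::sd)
      if (any(is.na(sds)) || any(sds == 0))
        stop("constant variable(s): ",
             paste(colnames(x)[is.na(sds) | sds == 0], collapse = ", "))
      stats::dist(scale(x))
    },
    "bray-curtis" = {
      if (any(x < 0)) stop("bray-curtis requires non-negative data")
      n <- nrow(x)
      num <- stats::dist(x, method = "manhattan")
      rs <- rowSums(x)
      den <- as.dist(outer(rs, rs, `+`))
      zero <- den == 0
      den[zero] <- 1
      d <- num / den
      d[zero] <- 0
      attr(d, "zero_pairs") <- sum(zero)
      d
    })
  attr(d, "metric") <- metric
  d
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering under the Ward minimum-variance criterion
#' (Lance-Williams implementation acting on Euclidean distances, without
#' pre-squaring). On Euclidean input the merge heights are non-decreasing.
#'
#' @param d a `dist` from [distance_matrix()] (Euclidean-compatible).
#' @return an `hclust` object.
#' @export
ward_cluster <- function(d) {
  if (!inherits(d, "dist")) stop("d must be a 'dist' object")
  if (attr(d, "Size") < 2) stop("need at least 2 items to cluster")
  stats::hclust(d, method = "ward.D2")
}

#' Cut a dendrogram at a similarity level
#'
#' Similarity of a merge height `h` is defined against the final merge:
#' `100 * (1 - h / h_max)`. Cutting at `similarity_pct` returns the
#' partition obtained by removing all merges with similarity strictly below
#' the cut; `0` gives a single group, `100` gives singletons.
#'
#' @param hc an `hclust` from [ward_cluster()].
#' @param similarity_pct percentage in `[0, 100]`.
#' @return named integer vector of group memberships (cluster ids ordered
#'   by first appearance of their members).
#' @export
cut_at_similarity <- function(hc, similarity_pct) {
  if (!inherits(hc, "hclust")) stop("hc must be an 'hclust' object")
  if (similarity_pct < 0 || similarity_pct > 100)
    stop("similarity_pct must be in [0, 100]")
  h_max <- max(hc$height)
  h_cut <- (1 - similarity_pct / 100) * h_max
  if (similarity_pct == 100) return(stats::cutree(hc, k = length(hc$order)))
  # keep merges with height <= h_cut (similarity >= cut)
  k <- sum(hc$height > h_cut + 1e-12) + 1
  stats::cutree(hc, k = k)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  lab <- gsub("[,;:()\\s]", "_", hc$labels, perl = TRUE)
  node <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%g", lab[-i], parent_h))
    kids <- hc$merge[i, ]
    h <- hc$height[i]
    sprintf("(%s,%s):%g", node(kids[1], h), node(kids[2], h), parent_h - h)
  }
  n <- nrow(hc$merge)
  kids <- hc$merge[n, ]
  h <- hc$height[n]
  s <- sprintf("(%s,%s);", node(kids[1], h), node(kids[2], h))
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Spearman correlation screen between index and environment tables
#'
#' Rank correlation (midranks for ties) with two-sided p-values for every
#' (index, variable) pair. Constant columns yield `NA` and are flagged.
#'
#' @param index_table data frame or matrix of community descriptors (rows =
#'   samples).
#' @param env_table matrix/data frame of environmental variables on the same
#'   samples, in the same row order.
#' @return list with matrices `rho` and `p` (indices x variables) and a
#'   character vector `constant` of skipped columns.
#' @export
spearman_screen <- function(index_table, env_table) {
  xi <- as.matrix(as.data.frame(index_table)[vapply(as.data.frame(index_table),
                                                    is.numeric, TRUE)])
  xe <- as.matrix(unclass(env_table))
  if (nrow(xi) != nrow(xe)) stop("tables must have the same samples")
  if (nrow(xi) < 4) stop("need at least 4 samples")
  const <- c(colnames(xi)[apply(xi, 2, stats::sd) == 0],
             colnames(xe)[apply(xe, 2, stats::sd) == 0])
  rho <- matrix(NA_real_, ncol(xi), ncol(xe),
                dimnames = list(colnames(xi), colnames(xe)))
  p <- rho
  for (i in seq_len(ncol(xi))) for (j in seq_len(ncol(xe))) {
    if (colnames(xi)[i] %in% const || colnames(xe)[j] %in% const) next
    ct <- suppressWarnings(stats::cor.test(xi[, i], xe[, j],
                                           method = "spearman"))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(rho = rho, p = p, constant = const)
}

# Fixed vectorisation of the off-diagonal (i < j) entries of a dist:
# pairs in the order (1,2),(1,3),(2,3),(1,4),... The order is shared by all
# rank computations, which is all a rank correlation needs.
.dist_vec <- function(d) {
  m <- as.matrix(d)
  m[upper.tri(m)]
}

#' Mantel-type matrix correlation (RELATE)
#'
#' Spearman rank correlation between the upper-triangle entries of two
#' distance matrices over the same samples, tested by jointly permuting the
#' rows/columns of the second matrix. The p-value is
#' `(1 + #(rho_perm >= rho_obs)) / (n_perm + 1)`. With `exhaustive = TRUE`
#' (or whenever `n! <= n_perm`) all `n!` relabellings are enumerated instead
#' and the p-value is the exact `#(rho_perm >= rho_obs) / n!` (the identity
#' permutation counts).
#'
#' @param d_bio,d_env `dist` objects (or square matrices) with identical
#'   labels in identical order.
#' @param n_perm number of random permutations (>= 99), default 999.
#' @param seed optional integer seed for the permutation stream.
#' @param exhaustive force exhaustive enumeration of all relabellings.
#' @return list of class `relate_result`: `rho`, `p_value`,
#'   `n_permutations`, `permuted_rho` (summary), `exhaustive`.
#' @export
relate <- function(d_bio, d_env, n_perm = 999, seed = NULL,
                   exhaustive = FALSE) {
  mb <- as.matrix(d_bio); me <- as.matrix(d_env)
  if (!identical(dim(mb), dim(me)))
    stop("distance matrices have different sizes")
  if (!is.null(rownames(mb)) && !is.null(rownames(me)) &&
      !identical(rownames(mb), rownames(me)))
    stop("distance matrix labels do not match")
  n <- nrow(mb)
  if (n < 3) stop("need at least 3 samples")
  ut <- upper.tri(mb)
  rb <- rank(mb[ut])
  obs <- stats::cor(rb, rank(me[ut]))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (exhaustive || factorial(n) <= n_perm) {
    perms <- .all_permutations(n)
    stat <- vapply(seq_len(nrow(perms)), function(i) {
      pm <- me[perms[i, ], perms[i, ]]
      stats::cor(rb, rank(pm[ut]))
    }, numeric(1))
    p <- sum(stat >= obs - 1e-12) / length(stat)
    perm_stat <- stat
    np <- length(stat)
    exh <- TRUE
  } else {
    if (n_perm < 99) stop("n_perm must be at least 99")
    perm_stat <- vapply(seq_len(n_perm), function(i) {
      pr <- sample.int(n)
      pm <- me[pr, pr]
      stats::cor(rb, rank(pm[ut]))
    }, numeric(1))
    p <- (1 + sum(perm_stat >= obs - 1e-12)) / (n_perm + 1)
    np <- n_perm
    exh <- FALSE
  }
  structure(list(rho = obs, p_value = p, n_permutations = np,
                 permuted_rho = summary(perm_stat), exhaustive = exh),
            class = "relate_result")
}

#' @export
print.relate_result <- function(x, ...) {
  cat(sprintf("RELATE: rho = %.4f, p = %.4g (%s%d permutations)\n",
              x$rho, x$p_value, if (x$exhaustive) "exhaustive " else "",
              x$n_permutations))
  invisible(x)
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Best environmental-variable subsets (BIOENV)
#'
#' Exhaustive search over all subsets of environmental variables up to size
#' `k_max` for the subset whose sample dissimilarity matrix best
#' rank-correlates (Spearman) with a fixed biotic dissimilarity matrix. By
#' default the biotic matrix is Bray-Curtis on square-root transformed
#' abundances and environmental dissimilarity is Euclidean on standardised
#' variables; both are parameters.
#'
#' @param bio a [community_matrix()] of abundances, or a precomputed `dist`.
#' @param env an [environment_matrix()] (constant variables are refused).
#' @param k_max largest subset size (default: all variables).
#' @param bio_metric,bio_transform metric and transform for the biotic
#'   matrix when `bio` is a community matrix.
#' @param env_metric metric for the environmental subsets.
#' @param n_best number of top subsets to keep per size and overall.
#' @return list of class `bioenv_result`: `best` (data frame of ranked
#'   subsets with `size`, `variables`, `rho`), `best_by_size`, `n_subsets`,
#'   and the metric tags used.
#' @export
bioenv <- function(bio, env, k_max = NULL,
                   bio_metric = "bray-curtis", bio_transform = "sqrt",
                   env_metric = "normalized-euclidean", n_best = 10) {
  if (inherits(bio, "dist")) {
    d_bio <- bio
    if (attr(d_bio, "Size") != nrow(env))
      stop("bio and env must cover the same samples")
  } else {
    if (!identical(rownames(unclass(bio)), rownames(unclass(env))))
      stop("bio and env must have identical samples in identical order")
    b <- if (identical(bio_transform, "sqrt") &&
             !isTRUE(attr(bio, "sqrt_transformed"))) sqrt_transform(bio) else bio
    d_bio <- distance_matrix(b, bio_metric)
  }
  x <- as.matrix(unclass(env))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant environmental variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- if (identical(env_metric, "normalized-euclidean")) scale(x) else x
  v <- ncol(z)
  if (is.null(k_max)) k_max <- v
  if (k_max > v) stop("k_max exceeds the number of variables")
  n_subsets <- sum(choose(v, seq_len(k_max)))
  if (n_subsets > 1e6) stop("subset count ", n_subsets, " exceeds 1e6 guard")
  rb <- rank(.dist_vec(d_bio))
  rows <- vector("list", n_subsets)
  r <- 0
  for (k in seq_len(k_max)) {
    sets <- utils::combn(v, k)
    for (j in seq_len(ncol(sets))) {
      idx <- sets[, j]
      de <- stats::dist(z[, idx, drop = FALSE])
      rho <- stats::cor(rb, rank(.dist_vec(de)))
      r <- r + 1
      rows[[r]] <- data.frame(size = k,
                              variables = paste(colnames(z)[idx],
                                                collapse = ", "),
                              rho = rho, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$rho), , drop = FALSE]
  rownames(tab) <- NULL
  by_size <- do.call(rbind, lapply(split(tab, tab$size),
                                   function(d) d[which.max(d$rho), ]))
  rownames(by_size) <- NULL
  structure(list(best = utils::head(tab, n_best),
                 best_by_size = by_size[order(by_size$size), ],
                 n_subsets = n_subsets,
                 bio_metric = if (inherits(bio, "dist"))
                   attr(bio, "metric") else bio_metric,
                 env_metric = env_metric),
            class = "bioenv_result")
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat(sprintf("BIOENV: %d subsets evaluated (bio: %s, env: %s)\n",
              x$n_subsets, x$bio_metric, x$env_metric))
  print(x$best, ...)
  invisible(x)
}
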