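# Community indices: richness, Shannon diversity, occurrence frequency,
# frequency-weighted dominance, phylum shares, grouped summaries.

#' Species richness of an abundance vector
#'
#' Number of taxa with strictly positive abundance.
#'
#' @param x non-negative numeric vector.
#' @return integer count.
#' @export
richness <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  sum(x > 0)
}

#' Shannon diversity (natural log)
#'
#' \deqn{H' = -\sum_i p_i \ln p_i, \quad p_i = n_i / N}
#' over taxa with positive abundance; returned as a positive value in nats.
#' Scale-invariant: multiplying all abundances by a constant leaves H'
#' unchanged.
#'
#' @param x non-negative numeric vector with at least one positive entry.
#' @return H' in natural-log units.
#' @examples
#' shannon(c(1, 1))  # log(2)
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  x <- x[x > 0]
  if (!length(x)) stop("Shannon index undefined for an all-zero vector")
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Occurrence frequency of taxa across samples
#'
#' Fraction of samples in which each taxon has abundance > 0.
#'
#' @param mat a [community_matrix()] (samples x taxa).
#' @param taxon optional taxon id(s); default all columns.
#' @return named numeric vector in `[0, 1]`.
#' @export
occurrence_frequency <- function(mat, taxon = NULL) {
  if (is.null(taxon)) taxon <- colnames(mat)
  miss <- setdiff(taxon, colnames(mat))
  if (length(miss)) stop("unknown taxon: ", paste(miss, collapse = ", "))
  colMeans(unclass(mat)[, taxon, drop = FALSE] > 0)
}

#' Frequency-weighted dominance of each taxon
#'
#' Dominance of taxon *i* over a sample collection is
#' \deqn{Y_i = (n_i / N) \, f_i}
#' where \eqn{n_i} is the taxon's total abundance over all samples, \eqn{N}
#' the grand total and \eqn{f_i} its occurrence frequency. A taxon is
#' dominant when \eqn{Y_i \ge} `threshold` (boundary inclusive).
#'
#' @param mat a [community_matrix()].
#' @param threshold dominance cutoff, default 0.02.
#' @return data frame with `taxon_id`, `relative_abundance`,
#'   `occurrence_frequency`, `dominance`, `is_dominant`, sorted by
#'   decreasing dominance.
#' @export
dominance <- function(mat, threshold = 0.02) {
  if (!nrow(mat) || !ncol(mat)) stop("empty community matrix")
  tot <- colSums(mat)
  N <- sum(tot)
  if (N <= 0) stop("community matrix has zero total abundance")
  f <- occurrence_frequency(mat)
  out <- data.frame(taxon_id = colnames(mat),
                    relative_abundance = unname(tot / N),
                    occurrence_frequency = unname(f),
                    stringsAsFactors = FALSE)
  out$dominance <- out$relative_abundance * out$occurrence_frequency
  out$is_dominant <- out$dominance >= threshold
  out[order(-out$dominance), , drop = FALSE]
}

#' Group totals and percentage shares
#'
#' Aggregates a community (abundance or biomass) matrix by a registry
#' grouping column, by default `phylum`, and reports group totals and
#' percentages of the grand total.
#'
#' @param mat a [community_matrix()].
#' @param registry a [trait_registry()] resolving every taxon in `mat`.
#' @param by registry column to group by (default `"phylum"`).
#' @return data frame with `group`, `total`, `percent`, sorted by
#'   decreasing share; percentages sum to 100.
#' @export
group_shares <- function(mat, registry, by = "phylum") {
  idx <- match(colnames(mat), registry$taxon_id)
  if (anyNA(idx))
    stop("taxa missing from registry: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "))
  grp <- registry[[by]][idx]
  if (anyNA(grp))
    stop("taxa with missing '", by, "': ",
         paste(colnames(mat)[is.na(grp)], collapse = ", "))
  tot <- tapply(colSums(mat), grp, sum)
  out <- data.frame(group = names(tot), total = as.numeric(tot),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$total / sum(out$total)
  out[order(-out$total), , drop = FALSE]
}

#' Per-sample index table
#'
#' Computes total abundance, richness and Shannon H' for every sample row.
#'
#' @param mat a [community_matrix()].
#' @return data frame with one row per sample.
#' @export
sample_indices <- function(mat) {
  m <- unclass(mat)
  data.frame(sample_id = rownames(m),
             total = rowSums(m),
             richness = apply(m, 1, richness),
             shannon = apply(m, 1, function(x)
               if (any(x > 0)) shannon(x) else NA_real_),
             stringsAsFactors = FALSE)
}

#' Grouped mean and standard deviation of community descriptors
#'
#' Summarises per-sample totals, richness and Shannon H' by a sample-level
#' factor (`site` or `season` from the matrix's `sample_info`). The SD is
#' the sample standard deviation (n - 1 denominator).
#'
#' @param mat a [community_matrix()] with `sample_info`.
#' @param factor grouping column, `"site"` or `"season"` (any `sample_info`
#'   column is accepted).
#' @return data frame with one row per factor level: n, mean and sd of the
#'   per-sample total, mean richness, mean Shannon.
#' @export
summarize_by_factor <- function(mat, factor = "site") {
  si <- sample_info(mat)
  if (is.null(si) || !factor %in% names(si))
    stop("sample_info lacks factor column '", factor, "'")
  lev <- si[[factor]]
  idx <- sample_indices(mat)
  agg <- function(v, f) c(mean = mean(v), sd = stats::sd(v))
  levs <- unique(lev)
  out <- do.call(rbind, lapply(levs, function(L) {
    sel <- lev == L
    data.frame(level = L, n = sum(sel),
               mean_total = mean(idx$total[sel]),
               sd_total = stats::sd(idx$total[sel]),
               mean_richness = mean(idx$richness[sel]),
               mean_shannon = mean(idx$shannon[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
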