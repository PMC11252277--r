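# Pantle-Buck saprobic index and water-quality classification.

#' Load a saprobic valence table
#'
#' A saprobic valence table maps saprobity code tokens to numeric valences
#' S in `[1, 4]` (oligosaprobic = 1 ... polysaprobic = 4, transitional codes
#' at midpoints) and carries the ordered classification bands that map an
#' index value to a saprobic level, a pollution-degree description and a
#' habitat-quality class (I-IV). Bands are half-open `[lower, upper)` and
#' contiguous over `[1, 4)`.
#'
#' The default table bundled with the package uses the conventional
#' Pantle-Buck valence scale: o = 1.0, o-b = 1.5, b = 2.0, b-a = a-b = 2.5,
#' a = 3.0, a-p = p-a = 3.5, p = 4.0, with o-a = 2.0 and the rarer
#' transitional codes p-i and p-m read as poly-leaning forms at 3.5 (both
#' are marked as assumptions in the shipped config and can be overridden).
#'
#' @param path YAML config with fields `code_to_S` (map) and `class_bands`
#'   (list of `lower`, `upper`, `level`, `degree`, `class`). Default: the
#'   bundled table.
#' @return object of class `saprobic_valence_table`: a list with
#'   `code_to_S` (named numeric) and `class_bands` (data frame).
#' @export
default_valence_table <- function(path = system.file("extdata",
                                                     "valences.yml",
                                                     package = "saprolens")) {
  cfg <- yaml::read_yaml(path)
  code_to_S <- unlist(cfg$code_to_S)
  bands <- do.call(rbind, lapply(cfg$class_bands, as.data.frame))
  saprobic_valence_table(code_to_S, bands)
}

#' Construct a saprobic valence table
#' @param code_to_S named numeric vector, values in `[1, 4]`.
#' @param class_bands data frame with `lower`, `upper`, `level`, `degree`,
#'   `class`; bands must be contiguous, non-overlapping and ordered.
#' @return object of class `saprobic_valence_table`.
#' @export
saprobic_valence_table <- function(code_to_S, class_bands) {
  code_to_S <- unlist(code_to_S)
  if (is.null(names(code_to_S)) || any(!nzchar(names(code_to_S))))
    stop("code_to_S must be a named vector")
  if (any(code_to_S < 1 | code_to_S > 4))
    stop("valences must lie in [1, 4]")
  class_bands <- as.data.frame(class_bands)
  need <- c("lower", "upper", "level", "degree", "class")
  if (!all(need %in% names(class_bands)))
    stop("class_bands needs columns: ", paste(need, collapse = ", "))
  class_bands <- class_bands[order(class_bands$lower), , drop = FALSE]
  rownames(class_bands) <- NULL
  if (any(class_bands$upper <= class_bands$lower))
    stop("each band needs upper > lower")
  if (nrow(class_bands) > 1 &&
      any(abs(class_bands$lower[-1] -
                class_bands$upper[-nrow(class_bands)]) > 1e-9))
    stop("class bands must be contiguous")
  structure(list(code_to_S = code_to_S, class_bands = class_bands),
            class = "saprobic_valence_table")
}

#' @export
print.saprobic_valence_table <- function(x, ...) {
  cat("saprobic_valence_table:", length(x$code_to_S), "codes,",
      nrow(x$class_bands), "class bands\n")
  print(x$class_bands, ...)
  invisible(x)
}

#' Resolve a saprobity code to its numeric valence
#'
#' Unknown codes are a declared error, never silently skipped: a registry
#' code absent from the table means the table is incomplete for the data at
#' hand and must be extended explicitly.
#'
#' @param code character vector of saprobity codes.
#' @param table a [saprobic_valence_table()].
#' @return numeric valence(s) S in `[1, 4]`.
#' @export
resolve_valence <- function(code, table = default_valence_table()) {
  code <- as.character(code)
  if (any(is.na(code) | !nzchar(code))) stop("empty saprobity code")
  unknown <- setdiff(unique(code), names(table$code_to_S))
  if (length(unknown))
    stop("saprobity code(s) not in valence table: ",
         paste(unknown, collapse = ", "))
  unname(table$code_to_S[code])
}

#' Pantle-Buck saprobic index
#'
#' The abundance-weighted mean valence of the classified taxa in a sample:
#' \deqn{SI = \frac{\sum_i S_i h_i}{\sum_i h_i}}
#' with \eqn{S_i} the species valence and \eqn{h_i} its abundance. The
#' index is invariant under uniform scaling of abundances and bounded by
#' the smallest and largest contributing valence.
#'
#' @param h abundances of the classified taxa (non-negative, sum > 0).
#' @param S valences aligned with `h`.
#' @return the saprobic index, a value in `[1, 4]`.
#' @examples
#' saprobic_index(c(10, 30), c(1, 3))  # 2.5
#' @export
saprobic_index <- function(h, S) {
  if (length(h) != length(S)) stop("h and S must have equal length")
  if (any(h < 0)) stop("abundances must be non-negative")
  if (sum(h) <= 0) stop("saprobic index undefined: zero classified abundance")
  sum(S * h) / sum(h)
}

#' Classify a saprobic index value
#'
#' Half-open band lookup (`lower` inclusive, `upper` exclusive) against the
#' table's classification bands.
#'
#' @param SI saprobic index value(s).
#' @param table a [saprobic_valence_table()].
#' @return data frame with `SI`, `level`, `degree`, `class`.
#' @examples
#' classify_saprobic(2.92)$class  # "III"
#' @export
classify_saprobic <- function(SI, table = default_valence_table()) {
  b <- table$class_bands
  idx <- vapply(SI, function(x) {
    i <- which(x >= b$lower & x < b$upper)
    if (!length(i)) NA_integer_ else i[1]
  }, integer(1))
  if (anyNA(idx))
    stop("SI outside the covered range [",
         min(b$lower), ", ", max(b$upper), "): ",
         paste(SI[is.na(idx)], collapse = ", "))
  data.frame(SI = SI, level = b$level[idx], degree = b$degree[idx],
             class = b$class[idx], stringsAsFactors = FALSE)
}

#' Saprobic assessment of a monitoring campaign
#'
#' Computes the Pantle-Buck index for groups of samples (sites by default)
#' from a community matrix and a registry. Only taxa carrying a saprobity
#' code contribute; the classified fraction of total abundance is reported
#' alongside each index so the representativity of the assessment can be
#' judged. Two aggregation modes are supported because survey reports differ
#' in which they use:
#' \describe{
#'   \item{`"mean_si"`}{compute SI per sample, then average within a group
#'     (samples with zero classified abundance are dropped with a warning);}
#'   \item{`"pooled"`}{compute one SI on the group's mean abundances.}
#' }
#'
#' @param mat a [community_matrix()] of abundances.
#' @param registry a [trait_registry()] with `saprobity_code`.
#' @param table a [saprobic_valence_table()].
#' @param group_by `sample_info` column to group by (default `"site"`), or
#'   `NULL` for per-sample results.
#' @param mode `"pooled"` (default) or `"mean_si"`, see above.
#' @return data frame with one row per group: `group`, `SI`,
#'   `n_classified_taxa`, `classified_fraction`, `level`, `degree`, `class`.
#' @export
campaign_saprobity <- function(mat, registry, table = default_valence_table(),
                               group_by = "site",
                               mode = c("pooled", "mean_si")) {
  mode <- match.arg(mode)
  idx <- match(colnames(mat), registry$taxon_id)
  if (anyNA(idx))
    stop("taxa missing from registry: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "))
  code <- registry$saprobity_code[idx]
  has_code <- !is.na(code) & nzchar(code)
  if (!any(has_code)) stop("no taxon carries a saprobity code")
  S <- resolve_valence(code[has_code], table)
  m <- unclass(mat)
  if (is.null(group_by)) {
    groups <- rownames(m)
    lev <- rownames(m)
  } else {
    si <- sample_info(mat)
    if (is.null(si) || !group_by %in% names(si))
      stop("sample_info lacks grouping column '", group_by, "'")
    lev <- as.character(si[[group_by]])
    groups <- unique(lev)
  }
  res <- do.call(rbind, lapply(groups, function(g) {
    rows <- m[lev == g, , drop = FALSE]
    hc <- rows[, has_code, drop = FALSE]
    if (mode == "pooled") {
      h <- colMeans(hc)
      if (sum(h) <= 0) stop("group '", g, "' has zero classified abundance")
      SI <- saprobic_index(h, S)
    } else {
      per <- apply(hc, 1, function(h) if (sum(h) > 0)
        saprobic_index(h, S) else NA_real_)
      if (all(is.na(per)))
        stop("group '", g, "' has zero classified abundance")
      if (anyNA(per))
        warning("group '", g, "': ", sum(is.na(per)),
                " sample(s) without classified taxa dropped")
      SI <- mean(per, na.rm = TRUE)
    }
    data.frame(group = g,
               SI = SI,
               n_classified_taxa = sum(colSums(hc) > 0),
               classified_fraction = sum(hc) / sum(rows),
               stringsAsFactors = FALSE)
  }))
  cls <- classify_saprobic(res$SI, table)
  res$level <- cls$level
  res$degree <- cls$degree
  res$class <- cls$class
  rownames(res) <- NULL
  res
}
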