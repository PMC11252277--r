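# Domain containers: trait registry, community matrix, environment matrix,
# saprobic valence table. All are thin S3 wrappers over base structures so
# they compose with stats/vegan-style workflows.

PHYLA <- c("Amoebozoa", "Choanozoa", "Heliozoa", "Cercozoa", "Myzozoa",
           "Ciliophora")
SHAPES <- c("sphere", "oval", "ellipsoid", "cone", "cylinder")

#' Construct a taxon trait registry
#'
#' A trait registry is a data frame with one row per taxon carrying the
#' morphological and autecological information the downstream operations
#' need: phylum, an assigned geometric shape with cell length and width
#' (for biovolume), a saprobity code (for the saprobic index) and a feeding
#' guild. Only `taxon_id` is mandatory; all trait columns may be `NA` and
#' are validated lazily by the operation that needs them.
#'
#' @param taxon_id character vector of unique short keys (slugs).
#' @param name display names (defaults to `taxon_id`).
#' @param phylum one of Amoebozoa, Choanozoa, Heliozoa, Cercozoa, Myzozoa,
#'   Ciliophora, or `NA`.
#' @param shape geometric shape class: one of `r paste(SHAPES, collapse=", ")`,
#'   or `NA`.
#' @param length_um,width_um cell dimensions in micrometres (full dimensions,
#'   not semi-axes); `length_um >= width_um` where both are given.
#' @param saprobity_code saprobity code token (e.g. `"o"`, `"b"`, `"a-b"`,
#'   `"p"`), stored verbatim and resolved against a valence table only when
#'   a saprobic index is computed.
#' @param feeding_guild feeding guild token(s) (e.g. `"Ba"`, `"O"`).
#' @return an object of class `trait_registry` (a data frame).
#' @seealso [read_trait_registry()], [load_study_fixture()]
#' @export
trait_registry <- function(taxon_id, name = taxon_id, phylum = NA,
                           shape = NA, length_um = NA, width_um = NA,
                           saprobity_code = NA, feeding_guild = NA) {
  n <- length(taxon_id)
  reg <- data.frame(
    taxon_id = as.character(taxon_id),
    name = rep_len(as.character(name), n),
    phylum = rep_len(as.character(phylum), n),
    shape = rep_len(as.character(shape), n),
    length_um = rep_len(as.numeric(length_um), n),
    width_um = rep_len(as.numeric(width_um), n),
    saprobity_code = rep_len(as.character(saprobity_code), n),
    feeding_guild = rep_len(as.character(feeding_guild), n),
    stringsAsFactors = FALSE
  )
  reg$saprobity_code[!is.na(reg$saprobity_code) &
                       !nzchar(reg$saprobity_code)] <- NA_character_
  reg$shape[!is.na(reg$shape) & !nzchar(reg$shape)] <- NA_character_
  reg$phylum[!is.na(reg$phylum) & !nzchar(reg$phylum)] <- NA_character_
  validate_trait_registry(reg)
  class(reg) <- c("trait_registry", "data.frame")
  reg
}

validate_trait_registry <- function(reg) {
  if (anyDuplicated(reg$taxon_id))
    stop("duplicate taxon_id in registry: ",
         paste(unique(reg$taxon_id[duplicated(reg$taxon_id)]), collapse = ", "))
  bad_ph <- setdiff(stats::na.omit(reg$phylum), PHYLA)
  if (length(bad_ph))
    stop("unknown phylum token(s): ", paste(bad_ph, collapse = ", "))
  bad_sh <- setdiff(stats::na.omit(reg$shape), SHAPES)
  if (length(bad_sh))
    stop("unknown shape token(s): ", paste(bad_sh, collapse = ", "))
  both <- !is.na(reg$length_um) & !is.na(reg$width_um)
  if (any(reg$length_um[both] < reg$width_um[both]))
    stop("length_um < width_um for: ",
         paste(reg$taxon_id[both][reg$length_um[both] < reg$width_um[both]],
               collapse = ", "))
  dims <- c(reg$length_um, reg$width_um)
  if (any(dims[!is.na(dims)] <= 0))
    stop("cell dimensions must be positive")
  invisible(reg)
}

#' Read a trait registry from a delimited text file
#'
#' Expects a header with at least a `taxon_id` column; recognised optional
#' columns are `name`, `phylum`, `shape`, `length_um`, `width_um`,
#' `saprobity_code`, `feeding_guild`. Field separator is sniffed from the
#' file extension (`.tsv` = tab, otherwise comma).
#'
#' @param path file path.
#' @return a [trait_registry()].
#' @export
read_trait_registry <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"taxon_id" %in% names(raw)) stop("registry file lacks 'taxon_id' column")
  get <- function(col, default = NA) if (col %in% names(raw)) raw[[col]] else default
  trait_registry(
    taxon_id = raw$taxon_id,
    name = get("name", raw$taxon_id),
    phylum = get("phylum"),
    shape = get("shape"),
    length_um = suppressWarnings(as.numeric(get("length_um"))),
    width_um = suppressWarnings(as.numeric(get("width_um"))),
    saprobity_code = get("saprobity_code"),
    feeding_guild = get("feeding_guild")
  )
}

#' Construct a community matrix
#'
#' Samples are rows, taxa are columns, entries are non-negative abundances
#' (individuals per litre by default) or biomasses. Absence is represented
#' by 0, never by `NA`. Optional per-sample metadata (site, month, season)
#' rides along as the `sample_info` attribute and is used by grouped
#' operations such as [summarize_by_factor()] and [campaign_saprobity()].
#'
#' @param values numeric matrix (samples x taxa) with dimnames.
#' @param sample_info optional data frame with columns `sample_id` and any
#'   of `site`, `month`, `season`; `sample_id` must match rownames.
#' @param units unit tag, `"ind_per_L"` (default) or `"ug_per_L"`.
#' @return object of class `community_matrix` (a numeric matrix with
#'   attributes).
#' @export
community_matrix <- function(values, sample_info = NULL,
                             units = "ind_per_L") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("community matrix needs taxon column names")
  if (anyNA(values))
    stop("community matrix must not contain NA (absence is 0)")
  if (any(values < 0))
    stop("community matrix must be non-negative")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample_id")
  if (!is.null(sample_info)) {
    sample_info <- as.data.frame(sample_info)
    if (!"sample_id" %in% names(sample_info))
      stop("sample_info needs a sample_id column")
    if (!setequal(sample_info$sample_id, rownames(values)))
      stop("sample_info$sample_id does not match matrix rows")
    sample_info <- sample_info[match(rownames(values), sample_info$sample_id), ,
                               drop = FALSE]
    rownames(sample_info) <- NULL
    if (all(c("site", "month") %in% names(sample_info)) &&
        anyDuplicated(sample_info[, c("site", "month")]))
      stop("(site, month) pairs must be unique within a campaign")
  }
  structure(values, sample_info = sample_info, units = units,
            sqrt_transformed = FALSE,
            class = c("community_matrix", "matrix", "array"))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d samples x %d taxa [%s]%s\n",
              nrow(x), ncol(x), attr(x, "units"),
              if (isTRUE(attr(x, "sqrt_transformed"))) " (sqrt-transformed)" else ""))
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE]), ...)
  if (ncol(x) > 6) cat("...", ncol(x) - 6, "more taxa\n")
  invisible(x)
}

#' Per-sample metadata of a community or environment matrix
#' @param x a `community_matrix` or `environment_matrix`.
#' @return the `sample_info` data frame, or `NULL`.
#' @export
sample_info <- function(x) attr(x, "sample_info")

#' Read a community matrix from a delimited text file
#'
#' The file must have a header row and a first column of labels; all other
#' cells must be numeric and non-negative. Internally the matrix is always
#' normalised to samples-as-rows, whatever the input orientation.
#'
#' @param path file path (CSV, or TSV by `.tsv` extension).
#' @param orientation `"samples-as-rows"` (default) or `"taxa-as-rows"`.
#' @param sample_info,units passed on to [community_matrix()].
#' @return a [community_matrix()].
#' @export
read_community_matrix <- function(path,
                                  orientation = c("samples-as-rows",
                                                  "taxa-as-rows"),
                                  sample_info = NULL, units = "ind_per_L") {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  labs <- as.character(raw[[1]])
  body <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(body),
                                     dimnames = list(NULL, names(body)))
  if (anyNA(num) && !anyNA(body))
    stop("non-numeric cell in community matrix body")
  if (anyNA(num)) stop("missing or non-numeric cell in community matrix body")
  rownames(num) <- labs
  if (orientation == "taxa-as-rows") num <- t(num)
  community_matrix(num, sample_info = sample_info, units = units)
}

#' Write a community matrix to CSV (samples as rows)
#'
#' Values are written at full precision (up to 15 significant digits) so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param x a `community_matrix`.
#' @param path output path.
#' @export
write_community_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x),
                   format(unclass(x), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an environment matrix
#'
#' Samples x variables matrix of physicochemical measurements with a unit
#' string per variable. Zero-variance variables are permitted but flagged
#' (attribute `constant_variables`) because correlation-based procedures
#' cannot use them.
#'
#' @param values numeric matrix (samples x variables) with dimnames.
#' @param units named character vector of unit strings (optional).
#' @param sample_info as in [community_matrix()].
#' @return object of class `environment_matrix`.
#' @export
environment_matrix <- function(values, units = NULL, sample_info = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("environment matrix needs variable names")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (!is.null(sample_info)) {
    sample_info <- as.data.frame(sample_info)
    sample_info <- sample_info[match(rownames(values), sample_info$sample_id), ,
                               drop = FALSE]
    rownames(sample_info) <- NULL
  }
  v <- apply(values, 2, stats::sd)
  structure(values, units = units, sample_info = sample_info,
            constant_variables = colnames(values)[!is.na(v) & v == 0],
            class = c("environment_matrix", "matrix", "array"))
}

#' @export
print.environment_matrix <- function(x, ...) {
  cat(sprintf("environment_matrix: %d samples x %d variables\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE]), ...)
  invisible(x)
}

#' Align a community and an environment matrix on shared samples
#'
#' @param comm a `community_matrix`.
#' @param env an `environment_matrix`.
#' @return list with both objects restricted to the common samples, in the
#'   community matrix's order.
#' @export
align_samples <- function(comm, env) {
  shared <- intersect(rownames(comm), rownames(env))
  if (!length(shared)) stop("no shared samples between matrices")
  list(community = comm[shared, , drop = FALSE],
       environment = env[shared, , drop = FALSE])
}

# Subsetting keeps class and slices sample_info along rows.
#' @export
`[.community_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (!is.matrix(out)) return(out)
  si <- attr(x, "sample_info")
  if (!is.null(si)) {
    si <- si[match(rownames(out), si$sample_id), , drop = FALSE]
    rownames(si) <- NULL
  }
  structure(out, sample_info = si, units = attr(x, "units"),
            sqrt_transformed = attr(x, "sqrt_transformed"),
            class = class(x))
}

#' @export
`[.environment_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (!is.matrix(out)) return(out)
  si <- attr(x, "sample_info")
  if (!is.null(si)) {
    si <- si[match(rownames(out), si$sample_id), , drop = FALSE]
    rownames(si) <- NULL
  }
  units <- attr(x, "units")
  if (!is.null(units) && !is.null(names(units)))
    units <- units[intersect(names(units), colnames(out))]
  environment_matrix(out, units = units, sample_info = si)
}

#' Write analysis results as delimited text
#'
#' Accepts a data frame (written as one CSV) or a named list of data frames
#' (written as `<path>_<name>.csv` each, plus a small human-readable index
#' at `path`). Output is byte-stable for identical input.
#'
#' @param results data frame or named list of data frames.
#' @param path output file path (for a list, used as prefix and index file).
#' @export
write_summary_report <- function(results, path) {
  fmt <- function(df) {
    df <- as.data.frame(df)
    for (j in seq_along(df))
      if (is.numeric(df[[j]]))
        df[[j]] <- format(df[[j]], digits = 10, trim = TRUE, scientific = FALSE)
    df
  }
  if (is.data.frame(results)) {
    utils::write.csv(fmt(results), path, row.names = FALSE, quote = TRUE)
    return(invisible(path))
  }
  if (!is.list(results) || is.null(names(results)))
    stop("results must be a data frame or a named list of data frames")
  stem <- sub("\\.[^.]*$", "", path)
  files <- character(0)
  for (nm in names(results)) {
    f <- paste0(stem, "_", nm, ".csv")
    utils::write.csv(fmt(as.data.frame(results[[nm]])), f,
                     row.names = FALSE, quote = TRUE)
    files <- c(files, f)
  }
  writeLines(c("saprolens summary report", paste0("- ", basename(files))), path)
  invisible(c(path, files))
}
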