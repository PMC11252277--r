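# Sedgwick-Rafter chamber enumeration: counted squares -> concentration.

#' Concentration from a counting-chamber observation
#'
#' Converts a Sedgwick-Rafter count to a concentration in individuals per
#' millilitre:
#' \deqn{N/mL = \frac{C \times V_C \times n_{squares}}{V_T \times N}}
#' where `C` is the number of organisms counted, `N` the number of squares
#' scanned, `n_squares` the total number of squares in the chamber (1000
#' for the standard 1 mL Sedgwick-Rafter cell), `V_C` the volume of the
#' concentrated sample (mL) and `V_T` the volume of the original grab
#' sample (mL). All arguments are vectorised.
#'
#' @param C organisms counted (non-negative).
#' @param N squares counted, in `[1, total_squares]`.
#' @param V_C concentrate volume, mL (> 0).
#' @param V_T grab volume, mL (> 0); `V_C <= V_T`.
#' @param total_squares squares in the chamber; 1000 for a Sedgwick-Rafter
#'   cell, overridable for other chamber geometries.
#' @return individuals per mL.
#' @examples
#' concentration_per_ml(C = 30, N = 60, V_C = 50, V_T = 1000)  # 25
#' @export
concentration_per_ml <- function(C, N, V_C, V_T, total_squares = 1000) {
  if (any(C < 0)) stop("C must be non-negative")
  if (any(N <= 0)) stop("N (squares counted) must be >= 1")
  if (any(N > total_squares)) stop("N exceeds total_squares")
  if (any(V_T <= 0) || any(V_C <= 0)) stop("volumes must be positive")
  if (any(V_C > V_T)) stop("V_C (concentrate) cannot exceed V_T (grab)")
  C * V_C * total_squares / (V_T * N)
}

#' Convert a per-millilitre concentration to per litre
#' @param c_ml individuals per mL (non-negative).
#' @return individuals per litre (`1000 * c_ml`).
#' @export
concentration_per_litre <- function(c_ml) {
  if (any(c_ml < 0)) stop("concentration must be non-negative")
  1000 * c_ml
}

#' Build a community matrix from a count sheet
#'
#' A count sheet is long-format chamber data with columns `sample_id`,
#' `taxon_id`, `C`, `N`, `V_C`, `V_T` (one row per taxon actually seen in a
#' sample). Each row is converted with [concentration_per_ml()] and scaled
#' to individuals per litre; (sample, taxon) pairs absent from the sheet
#' become 0.
#'
#' @param sheet data frame or path to a CSV with the columns above.
#' @param total_squares chamber constant, see [concentration_per_ml()].
#' @param sample_info optional per-sample metadata, see [community_matrix()].
#' @return a [community_matrix()] in individuals per litre.
#' @export
enumerate_count_sheet <- function(sheet, total_squares = 1000,
                                  sample_info = NULL) {
  if (is.character(sheet)) sheet <- utils::read.csv(sheet,
                                                    stringsAsFactors = FALSE)
  need <- c("sample_id", "taxon_id", "C", "N", "V_C", "V_T")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("count sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  conc <- concentration_per_litre(concentration_per_ml(
    sheet$C, sheet$N, sheet$V_C, sheet$V_T, total_squares))
  samples <- unique(as.character(sheet$sample_id))
  taxa <- unique(as.character(sheet$taxon_id))
  m <- matrix(0, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  # accumulate (duplicated sample/taxon rows sum, e.g. split counts)
  key <- paste(sheet$sample_id, sheet$taxon_id, sep = "\r")
  agg <- rowsum(conc, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  m[cbind(match(vapply(parts, `[`, "", 1), samples),
          match(vapply(parts, `[`, "", 2), taxa))] <- agg[, 1]
  community_matrix(m, sample_info = sample_info, units = "ind_per_L")
}
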