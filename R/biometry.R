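# Geometric biovolume -> dry weight -> biomass concentration.

# Shape coefficients: volume = coef * l * w^2 (sphere uses l^3).
# l and w are full cell dimensions (diameters), not semi-axes.
.shape_coef <- c(sphere = pi / 6, oval = pi / 6, ellipsoid = pi / 12,
                 cone = pi / 12, cylinder = pi / 4)

#' Cell biovolume from an assigned geometric solid
#'
#' Each taxon is assigned the closest standard geometric shape and its
#' biovolume is computed from the measured cell length `l` and width `w`
#' (micrometres, full dimensions):
#' \describe{
#'   \item{sphere}{\eqn{\pi/6 \cdot l^3} (width ignored; `l` is the diameter)}
#'   \item{oval (prolate spheroid)}{\eqn{\pi/6 \cdot l w^2}}
#'   \item{ellipsoid}{\eqn{\pi/6 \cdot l \cdot w \cdot w/2 = \pi/12 \cdot l w^2}}
#'   \item{cone}{\eqn{\pi/12 \cdot l w^2}}
#'   \item{cylinder}{\eqn{\pi/4 \cdot l w^2}}
#' }
#' The ellipsoid and cone coefficients coincide; both tokens are kept so a
#' registry reads naturally. Vectorised over all arguments.
#'
#' @param shape shape token, one of sphere, oval, ellipsoid, cone, cylinder.
#' @param length_um cell length in micrometres (> 0).
#' @param width_um cell width in micrometres (> 0); required for every shape
#'   except sphere. `length_um >= width_um`.
#' @return biovolume in cubic micrometres.
#' @examples
#' biovolume("sphere", 10)            # pi/6 * 1000
#' biovolume("cylinder", 10, 10)      # 3 x the cone volume
#' @export
biovolume <- function(shape, length_um, width_um = NULL) {
  shape <- as.character(shape)
  bad <- setdiff(unique(shape), names(.shape_coef))
  if (length(bad)) stop("unknown shape token(s): ", paste(bad, collapse = ", "))
  if (any(length_um <= 0)) stop("length_um must be positive")
  n <- max(length(shape), length(length_um),
           if (is.null(width_um)) 0 else length(width_um))
  shape <- rep_len(shape, n)
  length_um <- rep_len(length_um, n)
  needs_w <- shape != "sphere"
  if (is.null(width_um)) {
    if (any(needs_w)) stop("width_um required for shape(s): ",
                           paste(unique(shape[needs_w]), collapse = ", "))
    width_um <- rep_len(NA_real_, n)
  } else {
    width_um <- rep_len(as.numeric(width_um), n)
    if (any(needs_w & (is.na(width_um) | width_um <= 0)))
      stop("width_um must be positive for non-spherical shapes")
  }
  vol <- ifelse(shape == "sphere",
                .shape_coef["sphere"] * length_um^3,
                .shape_coef[shape] * length_um * width_um^2)
  unname(vol)
}

#' Biomass parameters
#'
#' @param dry_weight_density conversion factor from biovolume to dry weight,
#'   picograms per cubic micrometre. The default 0.524 pg/um^3 is the
#'   standard protozoan plasma dry-weight density.
#' @return a list of class `biomass_params`.
#' @export
biomass_params <- function(dry_weight_density = 0.524) {
  if (!is.numeric(dry_weight_density) || dry_weight_density <= 0)
    stop("dry_weight_density must be a positive number")
  structure(list(dry_weight_density = dry_weight_density),
            class = "biomass_params")
}

#' Cell dry weight from biovolume
#' @param volume_um3 biovolume in cubic micrometres (>= 0).
#' @param params a [biomass_params()].
#' @return dry weight in picograms.
#' @export
cell_dry_weight <- function(volume_um3, params = biomass_params()) {
  if (any(volume_um3 < 0)) stop("volume must be non-negative")
  volume_um3 * params$dry_weight_density
}

#' Biomass concentration from abundance and per-cell dry weight
#'
#' `abundance` (individuals per litre) times per-cell dry weight (pg),
#' converted to micrograms per litre (1 ug = 1e6 pg).
#'
#' @param abundance individuals per litre (>= 0).
#' @param dry_weight_pg per-cell dry weight in picograms (>= 0).
#' @return biomass in micrograms per litre.
#' @export
biomass_concentration <- function(abundance, dry_weight_pg) {
  if (any(abundance < 0) || any(dry_weight_pg < 0))
    stop("abundance and dry weight must be non-negative")
  abundance * dry_weight_pg * 1e-6
}

#' Community biomass matrix
#'
#' Converts an abundance matrix (individuals per litre) to a biomass matrix
#' (micrograms per litre) using each taxon's registry morphology via
#' [biovolume()] and [cell_dry_weight()]. Every taxon with a nonzero
#' abundance anywhere must carry a shape and dimensions.
#'
#' @param mat a [community_matrix()] of abundances.
#' @param registry a [trait_registry()] resolving every needed taxon.
#' @param params a [biomass_params()].
#' @return a [community_matrix()] with units `"ug_per_L"`, aligned with the
#'   input.
#' @export
community_biomass <- function(mat, registry, params = biomass_params()) {
  taxa <- colnames(mat)
  idx <- match(taxa, registry$taxon_id)
  if (anyNA(idx))
    stop("taxa missing from registry: ",
         paste(taxa[is.na(idx)], collapse = ", "))
  used <- colSums(mat) > 0
  no_morph <- used & (is.na(registry$shape[idx]) |
                        is.na(registry$length_um[idx]) |
                        (registry$shape[idx] != "sphere" &
                           is.na(registry$width_um[idx])))
  if (any(no_morph))
    stop("taxa with nonzero abundance lack morphology: ",
         paste(taxa[no_morph], collapse = ", "))
  dw <- rep(0, length(taxa))
  ok <- !is.na(registry$shape[idx]) & !is.na(registry$length_um[idx])
  if (any(ok))
    dw[ok] <- cell_dry_weight(
      biovolume(registry$shape[idx][ok], registry$length_um[idx][ok],
                registry$width_um[idx][ok]),
      params)
  out <- sweep(unclass(mat), 2, dw * 1e-6, `*`)
  community_matrix(out, sample_info = sample_info(mat), units = "ug_per_L")
}
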