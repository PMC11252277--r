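# Bundled transcriptions of a published six-site Nile River protozoan
# survey: the saprobic classification table, per-site means of the
# physicochemical variables, and the 54-species community table (per-site
# mean abundance and biomass, saprobity codes, feeding guilds).
#
# The community table in the source is printed with empty cells for
# absences; its transcription here reconstructs the site assignment of each
# printed value from the survey's own totals (per-row averages, per-site
# community figures, per-site phylum shares and the saprobic narrative).
# Rows whose assignment is not fully pinned down by print carry
# `site_assignment_uncertain = TRUE` in the raw file; two cells lost in the
# source's typesetting were back-solved from row/column sums and carry
# `has_reconstructed_cell = TRUE`.

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "saprolens")
  if (!nzchar(p)) stop("fixture file not found: ", file)
  p
}

.sites_roman <- c("I", "II", "III", "IV", "V", "VI")

.read_table4 <- function() {
  utils::read.csv(.fixture_path("table4_community.csv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load a bundled study fixture
#'
#' Returns typed transcriptions of the survey tables shipped with the
#' package:
#' \describe{
#'   \item{`"table1"`}{the saprobic classification ([saprobic_valence_table()]
#'     with the default code-to-valence map and the seven class bands);}
#'   \item{`"table2_site_means"`}{data frame of per-site mean and SD of the
#'     32 physicochemical variables;}
#'   \item{`"table4_site_means"`}{list of two 6-sample x 54-taxon
#'     [community_matrix()] objects, `abundance` (individuals/L) and
#'     `biomass` (ug/L), sites as samples;}
#'   \item{`"table4_averages"`}{data frame of the 54-taxon community-mean
#'     abundance and biomass columns;}
#'   \item{`"trait_registry"`}{[trait_registry()] with phylum, saprobity
#'     code and feeding guild for all 54 taxa plus synthetic shape/dimension
#'     assignments for the five shape-exemplar species.}
#' }
#'
#' @param name fixture name, see above.
#' @return the corresponding object.
#' @examples
#' nrow(load_study_fixture("table4_averages"))  # 54
#' @export
load_study_fixture <- function(name = c("table1", "table2_site_means",
                                        "table4_site_means",
                                        "table4_averages",
                                        "trait_registry")) {
  if (!is.character(name) || length(name) != 1)
    stop("unknown fixture name")
  name <- match.arg(name)
  switch(name,
    "table1" = default_valence_table(),
    "table2_site_means" =
      utils::read.csv(.fixture_path("table2_environment_site_means.csv"),
                      stringsAsFactors = FALSE, check.names = FALSE),
    "table4_averages" = {
      t4 <- .read_table4()
      t4[, c("taxon_id", "name", "phylum", "saprobity_code",
             "feeding_guild", "abund_avg", "biom_avg")]
    },
    "table4_site_means" = {
      t4 <- .read_table4()
      info <- data.frame(sample_id = paste0("site_", .sites_roman),
                         site = .sites_roman, stringsAsFactors = FALSE)
      mk <- function(prefix, units) {
        m <- t(as.matrix(t4[, paste0(prefix, "_", .sites_roman)]))
        dimnames(m) <- list(info$sample_id, t4$taxon_id)
        community_matrix(m, sample_info = info, units = units)
      }
      list(abundance = mk("abund", "ind_per_L"),
           biomass = mk("biom", "ug_per_L"),
           flags = t4[, c("taxon_id", "dominant_sites",
                          "site_assignment_uncertain",
                          "has_reconstructed_cell")])
    },
    "trait_registry" = {
      t4 <- .read_table4()
      shp <- utils::read.csv(.fixture_path("fig2_shapes_synthetic.csv"),
                             stringsAsFactors = FALSE)
      i <- match(t4$taxon_id, shp$taxon_id)
      trait_registry(
        taxon_id = t4$taxon_id, name = t4$name, phylum = t4$phylum,
        shape = shp$shape[i],
        length_um = shp$length_um[i], width_um = shp$width_um[i],
        saprobity_code = t4$saprobity_code,
        feeding_guild = t4$feeding_guild)
    })
}

#' Environmental site means as an environment matrix
#'
#' Convenience accessor shaping the `"table2_site_means"` fixture as a
#' 6-sample [environment_matrix()] of per-site means (SDs dropped), sites
#' aligned with the `"table4_site_means"` fixture.
#'
#' @return an [environment_matrix()].
#' @export
study_environment_site_means <- function() {
  t2 <- load_study_fixture("table2_site_means")
  m <- t(as.matrix(t2[, paste0("mean_", .sites_roman)]))
  dimnames(m) <- list(paste0("site_", .sites_roman), t2$variable)
  environment_matrix(m,
                     units = stats::setNames(t2$unit, t2$variable),
                     sample_info = data.frame(
                       sample_id = paste0("site_", .sites_roman),
                       site = .sites_roman, stringsAsFactors = FALSE))
}
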