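# Seeded simulator of monitoring campaigns with planted structure, plus a
# recovery scorer. The generator emulates the statistical shape of a
# balanced multi-site, multi-month protozoan survey: a lognormal
# species-abundance distribution, species-level occupancy, seasonal and
# site effects, and a pollution gradient that favours pollutant-tolerant
# (high-valence) taxa and drives a subset of environmental variables.

#' Campaign simulation configuration
#'
#' Defaults emulate a balanced six-site, twelve-month survey of a 54-species
#' protozoan community (phylum mix 10/4/4/5/1/30). Species log-abundances
#' are drawn from a normal (so abundances are lognormal); occupancy grows
#' with abundance rank; every species gets a seasonal sinusoid and random
#' site effects; coded species respond to the pollution gradient with a
#' coefficient proportional to their saprobic valence, so saprobity-weighted
#' composition tracks the gradient.
#'
#' @param n_sites,n_months campaign layout (default 6 x 12).
#' @param n_species species pool size (default 54).
#' @param phylum_mix named integer vector summing to `n_species`.
#' @param sad_meanlog,sad_sdlog lognormal species-abundance parameters on
#'   the log(individuals/L) scale.
#' @param occupancy_range occupancy probabilities assigned linearly over
#'   abundance ranks (rarest, commonest).
#' @param seasonal_amplitude max amplitude of the per-species seasonal
#'   sinusoid (log-units).
#' @param site_effect_sd SD of species-by-site random effects (log-units).
#' @param gradient numeric vector (length `n_sites`) of pollution pressure
#'   per site; the default puts the strongest pressure on the last site.
#' @param beta_scale gradient response per unit of saprobic valence
#'   (log-units); with valences spanning 1-4 the default 1 puts 3 log-units
#'   (about a twenty-fold abundance change across the gradient) between the
#'   most sensitive and the most tolerant species, comparable to the range
#'   tolerant bacterivores span between clean and organically loaded sites
#'   in river surveys.
#' @param code_fraction fraction of species carrying a saprobity code.
#' @param noise_sdlog SD of multiplicative lognormal sampling noise.
#' @param env_drivers names of environmental variables coupled to the
#'   gradient (must be in the built-in menu).
#' @param env_noise_sd SD of environmental noise (standardised scale).
#' @param seed integer seed; mandatory, every stochastic step derives from
#'   it.
#' @return a list of class `campaign_config`.
#' @export
campaign_config <- function(n_sites = 6, n_months = 12, n_species = 54,
                            phylum_mix = c(Amoebozoa = 10, Choanozoa = 4,
                                           Heliozoa = 4, Cercozoa = 5,
                                           Myzozoa = 1, Ciliophora = 30),
                            sad_meanlog = log(12.5), sad_sdlog = 1.15,
                            occupancy_range = c(0.1, 0.95),
                            seasonal_amplitude = 0.6,
                            site_effect_sd = 0.1,
                            gradient = NULL,
                            beta_scale = 1,
                            code_fraction = 0.6,
                            noise_sdlog = 0.4,
                            env_drivers = c("TOC", "NH3", "BOD"),
                            env_noise_sd = 0.3,
                            seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (sum(phylum_mix) != n_species)
    stop("phylum_mix must sum to n_species")
  if (is.null(gradient))
    gradient <- seq(0, 1, length.out = n_sites)
  if (length(gradient) != n_sites)
    stop("gradient must have length n_sites")
  if (any(occupancy_range < 0 | occupancy_range > 1))
    stop("occupancy probabilities must lie in [0, 1]")
  structure(list(n_sites = n_sites, n_months = n_months,
                 n_species = n_species, phylum_mix = phylum_mix,
                 sad_meanlog = sad_meanlog, sad_sdlog = sad_sdlog,
                 occupancy_range = occupancy_range,
                 seasonal_amplitude = seasonal_amplitude,
                 site_effect_sd = site_effect_sd, gradient = gradient,
                 beta_scale = beta_scale, code_fraction = code_fraction,
                 noise_sdlog = noise_sdlog, env_drivers = env_drivers,
                 env_noise_sd = env_noise_sd, seed = as.integer(seed)),
            class = "campaign_config")
}

# Environmental variable menu (names and units follow the conventions of
# river water-quality monitoring); mean/sd give a plausible reporting scale.
.env_menu <- data.frame(
  variable = c("Temp", "pH", "Turb", "TDS", "EC", "DO", "BOD", "COD",
               "NH3", "NO2", "PO4", "SiO3", "TOC", "Al", "Fe"),
  unit = c("degC", "", "NTU", "mg/L", "uS/cm", "mg/L", "mg/L", "mg/L",
           "ug/L", "ug/L", "ug/L", "ug/L", "mg/L", "ug/L", "ug/L"),
  mean = c(26, 8.2, 4.7, 278, 426, 8.0, 6.5, 49, 309, 21, 145, 1175, 5.6,
           58, 48),
  sd = c(6, 0.2, 1.8, 43, 66, 1.6, 3.2, 38, 135, 3, 18, 600, 1.0, 20, 38),
  seasonal = c(1, 0.3, 0.2, 0.3, 0.3, 0.4, 0.3, 0.3, 0.3, 0.2, 0.2, 0.2,
               0.2, 0, 0),
  stringsAsFactors = FALSE
)

#' Generate a synthetic monitoring campaign
#'
#' Draws a trait registry, an abundance matrix (individuals/L), an
#' environment matrix and a ground-truth record from a [campaign_config()].
#' The expectation of species *i* in the sample at site *s*, month *m* is
#' \deqn{\exp(\mu_i + u_{is} + A_i \sin(2\pi m/12 + \phi_i) + \beta_i g_s)}
#' thinned by per-species occupancy and multiplied by mean-one lognormal
#' noise. Coded species have \eqn{\beta_i} proportional to their saprobic
#' valence minus the scale midpoint, so tolerant taxa rise and sensitive
#' taxa fall along the gradient. Driver variables in the environment matrix
#' are linear in the gradient plus noise; the rest carry only season and
#' noise. Identical configs (same seed) give identical output.
#'
#' @param config a [campaign_config()].
#' @return list with `registry` ([trait_registry()]), `community`
#'   ([community_matrix()]), `environment` ([environment_matrix()]) and
#'   `truth` (planted parameters: `gradient`, `env_drivers`, `beta`,
#'   `occupancy`, `expected_log_abundance`, `planted_dominants`, `config`).
#' @export
generate_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)
  ns <- config$n_species
  phyla <- rep(names(config$phylum_mix), config$phylum_mix)

  # species traits
  mu <- stats::rnorm(ns, config$sad_meanlog, config$sad_sdlog)
  occ <- config$occupancy_range[1] +
    (rank(mu) - 1) / (ns - 1) *
    diff(config$occupancy_range)
  shapes <- sample(SHAPES, ns, replace = TRUE)
  len <- stats::rlnorm(ns, log(50), 0.4)
  wid <- len * stats::runif(ns, 0.3, 0.8)
  codes <- rep(NA_character_, ns)
  n_coded <- round(config$code_fraction * ns)
  coded_idx <- sample.int(ns, n_coded)
  pool <- c("o", "o-b", "b", "a-b", "a", "p-a", "p")
  pool_S <- c(1, 1.5, 2, 2.5, 3, 3.5, 4)
  draw <- sample.int(length(pool), n_coded, replace = TRUE)
  codes[coded_idx] <- pool[draw]
  Sval <- rep(NA_real_, ns)
  Sval[coded_idx] <- pool_S[draw]
  beta <- ifelse(is.na(Sval), stats::rnorm(ns, 0, 0.05),
                 config$beta_scale * (Sval - 2.5))
  guilds <- ifelse(!is.na(Sval) & Sval >= 3, "Ba",
                   sample(c("Al", "O", "R", "Ki", "Fl"), ns, replace = TRUE))
  ids <- sprintf("sp%02d", seq_len(ns))
  registry <- trait_registry(
    taxon_id = ids, name = sprintf("Synthetic species %02d", seq_len(ns)),
    phylum = phyla, shape = shapes, length_um = len, width_um = wid,
    saprobity_code = codes, feeding_guild = guilds)

  # samples
  sites <- if (config$n_sites <= 6)
    utils::head(c("I", "II", "III", "IV", "V", "VI"), config$n_sites)
  else paste0("S", seq_len(config$n_sites))
  grid <- expand.grid(month = seq_len(config$n_months),
                      site = seq_len(config$n_sites))
  sample_id <- sprintf("%s_m%02d", sites[grid$site], grid$month)
  season <- c("winter", "winter", "spring", "spring", "spring", "summer",
              "summer", "summer", "autumn", "autumn", "autumn", "winter")
  info <- data.frame(sample_id = sample_id, site = sites[grid$site],
                     month = grid$month,
                     season = season[((grid$month - 1) %% 12) + 1],
                     stringsAsFactors = FALSE)

  amp <- stats::runif(ns, 0, config$seasonal_amplitude)
  phase <- stats::runif(ns, 0, 2 * pi)
  site_fx <- matrix(stats::rnorm(ns * config$n_sites, 0,
                                 config$site_effect_sd),
                    ns, config$n_sites)
  nsamp <- nrow(grid)
  logmu <- matrix(0, nsamp, ns, dimnames = list(sample_id, ids))
  for (i in seq_len(ns)) {
    logmu[, i] <- mu[i] + site_fx[i, grid$site] +
      amp[i] * sin(2 * pi * grid$month / 12 + phase[i]) +
      beta[i] * config$gradient[grid$site]
  }
  present <- matrix(stats::rbinom(nsamp * ns, 1, rep(occ, each = nsamp)),
                    nsamp, ns)
  noise <- matrix(stats::rlnorm(nsamp * ns, -config$noise_sdlog^2 / 2,
                                config$noise_sdlog), nsamp, ns)
  values <- present * exp(logmu) * noise
  community <- community_matrix(values, sample_info = info)

  # environment
  menu <- .env_menu
  missing_drv <- setdiff(config$env_drivers, menu$variable)
  if (length(missing_drv))
    stop("unknown env driver(s): ", paste(missing_drv, collapse = ", "))
  env <- matrix(0, nsamp, nrow(menu),
                dimnames = list(sample_id, menu$variable))
  for (j in seq_len(nrow(menu))) {
    drv <- menu$variable[j] %in% config$env_drivers
    z <- (if (drv) config$gradient[grid$site] -
            mean(config$gradient) else 0) * 2 +
      menu$seasonal[j] * sin(2 * pi * grid$month / 12) +
      stats::rnorm(nsamp, 0, config$env_noise_sd)
    env[, j] <- menu$mean[j] + menu$sd[j] * z
  }
  environment <- environment_matrix(env,
                                    units = stats::setNames(menu$unit,
                                                            menu$variable),
                                    sample_info = info)

  # planted dominants: expected dominance from the construction itself
  exp_tot <- colSums(exp(logmu)) * occ
  rel <- exp_tot / sum(exp_tot)
  planted <- ids[rel * occ >= 0.02]
  truth <- list(gradient = stats::setNames(config$gradient, sites),
                env_drivers = config$env_drivers,
                beta = stats::setNames(beta, ids),
                valence = stats::setNames(Sval, ids),
                occupancy = stats::setNames(occ, ids),
                expected_log_abundance = t(logmu),
                planted_dominants = planted,
                config = config)
  list(registry = registry, community = community,
       environment = environment, truth = truth)
}

#' Simulate Sedgwick-Rafter count sheets from target concentrations
#'
#' Inverts the enumeration formula: for each (sample, taxon) cell the
#' expected chamber count implied by the concentration and the chamber
#' configuration is computed and a Poisson count is drawn, so that
#' [enumerate_count_sheet()] recovers the matrix up to Poisson error.
#'
#' @param mat a [community_matrix()] in individuals per litre.
#' @param chamber list with `N` (squares counted), `V_C`, `V_T` (mL) and
#'   `total_squares`.
#' @param seed integer seed.
#' @return data frame count sheet (`sample_id`, `taxon_id`, `C`, `N`,
#'   `V_C`, `V_T`), one row per nonzero target cell plus explicit zero rows
#'   for taxa present in the matrix but absent from a sample.
#' @export
generate_count_sheets <- function(mat,
                                  chamber = list(N = 100, V_C = 50,
                                                 V_T = 1000,
                                                 total_squares = 1000),
                                  seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- unclass(mat)
  conc_ml <- m / 1000
  c_expected <- conc_ml * chamber$V_T * chamber$N /
    (chamber$V_C * chamber$total_squares)
  C <- matrix(stats::rpois(length(c_expected), c_expected),
              nrow(m), ncol(m))
  data.frame(
    sample_id = rep(rownames(m), times = ncol(m)),
    taxon_id = rep(colnames(m), each = nrow(m)),
    C = as.vector(C),
    N = chamber$N, V_C = chamber$V_C, V_T = chamber$V_T,
    stringsAsFactors = FALSE
  )
}

#' Score recovery of planted campaign structure
#'
#' Runs (or accepts) the standard analyses on a generated campaign and
#' scores them against the campaign's ground truth:
#' \enumerate{
#'   \item Spearman correlation between per-site saprobic index and the
#'     planted pollution gradient;
#'   \item whether the top BIOENV subset intersects the planted driver set;
#'   \item recall of planted dominant species by the dominance index.
#' }
#'
#' @param campaign result of [generate_campaign()].
#' @param valence_table a [saprobic_valence_table()].
#' @param k_max BIOENV subset-size limit (default 2; exhaustive over the
#'   15-variable menu is unnecessary to score driver recovery).
#' @param saprobity,bioenv_result,dominance_result optional precomputed
#'   analysis outputs (as from [campaign_saprobity()], [bioenv()],
#'   [dominance()]); computed from the campaign when omitted.
#' @return list with `si_gradient_rho`, `bioenv_top_variables`,
#'   `bioenv_hit`, `dominance_recall`, and the underlying tables.
#' @export
recovery_suite <- function(campaign, valence_table = default_valence_table(),
                           k_max = 2, saprobity = NULL,
                           bioenv_result = NULL, dominance_result = NULL) {
  truth <- campaign$truth
  if (is.null(truth)) stop("campaign lacks ground truth")
  if (is.null(saprobity))
    saprobity <- campaign_saprobity(campaign$community, campaign$registry,
                                    valence_table, group_by = "site")
  g <- truth$gradient[saprobity$group]
  rho_si <- stats::cor(saprobity$SI, g, method = "spearman")
  if (is.null(bioenv_result))
    bioenv_result <- bioenv(campaign$community, campaign$environment,
                            k_max = k_max)
  top_vars <- strsplit(bioenv_result$best$variables[1], ", ")[[1]]
  hit <- length(intersect(top_vars, truth$env_drivers)) > 0
  if (is.null(dominance_result))
    dominance_result <- dominance(campaign$community)
  planted <- truth$planted_dominants
  recall <- if (length(planted))
    mean(planted %in% dominance_result$taxon_id[dominance_result$is_dominant])
  else NA_real_
  list(si_gradient_rho = rho_si,
       bioenv_top_variables = top_vars,
       bioenv_hit = hit,
       dominance_recall = recall,
       saprobity = saprobity,
       bioenv = bioenv_result,
       dominance = dominance_result)
}
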