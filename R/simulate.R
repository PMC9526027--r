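#' Configure a synthetic multi-species community
#'
#' Defines the generative conditions for [simulate_community()]: a community
#' of species with geographic ranges (discs in a flat projected plane, so the
#' signed distance to the range margin has a closed form) or 1-D elevational
#' ranges, occupancy decaying at range margins through the scaled
#' inverse-logit distance covariate with species-specific slopes, correlated
#' species intercepts for occupancy and detection, visit-level detection
#' heterogeneity, and a pool of species whose range excludes every site
#' (candidates for all-zero detection histories).
#'
#' Two modes:
#' * `"geographic"`: disc ranges on a `extent_km` landscape; occupancy
#'   `logit(psi_ij) = a_i + beta_elev_i * elev_j + beta_dist_i * g(d_ij)`
#'   with `g` the scaled inverse-logit distance transform and `elev_j` the
#'   site elevation standardized across sites.
#' * `"elevational"`: a 1-D gradient; occupancy
#'   `logit(psi_ij) = a_i + beta_quad_i * s_ij^2` with `s` the
#'   species-standardized elevation (+1/-1 at the range limits).
#'
#' Detection: `logit(theta_ijk) = c_i + det_time_effect * time_jk` with
#' `time_jk` (hours post-sunrise, standardized) drawn per site and visit.
#' `(a_i, c_i)` are bivariate normal with correlation `rho_ac`.
#'
#' @param n_species,n_sites,n_visits community dimensions (`n_visits >= 2`).
#' @param extent_km landscape rectangle, km (geographic mode).
#' @param elev_range_m site elevation bounds, m.
#' @param radius_meanlog,radius_sdlog lognormal disc-radius parameters (km).
#' @param frac_never_observable fraction of species whose range centroid is
#'   placed at least 3 radii beyond the site hull.
#' @param mu_a,sigma_a,mu_c,sigma_c,rho_ac hyperparameters of the joint
#'   intercept distribution (means, SDs >= 0, correlation in \[-1, 1\]).
#' @param mu_beta_elev,sigma_beta_elev elevation random-slope hyperparameters
#'   (geographic mode).
#' @param mu_beta_dist,sigma_beta_dist distance random-slope hyperparameters;
#'   strongly negative means occupancy decays sharply at the range margin.
#' @param distance_scale_km scale of the generative distance transform.
#' @param det_time_effect fixed effect of standardized visit time on
#'   detection.
#' @param mode `"geographic"` or `"elevational"`.
#' @param elev_mid_range_m,elev_halfbreadth_m uniform bounds on species
#'   elevational midpoints and half-breadths (elevational mode).
#' @param mu_beta_quad,sigma_beta_quad hyperparameters for the quadratic
#'   species-standardized-elevation slope (elevational mode).
#' @param frac_migratory fraction of species given a seasonal presence window.
#' @param survey_doy survey day-of-year range for site dates.
#' @param seed integer RNG seed.
#' @return a list of class `bmsom_config`.
#' @export
community_config <- function(n_species = 50, n_sites = 200, n_visits = 4,
                             extent_km = c(1000, 1000),
                             elev_range_m = c(0, 3000),
                             radius_meanlog = log(250), radius_sdlog = 0.3,
                             frac_never_observable = 0.15,
                             mu_a = 0.5, sigma_a = 1,
                             mu_c = 0, sigma_c = 1, rho_ac = 0.5,
                             mu_beta_elev = 0, sigma_beta_elev = 1,
                             mu_beta_dist = -6, sigma_beta_dist = 1.5,
                             distance_scale_km = 200,
                             det_time_effect = -0.2,
                             mode = c("geographic", "elevational"),
                             elev_mid_range_m = c(500, 2500),
                             elev_halfbreadth_m = c(300, 1200),
                             mu_beta_quad = -3, sigma_beta_quad = 1,
                             frac_migratory = 0,
                             survey_doy = c(130, 190),
                             seed = 1) {
  mode <- match.arg(mode)
  if (n_visits < 2) abort("`n_visits` must be >= 2 (repeat visits identify detection).")
  if (n_species < 1 || n_sites < 1) abort("need at least one species and one site.")
  sds <- c(sigma_a, sigma_c, sigma_beta_elev, sigma_beta_dist, sigma_beta_quad)
  if (any(sds < 0)) abort("hyperparameter standard deviations must be >= 0.")
  if (abs(rho_ac) > 1) abort("`rho_ac` must lie in [-1, 1].")
  if (radius_sdlog < 0 || !is.finite(radius_meanlog)) abort("invalid radius distribution.")
  if (frac_never_observable < 0 || frac_never_observable >= 1) {
    abort("`frac_never_observable` must be in [0, 1).")
  }
  if (any(extent_km <= 0)) abort("landscape extent must be positive.")
  structure(as.list(environment()), class = "bmsom_config")
}

#' @export
print.bmsom_config <- function(x, ...) {
  cat(sprintf("<community config: %d species x %d sites x %d visits, %s mode, seed %d>\n",
              x$n_species, x$n_sites, x$n_visits, x$mode, x$seed))
  invisible(x)
}

#' Simulate a multi-species detection dataset with known truth
#'
#' Draws species ranges, computes the true range covariates, draws correlated
#' species intercepts and species random slopes, then the latent occupancy
#' matrix `Z_ij ~ Bernoulli(psi_ij)` and detections
#' `Y_ijk ~ Bernoulli(Z_ij * theta_ijk)`. Deterministic given
#' `config$seed + replicate`.
#'
#' @param config a [community_config()].
#' @param replicate non-negative integer; replicate `r` uses seed
#'   `config$seed + r`, giving independent reproducible replicates.
#' @return a list of class `bmsom_sim` with elements `detections` (long
#'   tibble: `species_id`, `site_id`, `visit`, `y`), `sites` (tibble:
#'   `site_id`, `x_km`, `y_km`, `elev_m`, `date`), `visits` (long tibble:
#'   `site_id`, `visit`, `time`), `ranges` (a [range_table()]), and `truth`
#'   (species-level parameter tibble plus the latent matrices `psi`, `theta`,
#'   `Z`, `distances_km`, `std_elev` and the config).
#' @export
simulate_community <- function(config, replicate = 0) {
  stopifnot(inherits(config, "bmsom_config"))
  set.seed(as.integer(config$seed + replicate))
  S <- config$n_species; J <- config$n_sites; K <- config$n_visits
  species <- sprintf("sp%03d", seq_len(S))
  site_ids <- sprintf("site%04d", seq_len(J))

  # --- landscape & sites -----------------------------------------------------
  if (config$mode == "geographic") {
    x <- runif(J, 0, config$extent_km[1])
    y <- runif(J, 0, config$extent_km[2])
  } else {
    x <- seq(0, config$extent_km[1], length.out = J)
    y <- rep(0, J)
  }
  elev <- if (config$mode == "elevational") {
    # elevation tracks the transect so the gradient is 1-D
    seq(config$elev_range_m[1], config$elev_range_m[2], length.out = J)
  } else {
    runif(J, config$elev_range_m[1], config$elev_range_m[2])
  }
  doy <- round(runif(J, config$survey_doy[1], config$survey_doy[2]))
  sites <- tibble(
    site_id = site_ids, x_km = x, y_km = y, elev_m = elev,
    date = as.Date(doy - 1, origin = "2020-01-01")
  )
  pts <- cbind(x, y)

  # --- species ranges --------------------------------------------------------
  n_far <- floor(config$frac_never_observable * S)
  far <- rep(FALSE, S)
  if (n_far > 0) far[sample.int(S, n_far)] <- TRUE
  hull_ctr <- c(mean(x), mean(y))
  max_reach <- max_dist_to_points(hull_ctr, pts)

  geoms <- vector("list", S)
  elev_lo <- elev_hi <- rep(NA_real_, S)
  if (config$mode == "geographic") {
    radius <- rlnorm(S, config$radius_meanlog, config$radius_sdlog)
    for (i in seq_len(S)) {
      if (far[i]) {
        ang <- runif(1, 0, 2 * pi)
        ctr <- hull_ctr + (max_reach + 3 * radius[i]) * c(cos(ang), sin(ang))
      } else {
        ctr <- c(runif(1, -0.25 * config$extent_km[1], 1.25 * config$extent_km[1]),
                 runif(1, -0.25 * config$extent_km[2], 1.25 * config$extent_km[2]))
      }
      geoms[[i]] <- geom_disc(ctr, radius[i])
    }
  } else {
    half <- runif(S, config$elev_halfbreadth_m[1], config$elev_halfbreadth_m[2])
    mid <- runif(S, config$elev_mid_range_m[1], config$elev_mid_range_m[2])
    hi_side <- runif(S) < 0.5
    mid[far] <- ifelse(hi_side[far],
                       max(elev) + 3 * half[far],
                       min(elev) - 3 * half[far])
    elev_lo <- mid - half
    elev_hi <- mid + half
  }

  season_start <- season_end <- rep(NA_real_, S)
  n_mig <- floor(config$frac_migratory * S)
  if (n_mig > 0) {
    mig <- sample.int(S, n_mig)
    season_start[mig] <- round(runif(n_mig, 60, 150))
    season_end[mig] <- season_start[mig] + round(runif(n_mig, 60, 180))
    wrap <- season_end[mig] > 366
    season_end[mig][wrap] <- season_end[mig][wrap] - 366
  }
  ranges <- range_table(species, geoms,
                        elev_lower_m = elev_lo, elev_upper_m = elev_hi,
                        season_start = season_start, season_end = season_end)

  # --- true covariates -------------------------------------------------------
  if (config$mode == "geographic") {
    dist_km <- signed_distance_matrix(ranges, sites)
    dist_cov <- scaled_inverse_logit(dist_km, config$distance_scale_km)
    elev_std_site <- as.numeric(scale(elev))
    std_elev <- NULL
  } else {
    dist_km <- NULL; dist_cov <- NULL
    std_elev <- std_elevation_matrix(ranges, sites)
    elev_std_site <- NULL
  }

  # --- species-level parameters ---------------------------------------------
  z1 <- rnorm(S); z2 <- rnorm(S)
  a <- config$mu_a + config$sigma_a * z1
  cc <- config$mu_c + config$sigma_c *
    (config$rho_ac * z1 + sqrt(1 - config$rho_ac^2) * z2)
  truth_sp <- tibble(species_id = species, a = a, c = cc,
                     never_observable = far)
  if (config$mode == "geographic") {
    truth_sp$beta_elev <- rnorm(S, config$mu_beta_elev, config$sigma_beta_elev)
    truth_sp$beta_dist <- rnorm(S, config$mu_beta_dist, config$sigma_beta_dist)
    logit_psi <- a + outer(truth_sp$beta_elev, elev_std_site) +
      truth_sp$beta_dist * dist_cov
  } else {
    truth_sp$beta_quad <- rnorm(S, config$mu_beta_quad, config$sigma_beta_quad)
    logit_psi <- matrix(a, S, J) + truth_sp$beta_quad * std_elev^2
  }
  psi <- plogis(logit_psi)
  dimnames(psi) <- list(species, site_ids)

  # --- detection -------------------------------------------------------------
  time_raw <- matrix(runif(J * K, 0, 5), J, K)
  time_std <- (time_raw - mean(time_raw)) / sd(as.numeric(time_raw))
  theta <- array(NA_real_, c(S, J, K), dimnames = list(species, site_ids, NULL))
  for (k in seq_len(K)) {
    theta[, , k] <- plogis(matrix(cc, S, J) +
                             config$det_time_effect *
                             matrix(time_std[, k], S, J, byrow = TRUE))
  }

  # --- latent state and detections ------------------------------------------
  Z <- matrix(rbinom(S * J, 1, psi), S, J, dimnames = dimnames(psi))
  Y <- array(rbinom(S * J * K, 1, as.numeric(theta)), c(S, J, K))
  Y <- Y * as.numeric(Z) # recycles Z over visits
  dimnames(Y) <- dimnames(theta)

  detections <- tidyr::expand_grid(species_id = species, site_id = site_ids,
                                   visit = seq_len(K)) |>
    dplyr::arrange(.data$species_id, .data$site_id, .data$visit)
  detections$y <- as.integer(Y[cbind(match(detections$species_id, species),
                                     match(detections$site_id, site_ids),
                                     detections$visit)])

  visits <- tidyr::expand_grid(site_id = site_ids, visit = seq_len(K))
  visits$time <- time_raw[cbind(match(visits$site_id, site_ids), visits$visit)]

  structure(list(
    detections = detections, sites = sites, visits = visits, ranges = ranges,
    truth = list(species = truth_sp, psi = psi, theta = theta, Z = Z,
                 distances_km = dist_km, dist_cov = dist_cov,
                 std_elev = std_elev, elev_std_site = elev_std_site,
                 time_std = time_std, config = config, replicate = replicate)
  ), class = "bmsom_sim")
}

#' @export
print.bmsom_sim <- function(x, ...) {
  cfg <- x$truth$config
  nobs <- length(never_observed_species(x$detections))
  cat(sprintf("<simulated community: %d species x %d sites x %d visits; %d never observed>\n",
              cfg$n_species, cfg$n_sites, cfg$n_visits, nobs))
  invisible(x)
}

#' Species with all-zero detection histories
#'
#' Partitions the simulated (or observed) community into observed and
#' never-observed species. Never-observed species stay in the bMSOM with
#' all-zero histories; in a data-augmented analysis they would instead be
#' represented by anonymous pseudospecies.
#'
#' @param detections long detection table (`species_id`, `site_id`, `visit`,
#'   `y`).
#' @param species optional character vector of the full species pool; species
#'   absent from `detections` entirely are also reported as never observed.
#' @return character vector of never-observed species ids.
#' @export
never_observed_species <- function(detections, species = NULL) {
  seen <- detections |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(any_det = any(.data$y == 1), .groups = "drop")
  out <- seen$species_id[!seen$any_det]
  if (!is.null(species)) {
    out <- union(out, setdiff(as.character(species), seen$species_id))
  }
  sort(as.character(out), method = "radix")
}
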