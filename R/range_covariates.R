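#' Assemble a per-species range-information table
#'
#' A range table holds, per species, the planar range geometry plus optional
#' elevational limits and a seasonal presence window (day-of-year, wrap-around
#' allowed). It is the raw material for range covariates and for biogeographic
#' and temporal clipping.
#'
#' @param species_id character vector of species ids.
#' @param geometry list of [geom_disc()] / [geom_polygon_km()] objects (or
#'   lists of them for disjunct ranges); may contain `NULL` for species with
#'   no mapped geographic range.
#' @param elev_lower_m,elev_upper_m optional elevational limits (m); `NA`
#'   where unknown. Where both are present, `elev_lower_m < elev_upper_m`.
#' @param season_start,season_end optional day-of-year presence window
#'   (integers in 1..366); `season_start > season_end` denotes a wrap-around
#'   window (e.g. 300..60 spans the new year). `NA` means resident
#'   (always present).
#' @return a tibble of class `bmsom_ranges`.
#' @export
range_table <- function(species_id, geometry = NULL,
                        elev_lower_m = NA_real_, elev_upper_m = NA_real_,
                        season_start = NA_real_, season_end = NA_real_) {
  species_id <- as.character(species_id)
  n <- length(species_id)
  if (anyDuplicated(species_id)) abort("duplicate species_id in range table.")
  if (is.null(geometry)) geometry <- vector("list", n)
  if (inherits(geometry, "bmsom_geom")) geometry <- list(geometry)
  stopifnot(length(geometry) == n)
  out <- tibble(
    species_id = species_id,
    geometry = geometry,
    elev_lower_m = rep_len(as.numeric(elev_lower_m), n),
    elev_upper_m = rep_len(as.numeric(elev_upper_m), n),
    season_start = rep_len(as.numeric(season_start), n),
    season_end = rep_len(as.numeric(season_end), n)
  )
  bad <- !is.na(out$elev_lower_m) & !is.na(out$elev_upper_m) &
    out$elev_lower_m >= out$elev_upper_m
  if (any(bad)) {
    abort(paste0("elev_lower_m >= elev_upper_m for species: ",
                 paste(out$species_id[bad], collapse = ", ")))
  }
  class(out) <- c("bmsom_ranges", class(out))
  out
}

#' Signed distance matrix from sites to every species' range
#'
#' @param ranges a [range_table()].
#' @param sites a site table with columns `site_id`, `x_km`, `y_km`.
#' @return a species x site matrix of signed distances (km), negative
#'   in-range, with dimnames from the ids. Species without mapped geometry get
#'   a row of `NA`.
#' @export
signed_distance_matrix <- function(ranges, sites) {
  pts <- as_points_matrix(sites)
  out <- matrix(NA_real_, nrow(ranges), nrow(sites),
                dimnames = list(ranges$species_id, as.character(sites$site_id)))
  for (i in seq_len(nrow(ranges))) {
    g <- ranges$geometry[[i]]
    if (is.null(g)) next
    out[i, ] <- signed_distance_min(pts, g, species_id = ranges$species_id[i])
  }
  out
}

#' Scaled inverse-logit transform of distance to range
#'
#' Maps the signed distance from a survey point to a range margin onto (0, 1):
#' `1 / (1 + exp(-d / scale_km))`. Deep in-range (large negative distance) the
#' covariate asymptotes at 0, so the species intercept keeps its meaning of
#' core-range occupancy; far out-of-range it asymptotes at 1. The margin
#' itself maps to 0.5.
#'
#' @param distance_km signed distance(s), km (negative = in-range).
#' @param scale_km positive scale of the transform, km (200 km is a typical
#'   choice for continental-scale survey data; see
#'   [linearization_diagnostic()] for selecting it empirically).
#' @return values in (0, 1), same shape as `distance_km`.
#' @export
scaled_inverse_logit <- function(distance_km, scale_km = 200) {
  if (!is.numeric(scale_km) || length(scale_km) != 1 || scale_km <= 0) {
    abort("`scale_km` must be a single positive number.")
  }
  plogis(distance_km / scale_km)
}

#' Species-standardized elevation
#'
#' Linearly rescales raw elevation so a species' upper range limit maps to +1
#' and its lower limit to -1: `s = (2*elev - (upper + lower)) / (upper -
#' lower)`. `unstandardize_elevation()` is the exact inverse.
#'
#' @param elev_m elevation(s) in meters.
#' @param lower_m,upper_m species elevational limits in meters,
#'   `lower_m < upper_m`.
#' @export
standardize_elevation <- function(elev_m, lower_m, upper_m) {
  if (any(lower_m >= upper_m, na.rm = TRUE)) {
    abort("`lower_m` must be strictly below `upper_m`.")
  }
  (2 * elev_m - (upper_m + lower_m)) / (upper_m - lower_m)
}

#' @rdname standardize_elevation
#' @param s standardized elevation(s).
#' @export
unstandardize_elevation <- function(s, lower_m, upper_m) {
  if (any(lower_m >= upper_m, na.rm = TRUE)) {
    abort("`lower_m` must be strictly below `upper_m`.")
  }
  (s * (upper_m - lower_m) + (upper_m + lower_m)) / 2
}

#' Species x site matrix of standardized elevations
#'
#' @inheritParams signed_distance_matrix
#' @return species x site matrix; rows of `NA` for species lacking limits.
#' @export
std_elevation_matrix <- function(ranges, sites) {
  if (!"elev_m" %in% names(sites)) abort("`sites` needs an `elev_m` column.")
  out <- matrix(NA_real_, nrow(ranges), nrow(sites),
                dimnames = list(ranges$species_id, as.character(sites$site_id)))
  for (i in seq_len(nrow(ranges))) {
    lo <- ranges$elev_lower_m[i]; hi <- ranges$elev_upper_m[i]
    if (is.na(lo) || is.na(hi)) next
    out[i, ] <- standardize_elevation(sites$elev_m, lo, hi)
  }
  out
}

#' Choose a linearizing distance transform empirically
#'
#' Bins species-site cells by their signed distance to the range margin,
#' computes the naive occupancy proportion per bin (a cell counts as occupied
#' when it has at least one detection; imperfect detection is deliberately
#' ignored here -- the proportion is biased but adequate for choosing a
#' transform), and scores each candidate scale by the coefficient of
#' determination of a linear regression of the empirical logit of the bin
#' proportions on the transformed bin midpoints. The scale whose transform
#' best linearizes the relationship is selected; ties (and the degenerate
#' all-bins-equal case) resolve to the smallest candidate scale.
#'
#' Bins with a proportion of exactly 0 or 1 get the empirical-logit
#' correction (half a success and half a failure added) rather than being
#' dropped.
#'
#' @param detections long detection table (`species_id`, `site_id`, `visit`,
#'   `y`).
#' @param distances species x site signed distance matrix (km), as from
#'   [signed_distance_matrix()].
#' @param candidate_scales_km numeric vector of candidate scales (km).
#' @param n_bins number of equal-width distance bins (default 20).
#' @return an object of class `bmsom_linearization`: list with `table`
#'   (tibble: `scale_km`, `r_squared`), `selected_scale_km`, and
#'   `constant_proportions` flag.
#' @export
linearization_diagnostic <- function(detections, distances,
                                     candidate_scales_km = c(50, 100, 200, 400),
                                     n_bins = 20) {
  if (length(candidate_scales_km) < 1 || any(candidate_scales_km <= 0)) {
    abort("`candidate_scales_km` must be positive.")
  }
  occ <- detections |>
    dplyr::group_by(.data$species_id, .data$site_id) |>
    dplyr::summarise(occ = as.integer(any(.data$y == 1)), .groups = "drop")
  d <- distances[cbind(as.character(occ$species_id), as.character(occ$site_id))]
  keep <- is.finite(d)
  d <- d[keep]; occv <- occ$occ[keep]
  if (length(d) == 0) abort("no finite distances for observed cells.")
  span <- range(d)
  if (diff(span) <= 0 || n_bins < 2) abort("insufficient occupancy variation: need >= 2 non-degenerate distance bins.")
  breaks <- seq(span[1], span[2], length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  tab <- tibble(bin = bin, occ = occv) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$occ), .groups = "drop")
  if (nrow(tab) < 2) abort("insufficient occupancy variation: need >= 2 non-degenerate distance bins.")
  mid <- (breaks[tab$bin] + breaks[tab$bin + 1]) / 2
  # empirical-logit correction only where the raw proportion is 0 or 1
  k <- tab$k; n <- tab$n
  at_edge <- k == 0 | k == n
  p <- ifelse(at_edge, (k + 0.5) / (n + 1), k / n)
  lp <- qlogis(p)
  constant <- isTRUE(all(abs(lp - lp[1]) < 1e-12))
  scores <- vapply(candidate_scales_km, function(s) {
    if (constant) return(0)
    x <- scaled_inverse_logit(mid, s)
    if (sd(x) == 0) return(0)
    summary(lm(lp ~ x))$r.squared
  }, numeric(1))
  res <- tibble(scale_km = as.numeric(candidate_scales_km), r_squared = scores)
  ord <- order(-res$r_squared + 0, res$scale_km)
  best <- res$r_squared[ord[1]]
  sel <- min(res$scale_km[res$r_squared >= best - 1e-12])
  if (constant) {
    warn("bin proportions are constant across distance bins; all candidate scales score equally, returning the smallest.")
    sel <- min(res$scale_km)
  }
  structure(list(table = res, selected_scale_km = sel,
                 constant_proportions = constant,
                 bins = tibble(mid_km = mid, n = n, prop = p, logit_prop = lp)),
            class = "bmsom_linearization")
}

#' @export
print.bmsom_linearization <- function(x, ...) {
  cat("Distance-transform linearization diagnostic\n")
  print(x$table)
  cat(sprintf("selected scale: %g km%s\n", x$selected_scale_km,
              if (x$constant_proportions) " (constant proportions; tie-break)" else ""))
  invisible(x)
}

#' Build the covariate bundle for a model specification
#'
#' Assembles the occupancy and detection design data a [model_spec()] needs:
#' site-level covariates (centered and scaled, with the constants stored so
#' prediction points can be scaled identically), species-site range covariates
#' (the scaled inverse-logit distance transform `dist_range`, the
#' species-standardized elevation `elev_range` and its square `elev_range2` --
#' these keep their natural scales), and visit-level detection covariates.
#'
#' Recognised occupancy term names: `"dist_range"`, `"elev_range"`,
#' `"elev_range2"`, or any column of `sites`. Detection terms are columns of
#' `visits` (a long table `site_id`, `visit`, plus covariates) or of `sites`.
#'
#' @param ranges a [range_table()].
#' @param sites site table: `site_id`, `x_km`, `y_km`, optionally `elev_m`,
#'   `date` and further covariate columns.
#' @param spec a [model_spec()].
#' @param n_visits number of visits per site (used for visit-level design).
#' @param visits optional long visit table (`site_id`, `visit`, covariates).
#' @return an object of class `bmsom_bundle`.
#' @export
build_covariate_bundle <- function(ranges, sites, spec, n_visits, visits = NULL) {
  if (nrow(ranges) == 0) abort("empty species list: range table has no rows.")
  species <- as.character(ranges$species_id)
  site_ids <- as.character(sites$site_id)
  S <- length(species); J <- length(site_ids)
  occ_terms <- spec$occupancy
  det_terms <- spec$detection

  scaling <- list()
  psi_covs <- list()
  needs_dist <- "dist_range" %in% names(occ_terms)
  needs_elev_range <- any(c("elev_range", "elev_range2") %in% names(occ_terms))
  if (needs_dist) {
    dmat <- signed_distance_matrix(ranges, sites)
    miss <- species[!stats::complete.cases(dmat)]
    if (length(miss) > 0) {
      abort(paste0("term `dist_range` requested but range geometry is missing for species: ",
                   paste(miss, collapse = ", ")))
    }
  } else {
    dmat <- NULL
  }
  if (needs_elev_range) {
    smat <- std_elevation_matrix(ranges, sites)
    miss <- species[!stats::complete.cases(smat)]
    if (length(miss) > 0) {
      abort(paste0("elevational range covariates requested but elevational limits are missing for species: ",
                   paste(miss, collapse = ", ")))
    }
  } else {
    smat <- NULL
  }

  for (nm in names(occ_terms)) {
    if (nm == "dist_range") {
      psi_covs[[nm]] <- scaled_inverse_logit(dmat, spec$distance_scale_km)
    } else if (nm == "elev_range") {
      psi_covs[[nm]] <- smat
    } else if (nm == "elev_range2") {
      psi_covs[[nm]] <- smat^2
    } else {
      if (!nm %in% names(sites)) {
        abort(paste0("occupancy term `", nm, "` is not a recognised range covariate or a column of `sites`."))
      }
      v <- as.numeric(sites[[nm]])
      if (any(!is.finite(v))) abort(paste0("non-finite values in site covariate `", nm, "`."))
      ctr <- mean(v); scl <- sd(v)
      if (scl == 0) scl <- 1
      scaling[[nm]] <- c(center = ctr, scale = scl)
      psi_covs[[nm]] <- (v - ctr) / scl # length-J site vector, broadcast later
    }
  }

  theta_covs <- list()
  for (nm in names(det_terms)) {
    if (!is.null(visits) && nm %in% names(visits)) {
      wide <- visits |>
        dplyr::select("site_id", "visit", dplyr::all_of(nm)) |>
        tidyr::pivot_wider(names_from = "visit", values_from = dplyr::all_of(nm)) |>
        dplyr::arrange(match(.data$site_id, site_ids))
      m <- as.matrix(wide[, -1, drop = FALSE])
      if (nrow(m) != J || ncol(m) != n_visits) {
        abort(paste0("visit covariate `", nm, "` does not cover all sites x visits."))
      }
    } else if (nm %in% names(sites)) {
      m <- matrix(as.numeric(sites[[nm]]), J, n_visits)
    } else {
      abort(paste0("detection term `", nm, "` not found in `visits` or `sites`."))
    }
    if (any(!is.finite(m))) abort(paste0("non-finite values in detection covariate `", nm, "`."))
    ctr <- mean(m); scl <- sd(as.numeric(m))
    if (scl == 0) scl <- 1
    scaling[[paste0("det_", nm)]] <- c(center = ctr, scale = scl)
    theta_covs[[nm]] <- (m - ctr) / scl
  }

  structure(list(
    species = species, site_ids = site_ids, n_visits = n_visits,
    psi_covs = psi_covs, theta_covs = theta_covs,
    scaling = scaling, distances_km = dmat, std_elev = smat,
    spec = spec
  ), class = "bmsom_bundle")
}

#' @export
print.bmsom_bundle <- function(x, ...) {
  cat(sprintf("<covariate bundle: %d species, %d sites, %d visits>\n",
              length(x$species), length(x$site_ids), x$n_visits))
  cat("occupancy terms:", if (length(x$psi_covs)) paste(names(x$psi_covs), collapse = ", ") else "(intercept only)", "\n")
  cat("detection terms:", if (length(x$theta_covs)) paste(names(x$theta_covs), collapse = ", ") else "(intercept only)", "\n")
  invisible(x)
}
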