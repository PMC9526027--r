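#' Read and write long-format detection tables
#'
#' The canonical interchange format for detection histories is long CSV with
#' columns `species_id`, `site_id`, `visit`, `y` (binary). Missing
#' (species, site, visit) rows denote unsurveyed visits and become masked --
#' never zero-filled. Duplicate rows and `y` outside \{0, 1\} are errors.
#'
#' @param path CSV path.
#' @return a tibble (`read_detections_csv`); the input, invisibly
#'   (`write_detections_csv`).
#' @export
read_detections_csv <- function(path) {
  det <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "site_id", "visit", "y")
  miss <- setdiff(need, names(det))
  if (length(miss) > 0) abort(paste0("detection CSV lacks columns: ", paste(miss, collapse = ", ")))
  det <- as_tibble(det[need])
  det$species_id <- as.character(det$species_id)
  det$site_id <- as.character(det$site_id)
  det$visit <- as.integer(det$visit)
  bad <- which(!det$y %in% c(0, 1))
  if (length(bad) > 0) {
    abort(paste0("y outside {0,1} at rows: ", paste(head(bad, 5), collapse = ", ")))
  }
  det$y <- as.integer(det$y)
  dup <- which(duplicated(det[c("species_id", "site_id", "visit")]))
  if (length(dup) > 0) {
    abort(paste0("duplicate (species, site, visit) rows at: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  dplyr::arrange(det, .data$species_id, .data$site_id, .data$visit)
}

#' @rdname read_detections_csv
#' @param detections long detection tibble.
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(detections[c("species_id", "site_id", "visit", "y")],
                   path, row.names = FALSE)
  invisible(detections)
}

#' Read and write site tables
#'
#' Site CSVs carry `site_id`, projected coordinates `x_km`, `y_km`, and
#' optionally `elev_m`, ISO-8601 `date`, and covariate columns.
#'
#' @param path CSV path.
#' @export
read_sites_csv <- function(path) {
  s <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("site_id", "x_km", "y_km") %in% names(s))) {
    abort("site CSV needs columns site_id, x_km, y_km.")
  }
  s$site_id <- as.character(s$site_id)
  if ("date" %in% names(s)) s$date <- as.Date(s$date)
  s
}

#' @rdname read_sites_csv
#' @param sites site tibble.
#' @export
write_sites_csv <- function(sites, path) {
  s <- sites
  if ("date" %in% names(s)) s$date <- format(s$date, "%Y-%m-%d")
  utils::write.csv(s, path, row.names = FALSE)
  invisible(sites)
}

#' Write and read range geometries as GeoJSON
#'
#' Ranges are serialized as a GeoJSON FeatureCollection in a *projected*,
#' distance-preserving coordinate system (km units; the CRS name is recorded
#' in a top-level `crs_name` member and must not look geographic). Disc
#' geometries are written as 128-vertex polygons plus exact
#' `disc_center_x/y_km` and `disc_radius_km` properties, from which the
#' reader reconstructs the exact disc.
#'
#' @param ranges a [range_table()].
#' @param path GeoJSON path.
#' @param crs_name name of the projected CRS (informational).
#' @export
write_ranges_geojson <- function(ranges, path, crs_name = "local_km_plane") {
  feats <- purrr::map(seq_len(nrow(ranges)), function(i) {
    g <- ranges$geometry[[i]]
    if (is.null(g)) return(NULL)
    props <- list(species_id = ranges$species_id[i])
    if (inherits(g, "bmsom_geom") && g$type == "disc") {
      props$disc_center_x_km <- g$center[1]
      props$disc_center_y_km <- g$center[2]
      props$disc_radius_km <- g$radius
      ang <- seq(0, 2 * pi, length.out = 129)[-129]
      ring <- cbind(g$center[1] + g$radius * cos(ang),
                    g$center[2] + g$radius * sin(ang))
      rings <- list(ring)
    } else {
      rings <- g$rings
    }
    coords <- lapply(rings, function(r) {
      r <- rbind(r, r[1, , drop = FALSE]) # GeoJSON rings are closed
      lapply(seq_len(nrow(r)), function(v) c(r[v, 1], r[v, 2]))
    })
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  feats <- feats[!vapply(feats, is.null, logical(1))]
  fc <- list(type = "FeatureCollection", crs_name = crs_name,
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(ranges)
}

#' @rdname write_ranges_geojson
#' @param limits_csv optional CSV of elevational limits (`species_id`,
#'   `elev_lower_m`, `elev_upper_m`).
#' @param seasons_csv optional CSV of seasonal windows (`species_id`,
#'   `start_doy`, `end_doy`).
#' @param strict error (rather than warn) on unmatched species ids.
#' @export
read_ranges_geojson <- function(path, limits_csv = NULL, seasons_csv = NULL,
                                strict = FALSE) {
  fc <- jsonlite::read_json(path)
  crs <- fc$crs_name %||% ""
  if (grepl("4326|WGS84|longlat|geographic", crs, ignore.case = TRUE)) {
    abort(paste0("range CRS '", crs, "' looks geographic (unprojected); ",
                 "reproject to a distance-preserving planar CRS in km first."))
  }
  sp <- character(0); geoms <- list()
  for (f in fc$features) {
    sid <- as.character(f$properties$species_id)
    p <- f$properties
    if (!is.null(p$disc_radius_km)) {
      g <- geom_disc(c(p$disc_center_x_km, p$disc_center_y_km), p$disc_radius_km)
    } else {
      rings <- lapply(f$geometry$coordinates, function(r) {
        do.call(rbind, lapply(r, function(v) c(v[[1]], v[[2]])))
      })
      g <- geom_polygon_km(rings)
    }
    if (sid %in% sp) {
      # multiple features for one species: disjunct subranges
      prev <- geoms[[match(sid, sp)]]
      geoms[[match(sid, sp)]] <- c(if (inherits(prev, "bmsom_geom")) list(prev) else prev,
                                   list(g))
    } else {
      sp <- c(sp, sid)
      geoms <- c(geoms, list(g))
    }
  }
  lo <- hi <- rep(NA_real_, length(sp))
  st <- en <- rep(NA_real_, length(sp))
  note_unmatched <- function(ids, what) {
    un <- setdiff(ids, sp)
    if (length(un) > 0) {
      msg <- paste0(what, " present for species without geometry: ",
                    paste(un, collapse = ", "))
      if (strict) abort(msg) else warn(msg)
    }
    un
  }
  if (!is.null(limits_csv)) {
    lim <- utils::read.csv(limits_csv, stringsAsFactors = FALSE)
    lim$species_id <- as.character(lim$species_id)
    un <- note_unmatched(lim$species_id, "elevational limits")
    extra <- lim[lim$species_id %in% un, , drop = FALSE]
    m <- match(sp, lim$species_id)
    lo <- lim$elev_lower_m[m]; hi <- lim$elev_upper_m[m]
    if (nrow(extra) > 0) {
      sp <- c(sp, extra$species_id)
      geoms <- c(geoms, vector("list", nrow(extra)))
      lo <- c(lo, extra$elev_lower_m); hi <- c(hi, extra$elev_upper_m)
      st <- c(st, rep(NA_real_, nrow(extra))); en <- c(en, rep(NA_real_, nrow(extra)))
    }
  }
  if (!is.null(seasons_csv)) {
    sea <- utils::read.csv(seasons_csv, stringsAsFactors = FALSE)
    sea$species_id <- as.character(sea$species_id)
    note_unmatched(sea$species_id, "seasonal windows")
    m <- match(sp, sea$species_id)
    st <- sea$start_doy[m]; en <- sea$end_doy[m]
  }
  range_table(sp, geoms, elev_lower_m = lo, elev_upper_m = hi,
              season_start = st, season_end = en)
}

#' Write elevational limits / seasonal windows CSVs
#'
#' @param ranges a [range_table()].
#' @param path CSV path.
#' @export
write_limits_csv <- function(ranges, path) {
  keep <- !is.na(ranges$elev_lower_m) | !is.na(ranges$elev_upper_m)
  utils::write.csv(
    data.frame(species_id = ranges$species_id,
               elev_lower_m = ranges$elev_lower_m,
               elev_upper_m = ranges$elev_upper_m)[keep, ],
    path, row.names = FALSE)
  invisible(ranges)
}

#' @rdname write_limits_csv
#' @export
write_seasons_csv <- function(ranges, path) {
  keep <- !is.na(ranges$season_start)
  utils::write.csv(
    data.frame(species_id = ranges$species_id,
               start_doy = ranges$season_start,
               end_doy = ranges$season_end)[keep, ],
    path, row.names = FALSE)
  invisible(ranges)
}

#' Serialize a clip mask as long CSV
#'
#' @param mask a [new_clip_mask()].
#' @param path CSV path.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.csv(as_tibble(mask), path, row.names = FALSE)
  invisible(mask)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  sp <- id_levels(m$species_id); st <- id_levels(m$site_id)
  keep <- matrix(TRUE, length(sp), length(st), dimnames = list(sp, st))
  reason <- matrix(NA_character_, length(sp), length(st))
  keep[cbind(match(m$species_id, sp), match(m$site_id, st))] <- m$retained
  reason[cbind(match(m$species_id, sp), match(m$site_id, st))] <-
    ifelse(m$retained, NA_character_, as.character(m$reason))
  new_clip_mask(keep, reason)
}

#' Run the full pipeline from a config file
#'
#' Orchestrates simulate -> covariates -> clip -> fit -> loo -> predict from a
#' YAML/JSON config, writing versioned outputs, a log, and a machine-readable
#' run manifest (seed, config hash, convergence summary) into `out_dir`.
#' Stages: `simulate` (or external input paths), `covariates`, `clip`,
#' `fit`, `loo`, `predict`; any failure halts with the stage name.
#'
#' @param config path to a YAML/JSON config, or an equivalent named list. See
#'   the packaged demo config (`system.file("extdata", "demo_config.yml",
#'   package = "bmsom")`).
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = "bmsom_run") {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    if (grepl("[.]json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = logf, append = TRUE)
    inform(line)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
  }
  seed <- as.integer(cfg$seed %||% 1)
  manifest <- list(seed = seed, stages = character(0),
                   config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))))

  sim_cfg <- do.call(community_config,
                     c(cfg$simulate %||% list(), list(seed = seed)))
  sim <- stage("simulate", simulate_community(sim_cfg))
  write_detections_csv(sim$detections, file.path(out_dir, "detections.csv"))
  write_sites_csv(sim$sites, file.path(out_dir, "sites.csv"))
  write_ranges_geojson(sim$ranges, file.path(out_dir, "ranges.geojson"))
  manifest$stages <- c(manifest$stages, "simulate")
  manifest$species_order <- sim$ranges$species_id
  manifest$site_order <- sim$sites$site_id

  spec_args <- cfg$model %||% list()
  spec <- model_spec(
    occupancy = unlist(spec_args$occupancy %||%
                         c(elev_m = "random", dist_range = "random")),
    detection = unlist(spec_args$detection %||% c(time = "fixed")),
    variant = spec_args$variant %||% "bmsom",
    distance_scale_km = spec_args$distance_scale_km %||% 200
  )
  bundle <- stage("covariates",
                  build_covariate_bundle(sim$ranges, sim$sites, spec,
                                         n_visits = sim_cfg$n_visits,
                                         visits = sim$visits))

  mask <- NULL
  if (!is.null(cfg$clip$distance_km) && !is.null(bundle$distances_km)) {
    mask <- stage("clip", clip_by_distance(bundle$distances_km,
                                           cfg$clip$distance_km))
    viol <- validate_mask_against_detections(mask, sim$detections)
    if (nrow(viol) > 0) {
      abort(paste0("pipeline stage `clip` failed: ", nrow(viol),
                   " detections at clipped cells."))
    }
    write_mask_csv(mask, file.path(out_dir, "clip_mask.csv"))
    manifest$stages <- c(manifest$stages, "clip")
  }

  fit_args <- cfg$fit %||% list()
  fit <- stage("fit", fit_occupancy(
    spec, bundle, sim$detections, mask,
    chains = fit_args$chains %||% 2,
    warmup = fit_args$warmup %||% 400,
    draws = fit_args$draws %||% 400,
    seed = seed + 1
  ))
  manifest$stages <- c(manifest$stages, "fit")
  conv <- convergence_report(fit)
  manifest$convergence <- list(max_rhat = conv$max_rhat,
                               n_divergent = conv$n_divergent,
                               ebfmi = conv$ebfmi, pass = conv$pass)
  utils::write.csv(tidy(fit), file.path(out_dir, "posterior_summary.csv"),
                   row.names = FALSE)

  if (isTRUE(cfg$loo %||% TRUE)) {
    lo <- stage("loo", loo_psis(pointwise_loglik(fit)))
    manifest$stages <- c(manifest$stages, "loo")
    manifest$loo <- list(elpd = lo$elpd, se = lo$se, n_flagged = lo$n_flagged)
    utils::write.csv(lo$pointwise, file.path(out_dir, "loo_pointwise.csv"),
                     row.names = FALSE)
  }

  rich <- stage("predict", richness_profile(fit))
  utils::write.csv(rich, file.path(out_dir, "richness_profile.csv"),
                   row.names = FALSE)
  manifest$stages <- c(manifest$stages, "predict")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logmsg("pipeline complete: ", paste(manifest$stages, collapse = " -> "))
  invisible(manifest)
}
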