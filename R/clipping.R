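#' Clip masks: structural removal of species-site combinations
#'
#' A clip mask records, for every species x site cell, whether the cell is
#' retained in the likelihood and -- for removed cells -- why. Removed cells
#' are structural zeros: they are dropped from the likelihood entirely, so the
#' model never "sees" their non-detections. Reason codes follow a fixed
#' precedence when masks are combined: `barrier` > `geographic_distance` >
#' `standardized_elevation` > `temporal`.
#'
#' @param retained logical species x site matrix with dimnames.
#' @param reason character matrix of the same shape; `NA` where retained.
#' @return a long tibble of class `bmsom_mask` with columns `species_id`,
#'   `site_id`, `retained`, `reason`.
#' @export
new_clip_mask <- function(retained, reason = NULL) {
  if (is.null(dimnames(retained)) || is.null(rownames(retained))) {
    abort("`retained` needs species rownames and site colnames.")
  }
  if (is.null(reason)) {
    reason <- matrix(NA_character_, nrow(retained), ncol(retained))
  }
  if (!all(dim(reason) == dim(retained))) abort("`reason` dims must match `retained`.")
  if (any(!retained & is.na(reason))) abort("every removed cell needs a reason code.")
  out <- tibble(
    species_id = rep(rownames(retained), times = ncol(retained)),
    site_id = rep(colnames(retained), each = nrow(retained)),
    retained = as.logical(retained),
    reason = as.character(reason)
  )
  attr(out, "species") <- rownames(retained)
  attr(out, "sites") <- colnames(retained)
  class(out) <- c("bmsom_mask", class(out))
  out
}

#' @rdname new_clip_mask
#' @param mask a `bmsom_mask`.
#' @export
clip_mask_matrix <- function(mask) {
  sp <- attr(mask, "species"); st <- attr(mask, "sites")
  m <- matrix(mask$retained, length(sp), length(st), dimnames = list(sp, st))
  m
}

#' @rdname new_clip_mask
#' @param species,sites id vectors; `full_mask()` retains every cell.
#' @export
full_mask <- function(species, sites) {
  m <- matrix(TRUE, length(species), length(sites),
              dimnames = list(as.character(species), as.character(sites)))
  new_clip_mask(m)
}

reason_precedence <- c("barrier", "geographic_distance", "standardized_elevation", "temporal")

#' Biogeographic clipping by distance to range
#'
#' Removes species-site combinations farther than `threshold_km` from the
#' species' mapped range (400 km is the distance beyond which continental
#' survey data typically contain no detections). Cells exactly at the
#' threshold are retained.
#'
#' @param distances species x site signed-distance matrix (km), from
#'   [signed_distance_matrix()]. `NA` rows (no mapped geometry) are retained
#'   untouched.
#' @param threshold_km positive clip distance.
#' @return a [new_clip_mask()].
#' @export
clip_by_distance <- function(distances, threshold_km = 400) {
  if (!is.numeric(threshold_km) || threshold_km <= 0) abort("`threshold_km` must be positive.")
  keep <- is.na(distances) | distances <= threshold_km
  reason <- matrix(NA_character_, nrow(distances), ncol(distances))
  reason[!keep] <- "geographic_distance"
  new_clip_mask(keep, reason)
}

#' Biogeographic clipping by standardized elevation
#'
#' Removes species-site combinations whose species-standardized elevation
#' falls outside `[lower, upper]` (the bounds -3 and 3 are standardized
#' elevations beyond which field datasets typically contain no detections).
#' Species with no elevational limits (`NA` rows) are untouched, with a
#' warning.
#'
#' @param std_elev species x site standardized-elevation matrix, from
#'   [std_elevation_matrix()].
#' @param lower,upper retained band (inclusive), `lower < upper`.
#' @return a [new_clip_mask()].
#' @export
clip_by_std_elevation <- function(std_elev, lower = -3, upper = 3) {
  if (lower >= upper) abort("`lower` must be below `upper`.")
  no_limits <- rownames(std_elev)[!stats::complete.cases(std_elev)]
  if (length(no_limits) > 0) {
    warn(paste0("no elevational limits for: ", paste(no_limits, collapse = ", "),
                "; these species are untouched by the elevational clip."))
  }
  keep <- is.na(std_elev) | (std_elev >= lower & std_elev <= upper)
  reason <- matrix(NA_character_, nrow(std_elev), ncol(std_elev))
  reason[!keep] <- "standardized_elevation"
  new_clip_mask(keep, reason)
}

in_season <- function(doy, start, end) {
  if (start <= end) doy >= start & doy <= end else doy >= start | doy <= end
}

#' Temporal clipping for migratory species
#'
#' Removes species-site-visit combinations surveyed outside a species'
#' seasonal presence window (day-of-year; wrap-around windows like 300..60
#' are supported). Resident species (no window) keep all visits. A
#' species-site cell is removed entirely -- reason `temporal` -- when all of
#' its visits fall outside the window.
#'
#' @param visit_doy site x visit matrix of survey days-of-year, or a length-J
#'   vector (same day for every visit).
#' @param ranges a [range_table()] carrying `season_start` / `season_end`.
#' @param sites site ids matching the rows of `visit_doy`.
#' @param n_visits number of visits (needed when `visit_doy` is a vector).
#' @return a list of class `bmsom_temporal_mask`: `visit_retained` (long
#'   tibble `species_id`, `site_id`, `visit`, `retained`) and `cell_mask`
#'   (a [new_clip_mask()] for fully-removed cells).
#' @export
clip_temporal <- function(visit_doy, ranges, sites, n_visits = NULL) {
  if (is.vector(visit_doy)) {
    if (is.null(n_visits)) abort("give `n_visits` when `visit_doy` is a vector.")
    visit_doy <- matrix(visit_doy, length(visit_doy), n_visits)
  }
  J <- nrow(visit_doy); K <- ncol(visit_doy)
  sites <- as.character(sites)
  if (length(sites) != J) abort("`sites` must match the rows of `visit_doy`.")
  if (any(visit_doy < 1 | visit_doy > 366, na.rm = TRUE)) {
    abort("days-of-year must lie in 1..366.")
  }
  sp <- ranges$species_id
  S <- length(sp)
  vis <- array(TRUE, c(S, J, K))
  for (i in seq_len(S)) {
    st <- ranges$season_start[i]; en <- ranges$season_end[i]
    if (is.na(st) || is.na(en)) next # resident
    vis[i, , ] <- in_season(visit_doy, st, en)
  }
  cell_keep <- apply(vis, c(1, 2), any)
  dimnames(cell_keep) <- list(sp, sites)
  reason <- matrix(NA_character_, S, J)
  reason[!cell_keep] <- "temporal"
  visit_retained <- tidyr::expand_grid(species_id = sp, site_id = sites,
                                       visit = seq_len(K)) |>
    dplyr::arrange(.data$species_id, .data$site_id, .data$visit)
  visit_retained$retained <- as.logical(vis[cbind(match(visit_retained$species_id, sp),
                                                  match(visit_retained$site_id, sites),
                                                  visit_retained$visit)])
  structure(list(visit_retained = visit_retained,
                 cell_mask = new_clip_mask(cell_keep, reason),
                 visit_array = vis),
            class = "bmsom_temporal_mask")
}

#' Combine clip masks
#'
#' Logical AND of the retained sets. A cell removed by several rules keeps the
#' reason of the highest-precedence rule (`barrier` > `geographic_distance` >
#' `standardized_elevation` > `temporal`).
#'
#' @param ... `bmsom_mask` objects (or a single list of them) over identical
#'   species and sites.
#' @return a [new_clip_mask()].
#' @export
combine_masks <- function(...) {
  masks <- list(...)
  if (length(masks) == 1 && !inherits(masks[[1]], "bmsom_mask")) masks <- masks[[1]]
  masks <- lapply(masks, function(m) {
    if (inherits(m, "bmsom_temporal_mask")) m$cell_mask else m
  })
  if (length(masks) == 0) abort("no masks given.")
  sp <- attr(masks[[1]], "species"); st <- attr(masks[[1]], "sites")
  for (m in masks) {
    if (!identical(attr(m, "species"), sp) || !identical(attr(m, "sites"), st)) {
      abort("masks have mismatched species/site dimensions.")
    }
  }
  keep <- Reduce(`&`, lapply(masks, clip_mask_matrix))
  reason <- matrix(NA_character_, length(sp), length(st), dimnames = list(sp, st))
  # fill reasons by precedence: later assignments never overwrite earlier ones
  for (r in reason_precedence) {
    for (m in masks) {
      rm_ <- matrix(!m$retained & m$reason == r, length(sp), length(st))
      rm_[is.na(rm_)] <- FALSE
      fill <- rm_ & is.na(reason)
      reason[fill] <- r
    }
  }
  new_clip_mask(keep, reason)
}

#' Detections at clipped cells (range-map defects)
#'
#' A detection at a removed cell contradicts the clipping: the range
#' information is wrong (an error of omission), and model fitting refuses to
#' proceed until the range map is fixed. Returns all offending cells.
#'
#' @param mask a [new_clip_mask()].
#' @param detections long detection table.
#' @return tibble of violations (`species_id`, `site_id`, `n_detections`);
#'   zero rows when the mask is consistent with the data.
#' @export
validate_mask_against_detections <- function(mask, detections) {
  det_cells <- detections |>
    dplyr::filter(.data$y == 1) |>
    dplyr::count(.data$species_id, .data$site_id, name = "n_detections")
  removed <- dplyr::filter(as_tibble(mask), !.data$retained)
  dplyr::inner_join(det_cells,
                    removed[, c("species_id", "site_id", "reason")],
                    by = c("species_id", "site_id"))
}

#' Maximum detection distance report
#'
#' Reports, over all cells with at least one detection, the largest signed
#' distance to the range margin -- the empirical support on which a clipping
#' threshold can be based (the package does not choose the threshold
#' automatically).
#'
#' @param detections long detection table.
#' @param distances species x site signed-distance matrix (km).
#' @return a one-row tibble: `max_detection_distance_km`, `n_detected_cells`.
#' @export
max_detection_distance <- function(detections, distances) {
  det_cells <- detections |>
    dplyr::filter(.data$y == 1) |>
    dplyr::distinct(.data$species_id, .data$site_id)
  d <- distances[cbind(as.character(det_cells$species_id),
                       as.character(det_cells$site_id))]
  tibble(max_detection_distance_km = suppressWarnings(max(d, na.rm = TRUE)),
         n_detected_cells = nrow(det_cells))
}
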