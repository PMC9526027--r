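#' Range geometries in a projected plane
#'
#' Range geometries are planar (distance-preserving projection, km units).
#' Two kinds are supported: exact discs (`geom_disc()`), for which the signed
#' distance has the closed form `|p - center| - radius`, and (multi)polygons
#' (`geom_polygon_km()`), for which distance is computed against boundary
#' segments and containment by even-odd ray casting. A multipolygon is a list
#' of rings; interior rings (holes) are handled naturally by the even-odd
#' rule.
#'
#' @param center numeric length-2, disc center (km).
#' @param radius disc radius in km, > 0.
#' @param rings a single n x 2 matrix or a list of n x 2 matrices of ring
#'   vertices in km. Rings need not be explicitly closed.
#' @return an object of class `bmsom_geom`.
#' @examples
#' g <- geom_disc(c(0, 0), 100)
#' signed_distance(cbind(0, 0), g) # -100 at the center
#' @export
geom_disc <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 2 || !all(is.finite(center))) {
    abort("`center` must be a finite length-2 numeric (km).")
  }
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) || radius <= 0) {
    abort("`radius` must be a single positive number (km); zero-area ranges are not allowed.")
  }
  structure(list(type = "disc", center = center, radius = radius),
            class = "bmsom_geom")
}

#' @rdname geom_disc
#' @export
geom_polygon_km <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  if (!is.list(rings) || length(rings) == 0) {
    abort("`rings` must be a matrix or non-empty list of matrices.")
  }
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    if (ncol(r) != 2 || nrow(r) < 3 || !all(is.finite(r))) {
      abort("each ring must be a finite n x 2 matrix with n >= 3.")
    }
    # drop an explicit closing vertex; closure is implied
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3) abort("degenerate ring: fewer than 3 distinct vertices.")
    r
  })
  areas <- vapply(rings, ring_area, numeric(1))
  if (sum(abs(areas)) <= 0) abort("degenerate (zero-area) polygon geometry.")
  structure(list(type = "multipolygon", rings = rings), class = "bmsom_geom")
}

#' @export
print.bmsom_geom <- function(x, ...) {
  if (x$type == "disc") {
    cat(sprintf("<disc range: center (%.1f, %.1f) km, radius %.1f km>\n",
                x$center[1], x$center[2], x$radius))
  } else {
    cat(sprintf("<polygon range: %d ring(s), %d vertices>\n",
                length(x$rings), sum(vapply(x$rings, nrow, integer(1)))))
  }
  invisible(x)
}

# shoelace signed area of one ring
ring_area <- function(r) {
  n <- nrow(r)
  j <- c(n, seq_len(n - 1))
  sum(r[j, 1] * r[, 2] - r[, 1] * r[j, 2]) / 2
}

# even-odd ray casting; pts: m x 2, rings: list of n x 2. Returns logical m.
points_in_rings <- function(pts, rings) {
  inside <- rep(FALSE, nrow(pts))
  for (r in rings) {
    n <- nrow(r)
    x1 <- r[, 1]; y1 <- r[, 2]
    j <- c(2:n, 1)
    x2 <- r[j, 1]; y2 <- r[j, 2]
    for (i in seq_len(nrow(pts))) {
      px <- pts[i, 1]; py <- pts[i, 2]
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      if (sum(crosses) %% 2L == 1L) inside[i] <- !inside[i]
    }
  }
  inside
}

# min distance from each point to the boundary segments of the rings
points_dist_to_boundary <- function(pts, rings) {
  d2 <- rep(Inf, nrow(pts))
  for (r in rings) {
    n <- nrow(r)
    j <- c(2:n, 1)
    ax <- r[, 1]; ay <- r[, 2]
    bx <- r[j, 1]; by <- r[j, 2]
    vx <- bx - ax; vy <- by - ay
    vv <- vx * vx + vy * vy
    vv[vv == 0] <- 1 # degenerate segment: treat as point a
    for (i in seq_len(nrow(pts))) {
      px <- pts[i, 1]; py <- pts[i, 2]
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / vv))
      dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
      d2[i] <- min(d2[i], min(dx * dx + dy * dy))
    }
  }
  sqrt(d2)
}

#' Signed distance from survey points to a range margin
#'
#' Negative inside the range, positive outside, zero exactly on the boundary.
#' For disc geometries the closed form `|p - center| - radius` is used; for
#' polygons the distance to the nearest boundary segment, signed by even-odd
#' containment. For a range made of several geometries (e.g. disjunct
#' subranges) use [signed_distance_min()].
#'
#' @param pts an m x 2 matrix (or data frame with columns `x_km`, `y_km`) of
#'   point coordinates in the same projection as the geometry, km units.
#' @param geom a [geom_disc()] / [geom_polygon_km()] object.
#' @param species_id optional id used in error messages.
#' @return numeric vector of length m, km.
#' @export
signed_distance <- function(pts, geom, species_id = NULL) {
  pts <- as_points_matrix(pts)
  if (is.null(geom) || !inherits(geom, "bmsom_geom")) {
    abort(paste0("empty or invalid range geometry",
                 if (!is.null(species_id)) paste0(" for species '", species_id, "'")))
  }
  if (geom$type == "disc") {
    sqrt((pts[, 1] - geom$center[1])^2 + (pts[, 2] - geom$center[2])^2) - geom$radius
  } else {
    d <- points_dist_to_boundary(pts, geom$rings)
    inside <- points_in_rings(pts, geom$rings)
    ifelse(inside, -d, d)
  }
}

#' @rdname signed_distance
#' @param geoms a list of `bmsom_geom` objects forming one species' range;
#'   the signed distance to the union is the minimum over components of the
#'   per-component signed rule (negative once inside any component).
#' @export
signed_distance_min <- function(pts, geoms, species_id = NULL) {
  if (inherits(geoms, "bmsom_geom")) geoms <- list(geoms)
  if (length(geoms) == 0) {
    abort(paste0("empty range geometry",
                 if (!is.null(species_id)) paste0(" for species '", species_id, "'")))
  }
  d <- do.call(pmin, lapply(geoms, function(g) signed_distance(pts, g, species_id)))
  d
}

as_points_matrix <- function(pts) {
  if (is.data.frame(pts)) {
    if (!all(c("x_km", "y_km") %in% names(pts))) {
      abort("point data frames need columns `x_km` and `y_km`.")
    }
    pts <- cbind(pts$x_km, pts$y_km)
  }
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2) abort("points must be m x 2 (x_km, y_km).")
  pts
}

# convex-hull based placement helper: max distance from any site to a point
max_dist_to_points <- function(pt, pts) {
  max(sqrt((pts[, 1] - pt[1])^2 + (pts[, 2] - pt[2])^2))
}
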