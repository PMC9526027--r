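#' Specify a multi-species occupancy model
#'
#' A model specification names the occupancy and detection terms, says which
#' occupancy coefficients get species-level random slopes, and sets the
#' hierarchical priors. Species random intercepts for both occupancy (`a_i`)
#' and detection (`c_i`) are always present and are modeled as a correlated
#' bivariate pair -- the minimum random-effects structure a multi-species
#' occupancy model requires.
#'
#' Three variants are supported:
#' * `"msom"` -- a traditional MSOM: no range covariates (but any site
#'   covariates, e.g. a random elevation slope, are allowed).
#' * `"bmsom"` -- an MSOM whose occupancy terms include one or more range
#'   covariates (`dist_range`, `elev_range`, `elev_range2`), each normally
#'   given a species random slope.
#' * `"augmented"` -- a data-augmented MSOM: the observed species plus
#'   `n_pseudospecies` all-zero pseudospecies, each a community member with
#'   probability `Omega` (estimated). Species-specific covariates (range
#'   covariates) are not allowed in this variant, mirroring how data
#'   augmentation is used when species identities are unknown.
#'
#' @param occupancy named character vector of occupancy terms:
#'   `c(term = "random")` for a species random slope, `c(term = "fixed")` for
#'   a single shared coefficient. Term names are resolved by
#'   [build_covariate_bundle()] (range covariates or columns of the site
#'   table). May be empty (intercept-only occupancy).
#' @param detection named character vector of detection terms; currently all
#'   detection slopes are fixed effects (`"fixed"`); the species random
#'   detection intercept is always present.
#' @param variant `"msom"`, `"bmsom"` or `"augmented"`.
#' @param distance_scale_km scale of the inverse-logit distance transform
#'   (km), used when `dist_range` is among the occupancy terms.
#' @param n_pseudospecies number of all-zero pseudospecies (augmented variant
#'   only).
#' @param priors a list as produced by [prior_settings()].
#' @return an object of class `bmsom_spec`.
#' @examples
#' # traditional MSOM with a random elevation slope
#' m1 <- model_spec(occupancy = c(elev_m = "random"), variant = "msom")
#' # bMSOM: adds the distance-to-range covariate
#' m2 <- model_spec(occupancy = c(elev_m = "random", dist_range = "random"),
#'                  variant = "bmsom")
#' @export
model_spec <- function(occupancy = character(),
                       detection = character(),
                       variant = c("msom", "bmsom", "augmented"),
                       distance_scale_km = 200,
                       n_pseudospecies = 0,
                       priors = prior_settings()) {
  variant <- match.arg(variant)
  occupancy <- validate_terms(occupancy, "occupancy")
  detection <- validate_terms(detection, "detection")
  if (any(detection == "random")) {
    abort("species random slopes on detection covariates are not supported; detection terms must be \"fixed\".")
  }
  range_terms <- intersect(names(occupancy), c("dist_range", "elev_range", "elev_range2"))
  if (variant == "msom" && length(range_terms) > 0) {
    abort(paste0("variant \"msom\" cannot include range covariates (",
                 paste(range_terms, collapse = ", "),
                 "); use variant = \"bmsom\"."))
  }
  if (variant == "augmented") {
    if (length(range_terms) > 0) {
      abort("the data-augmented variant excludes species-specific range covariates.")
    }
    if (n_pseudospecies < 1) abort("augmented variant needs n_pseudospecies >= 1.")
  } else {
    n_pseudospecies <- 0
  }
  if (!is.numeric(distance_scale_km) || distance_scale_km <= 0) {
    abort("`distance_scale_km` must be positive.")
  }
  structure(list(
    variant = variant,
    occupancy = occupancy,
    detection = detection,
    distance_scale_km = distance_scale_km,
    n_pseudospecies = as.integer(n_pseudospecies),
    priors = priors
  ), class = "bmsom_spec")
}

validate_terms <- function(x, what) {
  if (length(x) == 0) return(setNames(character(0), character(0)))
  if (is.null(names(x)) || any(names(x) == "")) {
    abort(paste0(what, " terms must be a named character vector, e.g. c(elev = \"random\")."))
  }
  x <- vapply(x, as.character, character(1))
  bad <- !x %in% c("fixed", "random")
  if (any(bad)) abort(paste0(what, " term types must be \"fixed\" or \"random\"."))
  if (anyDuplicated(names(x))) abort(paste0("duplicate ", what, " term names."))
  x
}

#' Hierarchical prior settings
#'
#' Weakly-informative defaults: Normal(0, 2.5) for population means and fixed
#' coefficients, Half-Normal(0, 1) for hierarchical standard deviations, a
#' uniform prior on (-1, 1) for the occupancy-detection intercept correlation,
#' and Uniform(0, 1) for the data-augmentation inclusion probability Omega.
#' All scales are on the logit scale of the linear predictors.
#'
#' @param mean_loc,mean_scale location/scale of the normal prior on population
#'   means and fixed coefficients.
#' @param sd_scale scale of the half-normal prior on hierarchical SDs.
#' @export
prior_settings <- function(mean_loc = 0, mean_scale = 2.5, sd_scale = 1) {
  if (mean_scale <= 0 || sd_scale <= 0) abort("prior scales must be positive.")
  list(mean_loc = mean_loc, mean_scale = mean_scale, sd_scale = sd_scale)
}

#' @export
print.bmsom_spec <- function(x, ...) {
  cat(sprintf("<bmsom model spec: variant \"%s\">\n", x$variant))
  fmt <- function(tt) {
    if (length(tt) == 0) return("(intercept only)")
    paste(sprintf("%s [%s]", names(tt), tt), collapse = ", ")
  }
  cat(" occupancy:", fmt(x$occupancy), "\n")
  cat(" detection:", fmt(x$detection), "\n")
  if (x$variant == "augmented") {
    cat(" pseudospecies:", x$n_pseudospecies, "\n")
  }
  invisible(x)
}
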