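#' Marginalized log-likelihood of one species-site detection history
#'
#' The latent occupancy state `Z` is summed out analytically:
#' `log[ psi * prod_k theta_k^y_k (1-theta_k)^(1-y_k) + (1-psi) * 1{sum(y)=0} ]`,
#' computed stably on the log scale (log-sum-exp for the all-zero branch).
#' With every visit masked the history carries no information and the
#' log-likelihood is 0. A detection with `psi = 0` is impossible: `-Inf` is
#' returned with a warning.
#'
#' @param psi occupancy probability (scalar).
#' @param theta per-visit detection probabilities.
#' @param y binary detection history, same length as `theta`.
#' @param visit_mask logical; `FALSE` visits are excluded (unsurveyed or
#'   temporally clipped). Default: all visits included.
#' @return scalar log-likelihood.
#' @export
cell_loglik <- function(psi, theta, y, visit_mask = NULL) {
  if (length(theta) != length(y)) abort("`theta` and `y` lengths differ.")
  if (!is.null(visit_mask)) {
    theta <- theta[visit_mask]
    y <- y[visit_mask]
  }
  if (length(y) == 0) return(0)
  lp_det <- sum(ifelse(y == 1, log(theta), log1p(-theta)))
  if (sum(y) > 0) {
    if (psi <= 0) {
      warn("detection with psi = 0: impossible history, returning -Inf.")
      return(-Inf)
    }
    return(log(psi) + lp_det)
  }
  logsumexp(c(log(psi) + lp_det, log1p(-psi)))
}

#' Occupancy and detection probabilities from parameters
#'
#' Applies the logit-linear model: `logit(psi_ij) = a_i + sum_m coef_m *
#' U_m[i,j]` and `logit(theta_ijk) = c_i + sum_q d_q * W_q[j,k]`, where each
#' occupancy coefficient is either a scalar (fixed effect) or a per-species
#' vector (random slopes), and the covariates come from a
#' [build_covariate_bundle()].
#'
#' @param params list with `a` (length-S), `c` (length-S), `coefs` (named
#'   list matching `bundle$psi_covs`: scalar or length-S numeric each) and
#'   `d` (named numeric matching `bundle$theta_covs`).
#' @param bundle a [build_covariate_bundle()].
#' @return list with `psi` (S x J matrix) and `theta` (S x J x K array).
#' @export
linear_predictors <- function(params, bundle) {
  S <- length(bundle$species); J <- length(bundle$site_ids); K <- bundle$n_visits
  if (length(params$a) != S || length(params$c) != S) {
    abort("`params$a` and `params$c` must have one entry per species.")
  }
  lp <- matrix(params$a, S, J)
  for (nm in names(bundle$psi_covs)) {
    cov <- bundle$psi_covs[[nm]]
    coef <- params$coefs[[nm]]
    if (is.null(coef)) abort(paste0("no coefficient supplied for occupancy term `", nm, "`."))
    if (!all(is.finite(if (is.matrix(cov)) cov else cov))) {
      abort(paste0("non-finite covariate in occupancy term `", nm, "`."))
    }
    if (is.matrix(cov)) {
      lp <- lp + coef * cov # coef scalar or length-S (recycled by row)
    } else {
      lp <- lp + outer(if (length(coef) == 1) rep(coef, S) else coef, cov)
    }
  }
  psi <- plogis(lp)
  dimnames(psi) <- list(bundle$species, bundle$site_ids)
  theta <- array(NA_real_, c(S, J, K),
                 dimnames = list(bundle$species, bundle$site_ids, NULL))
  for (k in seq_len(K)) {
    lt <- matrix(params$c, S, J)
    for (nm in names(bundle$theta_covs)) {
      w <- bundle$theta_covs[[nm]]
      if (!all(is.finite(w))) abort(paste0("non-finite covariate in detection term `", nm, "`."))
      lt <- lt + params$d[[nm]] * matrix(w[, k], S, J, byrow = TRUE)
    }
    theta[, , k] <- plogis(lt)
  }
  list(psi = psi, theta = theta)
}

#' Joint log-probability of the dataset (marginalized likelihood + priors)
#'
#' Sums [cell_loglik()] over retained cells (removed cells contribute exactly
#' 0) and, optionally, adds the hierarchical prior terms: bivariate-normal
#' species intercepts with hyperpriors on their means, SDs and correlation,
#' normal random-slope deviations with hyperpriors, and normal priors on fixed
#' coefficients. Refuses to evaluate when the mask removes cells containing
#' detections (a range-map defect to fix upstream).
#'
#' @inheritParams linear_predictors
#' @param params as in [linear_predictors()], plus (when `include_priors`)
#'   hyperparameters `mu_a`, `sigma_a`, `mu_c`, `sigma_c`, `rho` and, per
#'   random slope `m`, `hyper` entries `list(mu, sigma)`; and optionally
#'   `omega` for augmented models.
#' @param detections long detection table covering the bundle's species/sites.
#' @param mask a [new_clip_mask()]; default retains everything.
#' @param visit_array optional S x J x K logical array of retained visits
#'   (from [clip_temporal()] and/or ragged visit coverage).
#' @param include_priors add the hierarchical prior density (default `TRUE`).
#' @param spec optional [model_spec()]; defaults to the bundle's.
#' @return scalar log posterior density (unnormalized).
#' @export
dataset_logprob <- function(params, bundle, detections, mask = NULL,
                            visit_array = NULL, include_priors = TRUE,
                            spec = NULL) {
  spec <- spec %||% bundle$spec
  if (is.null(mask)) mask <- full_mask(bundle$species, bundle$site_ids)
  viol <- validate_mask_against_detections(mask, detections)
  if (nrow(viol) > 0) {
    abort(paste0("detections at ", nrow(viol),
                 " clipped cell(s) (range-map errors of omission); ",
                 "fix the range data or the mask before fitting."))
  }
  da <- as_detection_array(detections, bundle$species, bundle$site_ids,
                           bundle$n_visits)
  vm <- da$observed
  if (!is.null(visit_array)) vm <- vm & visit_array
  lp <- linear_predictors(params, bundle)
  keep <- clip_mask_matrix(mask)
  ll <- 0
  S <- length(bundle$species); J <- length(bundle$site_ids)
  for (i in seq_len(S)) {
    for (j in seq_len(J)) {
      if (!keep[i, j]) next
      ll <- ll + cell_loglik(lp$psi[i, j], lp$theta[i, j, ], da$y[i, j, ], vm[i, j, ])
    }
  }
  if (spec$variant == "augmented") {
    if (is.null(params$omega)) abort("augmented variant needs `params$omega`.")
    # recompute per-species sums with the inclusion indicator marginalized
    ll <- 0
    for (i in seq_len(S)) {
      cl <- vapply(seq_len(J), function(j) {
        if (!keep[i, j]) return(0)
        cell_loglik(lp$psi[i, j], lp$theta[i, j, ], da$y[i, j, ], vm[i, j, ])
      }, numeric(1))
      observed <- sum(da$y[i, , ][vm[i, , ]]) > 0
      ll <- ll + augmented_species_logprob(params$omega, cl, observed)
    }
  }
  if (!include_priors) return(ll)
  ll + hierarchical_logprior(params, bundle, spec)
}

# bivariate-normal + hyperprior density of the hierarchical structure
hierarchical_logprior <- function(params, bundle, spec) {
  pr <- spec$priors
  lp <- 0
  # species intercept pair (a_i, c_i) ~ BVN(mu, Sigma)
  mu_a <- params$mu_a %||% 0; mu_c <- params$mu_c %||% 0
  sigma_a <- params$sigma_a %||% 1; sigma_c <- params$sigma_c %||% 1
  rho <- params$rho %||% 0
  lp <- lp + sum(dbvnorm_log(params$a, params$c, mu_a, mu_c, sigma_a, sigma_c, rho))
  lp <- lp + stats::dnorm(mu_a, pr$mean_loc, pr$mean_scale, log = TRUE) +
    stats::dnorm(mu_c, pr$mean_loc, pr$mean_scale, log = TRUE) +
    dhalfnorm_log(sigma_a, pr$sd_scale) + dhalfnorm_log(sigma_c, pr$sd_scale) +
    log(0.5) # uniform(-1, 1) on rho
  for (nm in names(bundle$psi_covs)) {
    coef <- params$coefs[[nm]]
    if (length(coef) > 1) { # random slope
      h <- params$hyper[[nm]] %||% list(mu = 0, sigma = 1)
      lp <- lp + sum(stats::dnorm(coef, h$mu, h$sigma, log = TRUE)) +
        stats::dnorm(h$mu, pr$mean_loc, pr$mean_scale, log = TRUE) +
        dhalfnorm_log(h$sigma, pr$sd_scale)
    } else {
      lp <- lp + stats::dnorm(coef, pr$mean_loc, pr$mean_scale, log = TRUE)
    }
  }
  for (nm in names(bundle$theta_covs)) {
    lp <- lp + stats::dnorm(params$d[[nm]], pr$mean_loc, pr$mean_scale, log = TRUE)
  }
  lp # omega ~ Uniform(0,1): density 0 on the log scale
}

dbvnorm_log <- function(x, y, mx, my, sx, sy, rho) {
  zx <- (x - mx) / sx; zy <- (y - my) / sy
  q <- (zx^2 - 2 * rho * zx * zy + zy^2) / (1 - rho^2)
  -log(2 * pi) - log(sx) - log(sy) - 0.5 * log(1 - rho^2) - q / 2
}

dhalfnorm_log <- function(x, scale) {
  if (x < 0) return(-Inf)
  log(2) + stats::dnorm(x, 0, scale, log = TRUE)
}

#' Log-probability of a species' full history under data augmentation
#'
#' In the data-augmented model each (pseudo)species belongs to the community
#' with probability `omega`. An observed species is necessarily a member:
#' `log(omega) + sum_j cell_loglik`. A never-observed species (or
#' pseudospecies) marginalizes membership:
#' `log[(1 - omega) + omega * exp(sum_j cell_loglik)]`, via log-sum-exp.
#'
#' @param omega community inclusion probability, in (0, 1\].
#' @param cell_logliks per-site marginalized log-likelihoods for the species
#'   (all-zero histories for a never-observed species).
#' @param observed was the species detected at least once?
#' @return scalar log-probability.
#' @export
augmented_species_logprob <- function(omega, cell_logliks, observed) {
  if (omega < 0 || omega > 1) abort("`omega` must lie in [0, 1].")
  s <- sum(cell_logliks)
  if (observed) return(log(omega) + s)
  if (omega == 1) return(s)
  if (omega == 0) return(0)
  logsumexp(c(log1p(-omega), log(omega) + s))
}

#' Dense detection array from a long detection table
#'
#' Species and sites are ordered lexicographically (stable across
#' round-trips). Missing (species, site, visit) rows become masked visits --
#' not zero-filled.
#'
#' @param detections long detection table (`species_id`, `site_id`, `visit`,
#'   `y`).
#' @param species,sites id orderings to use; default: lexicographic over the
#'   ids present.
#' @param n_visits number of visit slots; default: max visit index present.
#' @return list with `y` (S x J x K integer array, 0 where masked),
#'   `observed` (logical S x J x K), `species`, `sites`.
#' @export
as_detection_array <- function(detections, species = NULL, sites = NULL,
                               n_visits = NULL) {
  species <- species %||% id_levels(detections$species_id)
  sites <- sites %||% id_levels(detections$site_id)
  n_visits <- n_visits %||% max(detections$visit)
  i <- match(as.character(detections$species_id), species)
  j <- match(as.character(detections$site_id), sites)
  k <- as.integer(detections$visit)
  if (anyNA(i) || anyNA(j)) abort("detections contain ids missing from `species`/`sites`.")
  if (any(k < 1 | k > n_visits)) abort("visit index outside 1..n_visits.")
  if (!all(detections$y %in% c(0L, 1L))) {
    bad <- which(!detections$y %in% c(0L, 1L))
    abort(paste0("y outside {0,1} at rows: ", paste(head(bad, 5), collapse = ", ")))
  }
  idx <- cbind(i, j, k)
  if (anyDuplicated(idx)) {
    bad <- which(duplicated(idx))
    abort(paste0("duplicate (species, site, visit) rows: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  y <- array(0L, c(length(species), length(sites), n_visits),
             dimnames = list(species, sites, NULL))
  observed <- array(FALSE, dim(y), dimnames = dimnames(y))
  y[idx] <- as.integer(detections$y)
  observed[idx] <- TRUE
  list(y = y, observed = observed, species = species, sites = sites)
}
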