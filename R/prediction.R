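#' Conditional occupancy given a detection history
#'
#' Posterior probability that the latent occupancy state is 1 given the
#' observed history: 1 after any detection; otherwise the Bayes update
#' `psi * prod_k (1 - theta_k) / (psi * prod_k (1 - theta_k) + 1 - psi)`.
#'
#' @param psi occupancy probability (scalar or vector).
#' @param theta per-visit detection probabilities (vector, or matrix with
#'   rows matching `psi`).
#' @param y binary history, same shape as `theta`.
#' @param visit_mask logical; masked visits are ignored.
#' @return probability/ies that Z = 1.
#' @export
conditional_occupancy <- function(psi, theta, y, visit_mask = NULL) {
  theta <- rbind(theta); y <- rbind(y)
  if (!is.null(visit_mask)) {
    visit_mask <- rbind(visit_mask)
  } else {
    visit_mask <- matrix(TRUE, nrow(theta), ncol(theta))
  }
  out <- numeric(length(psi))
  for (i in seq_along(psi)) {
    yy <- y[min(i, nrow(y)), ][visit_mask[min(i, nrow(visit_mask)), ]]
    th <- theta[min(i, nrow(theta)), ][visit_mask[min(i, nrow(visit_mask)), ]]
    if (length(yy) > 0 && sum(yy) > 0) {
      out[i] <- 1
    } else {
      p0 <- psi[i] * prod(1 - th)
      out[i] <- p0 / (p0 + 1 - psi[i])
    }
  }
  out
}

# per-draw species-level parameter matrices from a fit (chains stacked)
draw_matrix <- function(fit, names) {
  dn <- dimnames(fit$draws)[[3]]
  idx <- match(names, dn)
  if (anyNA(idx)) abort(paste0("missing parameters: ",
                               paste(names[is.na(idx)], collapse = ", ")))
  d <- fit$draws[, , idx, drop = FALSE]
  matrix(d, dim(d)[1] * dim(d)[2], length(idx),
         dimnames = list(NULL, names))
}

# occupancy linear-predictor draws for one species at given sites:
# returns draws x sites matrix of logit(psi)
species_logit_psi <- function(fit, sp, psi_covs) {
  species_logit_psi_all(fit, sp, psi_covs, fit$packed)
}

# detection-probability draws for one species: draws x sites x visits
species_theta <- function(fit, sp, theta_covs, J, K) {
  cc <- draw_matrix(fit, paste0("c[", sp, "]"))[, 1]
  D <- length(cc)
  th <- array(NA_real_, c(D, J, K))
  for (k in seq_len(K)) {
    lt <- matrix(cc, D, J)
    for (nm in names(theta_covs)) {
      w <- theta_covs[[nm]][, k]
      d <- draw_matrix(fit, paste0("d_", nm))[, 1]
      lt <- lt + outer(d, w)
    }
    th[, , k] <- plogis(lt)
  }
  th
}

#' Prediction-point covariates on the training scale
#'
#' Rebuilds the occupancy covariates of a fitted bundle at new prediction
#' points, reusing the centering/scaling constants stored at training time
#' (prediction covariates must never be re-standardized on their own scale).
#'
#' @param bundle the training [build_covariate_bundle()].
#' @param new_sites site table for the prediction points (`site_id`, `x_km`,
#'   `y_km`, `elev_m`, covariate columns as needed).
#' @param ranges the [range_table()] (needed when range covariates are in the
#'   spec).
#' @return list with `values` (named list of covariates: site vectors or
#'   species x site matrices) and `site_ids`.
#' @export
prediction_covariates <- function(bundle, new_sites, ranges = NULL) {
  values <- list()
  for (nm in names(bundle$psi_covs)) {
    if (nm == "dist_range") {
      if (is.null(ranges)) abort("`ranges` needed to rebuild `dist_range` at new points.")
      dmat <- signed_distance_matrix(ranges, new_sites)
      values[[nm]] <- scaled_inverse_logit(dmat, bundle$spec$distance_scale_km)
    } else if (nm %in% c("elev_range", "elev_range2")) {
      if (is.null(ranges)) abort("`ranges` needed to rebuild elevational covariates.")
      smat <- std_elevation_matrix(ranges, new_sites)
      values[[nm]] <- if (nm == "elev_range") smat else smat^2
    } else {
      if (!nm %in% names(new_sites)) {
        abort(paste0("prediction sites lack covariate `", nm, "`."))
      }
      sc <- bundle$scaling[[nm]]
      if (is.null(sc)) abort(paste0("no stored scaling for `", nm, "`; cannot scale prediction covariates."))
      values[[nm]] <- (as.numeric(new_sites[[nm]]) - sc["center"]) / sc["scale"]
    }
  }
  list(values = values, site_ids = as.character(new_sites$site_id),
       template = matrix(0, 1, nrow(new_sites)))
}

#' Posterior occupancy surfaces
#'
#' Pushes every posterior draw through the occupancy linear predictor at
#' prediction points and summarizes per species and point. In `"clipped"`
#' mode, cells removed by `mask` are structural zeros (psi = 0 exactly); in
#' `"projected"` mode the fitted coefficients are projected everywhere.
#'
#' @param fit a [fit_occupancy()] result.
#' @param new_sites optional prediction site table (default: training sites).
#' @param ranges [range_table()] for rebuilding range covariates at new
#'   points.
#' @param mask optional [new_clip_mask()] over species x prediction points.
#' @param mode `"clipped"` or `"projected"`.
#' @param probs posterior quantiles to report.
#' @return tibble: `species_id`, `site_id`, `psi_mean`, and one column per
#'   quantile.
#' @export
occupancy_surface <- function(fit, new_sites = NULL, ranges = NULL,
                              mask = NULL, mode = c("clipped", "projected"),
                              probs = c(0.05, 0.95)) {
  mode <- match.arg(mode)
  if (is.null(new_sites)) {
    pc <- list(values = fit$bundle$psi_covs, site_ids = fit$bundle$site_ids,
               template = matrix(0, 1, length(fit$bundle$site_ids)))
  } else {
    pc <- prediction_covariates(fit$bundle, new_sites, ranges)
  }
  keep <- if (!is.null(mask)) clip_mask_matrix(mask) else NULL
  species <- setdiff(fit$packed$species_all,
                     grep("^pseudo", fit$packed$species_all, value = TRUE))
  out <- purrr::map_dfr(species, function(sp) {
    psi <- plogis(species_logit_psi(fit, sp, pc))
    if (mode == "clipped" && !is.null(keep)) {
      rm_ <- !keep[sp, pc$site_ids]
      psi[, rm_] <- 0
    }
    q <- apply(psi, 2, quantile, probs = probs, names = FALSE)
    if (is.null(dim(q))) q <- matrix(q, nrow = length(probs))
    res <- tibble(species_id = sp, site_id = pc$site_ids,
                  psi_mean = colMeans(psi))
    for (p in seq_along(probs)) res[[paste0("q", probs[p] * 100)]] <- q[p, ]
    res
  })
  out
}

#' Posterior point-scale species richness
#'
#' For every posterior draw and site, sums conditional occupancy
#' ([conditional_occupancy()]) over retained species -- detections force
#' `Z = 1`, all-zero histories are down-weighted by the Bayes update -- and
#' summarizes the per-site posterior. Never-observed species contribute
#' through their all-zero histories at retained cells; in augmented fits,
#' (pseudo)species contributions are additionally multiplied by the posterior
#' community-membership probability.
#'
#' @param fit a [fit_occupancy()] result.
#' @param include `"all"` or `"never_observed"` (species, incl. pseudospecies,
#'   with all-zero histories).
#' @param mode `"expectation"` (sum of conditional probabilities) or
#'   `"bernoulli"` (posterior draws of the realized richness).
#' @param probs credible-interval quantiles (default 80% interval).
#' @param seed RNG seed for `"bernoulli"` mode.
#' @return tibble: `site_id`, `richness_mean`, `richness_median`, quantile
#'   columns.
#' @export
richness_profile <- function(fit, include = c("all", "never_observed"),
                             mode = c("expectation", "bernoulli"),
                             probs = c(0.1, 0.9), seed = 1) {
  include <- match.arg(include)
  mode <- match.arg(mode)
  packed <- fit$packed
  data <- packed$data
  S <- data$S; J <- data$J; K <- data$K
  y <- array(data$y, c(S, J, K))
  vis <- array(data$vis, c(S, J, K)) == 1L
  keep <- t(matrix(data$keep, J, S)) == 1L # packed layout is site-fastest
  species <- packed$species_all
  observed_sp <- species[data$observed == 1L]
  use_species <- if (include == "all") species else setdiff(species, observed_sp)

  pc <- list(values = fit$bundle$psi_covs, site_ids = fit$bundle$site_ids,
             template = matrix(0, 1, J))
  augmented <- isTRUE(data$augmented)
  omega <- if (augmented) draw_matrix(fit, "omega")[, 1] else NULL

  D <- dim(fit$draws)[1] * dim(fit$draws)[2]
  if (mode == "bernoulli") set.seed(seed)
  rich <- matrix(0, D, J)
  for (sp in use_species) {
    i <- match(sp, species)
    psi <- plogis(species_logit_psi_all(fit, sp, pc, packed))
    th <- species_theta(fit, sp, fit$bundle$theta_covs, J, K)
    # log prod (1 - theta) over retained, visited, zero visits
    l1m <- matrix(0, D, J)
    anydet <- rep(FALSE, J)
    for (k in seq_len(K)) {
      vk <- vis[i, , k]
      anydet <- anydet | (vk & y[i, , k] == 1L)
      l1m[, vk] <- l1m[, vk] + log1p(-th[, vk, k, drop = TRUE])
    }
    p0 <- exp(l1m) # prob of all-zero given occupied
    cond <- psi * p0 / (psi * p0 + 1 - psi)
    cond[, anydet] <- 1
    cond[, !keep[i, ]] <- 0
    if (augmented && !(sp %in% observed_sp)) {
      # posterior membership: T = sum_j log marginal all-zero cell prob
      cell0 <- log(psi * p0 + 1 - psi)
      cell0[, !keep[i, ]] <- 0
      T_ <- rowSums(cell0)
      q <- omega * exp(T_) / (omega * exp(T_) + 1 - omega)
      cond <- cond * q
    }
    if (mode == "bernoulli") {
      zdraw <- matrix(rbinom(length(cond), 1, pmin(pmax(cond, 0), 1)), D, J)
      rich <- rich + zdraw
    } else {
      rich <- rich + cond
    }
  }
  q <- apply(rich, 2, quantile, probs = probs, names = FALSE)
  if (is.null(dim(q))) q <- matrix(q, nrow = length(probs))
  out <- tibble(site_id = fit$bundle$site_ids,
                richness_mean = colMeans(rich),
                richness_median = apply(rich, 2, median))
  for (p in seq_along(probs)) out[[paste0("q", probs[p] * 100)]] <- q[p, ]
  out
}

# logit-psi draws for any species including pseudospecies (which have no
# species-site covariate rows; site-vector covariates still apply)
species_logit_psi_all <- function(fit, sp, pc, packed) {
  a <- draw_matrix(fit, paste0("a[", sp, "]"))[, 1]
  lp <- matrix(a, length(a), ncol(pc$template))
  for (nm in names(pc$values)) {
    v <- pc$values[[nm]]
    row <- if (is.matrix(v)) v[sp, ] else v
    coef_name <- if (fit$spec$occupancy[[nm]] == "random") {
      paste0("beta_", nm, "[", sp, "]")
    } else paste0("b_", nm)
    coef <- draw_matrix(fit, coef_name)[, 1]
    lp <- lp + outer(coef, row)
  }
  lp
}

#' Per-species posterior of a land-use contrast
#'
#' For a binary land-use covariate in the occupancy design (e.g. forest = 0,
#' pasture = 1), returns each species' posterior of the logit-scale occupancy
#' difference between the two levels (the species' total coefficient --
#' fixed or random -- times the covariate step on the training scale).
#' Never-observed species get a finite, hierarchically pooled contrast.
#'
#' @param fit a [fit_occupancy()] result.
#' @param term name of the land-use occupancy term.
#' @param level_values the two raw covariate levels contrasted
#'   (default pasture 1 vs forest 0).
#' @return tibble: `species_id`, `median`, `q5`, `q95`.
#' @export
pasture_effect_table <- function(fit, term = "habitat", level_values = c(0, 1)) {
  if (!term %in% names(fit$spec$occupancy)) {
    abort(paste0("no land-use term `", term, "` in the occupancy design."))
  }
  sc <- fit$bundle$scaling[[term]]
  step <- if (!is.null(sc)) diff(level_values) / sc["scale"] else diff(level_values)
  species <- setdiff(fit$packed$species_all,
                     grep("^pseudo", fit$packed$species_all, value = TRUE))
  purrr::map_dfr(species, function(sp) {
    coef_name <- if (fit$spec$occupancy[[term]] == "random") {
      paste0("beta_", term, "[", sp, "]")
    } else paste0("b_", term)
    v <- draw_matrix(fit, coef_name)[, 1] * step
    tibble(species_id = sp, median = median(v),
           q5 = quantile(v, 0.05, names = FALSE),
           q95 = quantile(v, 0.95, names = FALSE))
  })
}
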