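#' Generalized Pareto fit to sample exceedances
#'
#' Profile-likelihood/empirical-Bayes estimator of the generalized Pareto
#' shape `k` and scale `sigma` (Zhang & Stephens 2009 style: a grid of
#' quadrature points on the profile of the scale parameter, posterior-mean
#' combination), with the usual weak regularization of `k` toward 0.5 that
#' stabilizes small tails.
#'
#' @param x positive exceedances (already shifted above the tail cutoff).
#' @param wip apply the weakly-informative regularization of `k`.
#' @return list with `k` and `sigma`.
#' @export
gpd_fit <- function(x, wip = TRUE) {
  x <- sort(x)
  n <- length(x)
  if (n < 2 || all(x == x[1])) return(list(k = -Inf, sigma = 0))
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- exp(prof - logsumexp(prof))
  theta_hat <- sum(theta * w)
  # positive k = heavy tail: theta_hat < 0, so -log1p(-theta_hat x) < 0
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  if (wip) k <- (k * n + 0.5 * 10) / (n + 10)
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smoothed importance sampling weights
#'
#' Stabilizes a vector of log importance ratios: fits a generalized Pareto
#' distribution to the largest `ceiling(min(0.2 * S, 3 * sqrt(S)))` ratios,
#' replaces them by the expected order statistics of the fitted tail,
#' truncates at the raw maximum, and normalizes. The tail-shape diagnostic
#' `pareto_k` flags unreliable cells (conventionally k > 0.7).
#'
#' @param log_ratios vector of log importance ratios (>= 100 draws for a
#'   meaningful tail fit; fewer are allowed but the tail is left unsmoothed
#'   with `pareto_k = Inf` unless the ratios are constant).
#' @return list with `log_weights` (normalized: `logsumexp(log_weights) = 0`)
#'   and `pareto_k` (`-Inf` for constant ratios).
#' @export
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  if (any(!is.finite(log_ratios))) abort("log importance ratios must be finite.")
  if (all(abs(log_ratios - log_ratios[1]) < 1e-12)) {
    return(list(log_weights = rep(-log(S), S), pareto_k = -Inf))
  }
  lr <- log_ratios - max(log_ratios)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (S < 5 || M < 5) {
    lw <- lr - logsumexp(lr)
    return(list(log_weights = lw, pareto_k = Inf))
  }
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lr[ord[S - M]]
  exceed <- exp(lr[tail_ids]) - exp(cutoff)
  fit <- gpd_fit(exceed)
  k <- fit$k
  if (is.finite(k) && fit$sigma > 0) {
    p <- (seq_len(M) - 0.5) / M
    smoothed <- log(exp(cutoff) + vapply(p, gpd_quantile, numeric(1),
                                         k = k, sigma = fit$sigma))
    # assign expected order statistics to the sorted tail, cap at raw max
    lr[tail_ids[order(lr[tail_ids])]] <- pmin(smoothed, 0)
  }
  lw <- lr - logsumexp(lr)
  list(log_weights = lw, pareto_k = k)
}

#' Approximate leave-one-out cross-validation (PSIS-LOO)
#'
#' Estimates the expected log pointwise predictive density (ELPD) of each
#' retained species-site cell by importance sampling from the full posterior,
#' with Pareto-smoothed weights. Cells whose tail diagnostic exceeds
#' `k_threshold` are re-evaluated by exact refit when a `refit_fun` is given
#' (the unambiguous remedy at desk scale); otherwise they are flagged.
#'
#' @param pointwise a [pointwise_loglik()] result.
#' @param refit_fun optional function(cell_index) returning the exact
#'   leave-one-out predictive log-density of that cell (e.g. a wrapper that
#'   refits without the cell and averages `exp(cell_loglik)` over the new
#'   draws).
#' @param k_threshold Pareto-k above which a cell is refit/flagged (0.7).
#' @return an object of class `bmsom_loo`: list with `elpd` (total), `se`,
#'   `pointwise` (tibble: `species_id`, `site_id`, `elpd_i`, `pareto_k`,
#'   `refit`), `n_refit`, `n_flagged`.
#' @export
loo_psis <- function(pointwise, refit_fun = NULL, k_threshold = 0.7) {
  stopifnot(inherits(pointwise, "bmsom_pointwise"))
  ll <- pointwise$ll
  if (any(!is.finite(ll))) abort("non-finite pointwise log-likelihoods.")
  ncell <- ncol(ll)
  elpd_i <- numeric(ncell)
  k_i <- numeric(ncell)
  refit <- logical(ncell)
  for (cc in seq_len(ncell)) {
    sm <- psis_smooth(-ll[, cc])
    k_i[cc] <- sm$pareto_k
    elpd_i[cc] <- logsumexp(sm$log_weights + ll[, cc])
    if (is.finite(k_i[cc]) && k_i[cc] > k_threshold) {
      if (!is.null(refit_fun)) {
        elpd_i[cc] <- refit_fun(cc)
        refit[cc] <- TRUE
      }
    }
  }
  pw <- pointwise$cells
  pw$elpd_i <- elpd_i
  pw$pareto_k <- k_i
  pw$refit <- refit
  flagged <- sum(k_i > k_threshold & !refit)
  structure(list(
    elpd = sum(elpd_i),
    se = sqrt(ncell * var(elpd_i)),
    pointwise = pw,
    n_refit = sum(refit),
    n_flagged = flagged,
    k_threshold = k_threshold
  ), class = "bmsom_loo")
}

#' @export
print.bmsom_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.1f (se %.1f) over %d cells; %d refit, %d flagged (k > %.2f)\n",
              x$elpd, x$se, nrow(x$pointwise), x$n_refit, x$n_flagged,
              x$k_threshold))
  invisible(x)
}

#' Compare two models by ELPD, overall and per species
#'
#' Pointwise ELPD differences (`a` minus `b`) with standard errors, overall
#' and aggregated by species. Both results must cover exactly the same cells;
#' comparisons involving clipped models must be restricted to the retained
#' cells before calling (the clipped model treats removed cells as structural
#' zeros, not predictions).
#'
#' @param a,b `bmsom_loo` results on identical cell sets.
#' @return an object of class `bmsom_elpd_comparison`: list with `elpd_diff`,
#'   `se_diff`, and `by_species` (tibble: `species_id`, `elpd_diff`,
#'   `se_diff`, `n_cells`).
#' @export
elpd_compare <- function(a, b) {
  ca <- a$pointwise; cb <- b$pointwise
  if (nrow(ca) != nrow(cb) ||
      !identical(paste(ca$species_id, ca$site_id),
                 paste(cb$species_id, cb$site_id))) {
    abort(paste0("the two models cover different cell sets; restrict both to the ",
                 "intersection (e.g. the clipped model's retained cells) before comparing."))
  }
  di <- ca$elpd_i - cb$elpd_i
  by_sp <- tibble(species_id = ca$species_id, d = di) |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      elpd_diff = sum(.data$d),
      se_diff = sqrt(dplyr::n() * var(.data$d)),
      n_cells = dplyr::n(), .groups = "drop"
    )
  structure(list(
    elpd_diff = sum(di),
    se_diff = sqrt(length(di) * var(di)),
    pointwise_diff = tibble(species_id = ca$species_id, site_id = ca$site_id,
                            elpd_diff = di),
    by_species = by_sp
  ), class = "bmsom_elpd_comparison")
}

#' @export
print.bmsom_elpd_comparison <- function(x, ...) {
  cat(sprintf("ELPD difference (model a - model b): %.1f (se %.1f)\n",
              x$elpd_diff, x$se_diff))
  n_better <- sum(x$by_species$elpd_diff > 0)
  cat(sprintf("  species with improvement: %d of %d\n",
              n_better, nrow(x$by_species)))
  invisible(x)
}

#' Exact leave-one-out refit hook
#'
#' Builds a `refit_fun` for [loo_psis()]: for cell `i` it refits the model
#' with that cell removed from the likelihood (clip mask without reason
#' bookkeeping) and returns `log mean exp(cell_loglik_i)` over the new draws
#' -- the exact LOO predictive density up to Monte-Carlo error.
#'
#' @param fit a [fit_occupancy()] result.
#' @param chains,warmup,draws sampler sizes for the refits (smaller than the
#'   main fit is usual).
#' @return function(cell_index) -> exact elpd_i.
#' @export
exact_loo_refit <- function(fit, chains = 2, warmup = 300, draws = 300) {
  force(fit)
  function(cell_index) {
    cells <- fit$packed$cells
    sp <- cells$species_id[cell_index]; st <- cells$site_id[cell_index]
    keep <- clip_mask_matrix(fit$mask)
    keep[sp, st] <- FALSE
    reason <- matrix(NA_character_, nrow(keep), ncol(keep))
    reason[!keep] <- "geographic_distance" # placeholder reason for held-out cell
    mask_i <- new_clip_mask(keep, reason)
    det_i <- dplyr::filter(fit$detections,
                           !(.data$species_id == sp & .data$site_id == st))
    refit <- fit_occupancy(fit$spec, fit$bundle, det_i, mask_i,
                           chains = chains, warmup = warmup, draws = draws,
                           seed = fit$sampler$seed + 1000 + cell_index)
    # evaluate the held-out cell's loglik under the refit draws
    full_mask_ <- fit$mask
    pw_data <- pack_model_data(fit$spec, fit$bundle, fit$detections,
                               full_mask_, NULL)
    d <- refit$draws_unc
    flat <- matrix(d, dim(d)[1] * dim(d)[2], dim(d)[3])
    ll_all <- .cpp_pointwise(pw_data$data, flat)
    idx <- which(pw_data$cells$species_id == sp & pw_data$cells$site_id == st)
    lls <- ll_all[, idx]
    logsumexp(lls) - log(length(lls))
  }
}
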