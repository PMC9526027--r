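#' Fit a multi-species occupancy model by NUTS
#'
#' Fits the marginalized-likelihood model defined by a [model_spec()] and a
#' [build_covariate_bundle()] with the package's No-U-Turn sampler (adaptive
#' Hamiltonian Monte Carlo with dual-averaging step-size adaptation and a
#' diagonal mass matrix; non-centered parameterization throughout). The latent
#' occupancy states are summed out of the likelihood analytically, so
#' gradient-based sampling applies; conditional occupancy is recovered
#' afterwards with [conditional_occupancy()].
#'
#' Fitting refuses to proceed while the clip mask removes cells containing
#' detections ([validate_mask_against_detections()]): such detections signal
#' range-map errors to fix upstream.
#'
#' @param spec a [model_spec()].
#' @param bundle a [build_covariate_bundle()] built with the same spec.
#' @param detections long detection table.
#' @param mask optional [new_clip_mask()] (default: retain everything).
#' @param visit_array optional S x J x K logical array of temporally retained
#'   visits (e.g. `clip_temporal(...)$visit_array`).
#' @param chains number of chains (>= 2 for diagnostics; 1 is allowed with a
#'   warning).
#' @param warmup,draws warmup and sampling iterations per chain.
#' @param seed integer seed; chain `k` uses `seed + k - 1`. Identical seeds
#'   give identical draws.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param max_treedepth NUTS doubling cap.
#' @param init_jitter SD of the normal jitter around the prior-mean
#'   initialization.
#' @return an object of class `bmsom_fit`.
#' @export
fit_occupancy <- function(spec, bundle, detections, mask = NULL,
                          visit_array = NULL, chains = 4, warmup = 1000,
                          draws = 1000, seed = 1, target_accept = 0.9,
                          max_treedepth = 10, init_jitter = 0.1) {
  stopifnot(inherits(spec, "bmsom_spec"), inherits(bundle, "bmsom_bundle"))
  if (chains < 1 || warmup < 0 || draws < 1) abort("invalid sampler sizes.")
  if (chains == 1) {
    warn("a single chain cannot support split R-hat diagnostics; run >= 2 chains for a convergence report.")
  }
  if (is.null(mask)) mask <- full_mask(bundle$species, bundle$site_ids)
  viol <- validate_mask_against_detections(mask, detections)
  if (nrow(viol) > 0) {
    abort(paste0("refusing to fit: ", nrow(viol), " detection(s) at clipped cells ",
                 "(range-map errors of omission). First: ",
                 viol$species_id[1], " @ ", viol$site_id[1]))
  }
  packed <- pack_model_data(spec, bundle, detections, mask, visit_array)
  npar <- .cpp_n_params(packed$data)
  stopifnot(npar == length(packed$par_names))

  draws_unc <- array(NA_real_, c(draws, chains, npar),
                     dimnames = list(NULL, NULL, packed$par_names))
  energy <- matrix(NA_real_, draws, chains)
  divergent <- matrix(0L, draws, chains)
  treedepth <- matrix(0L, draws, chains)
  stepsize <- numeric(chains)
  n_grad <- numeric(chains)

  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed + ch - 1))
    init <- packed$init + rnorm(npar, 0, init_jitter)
    res <- .cpp_nuts(packed$data, init, as.integer(warmup), as.integer(draws),
                     target_accept, as.integer(max_treedepth), TRUE)
    draws_unc[, ch, ] <- res$draws
    energy[, ch] <- res$energy
    divergent[, ch] <- res$divergent
    treedepth[, ch] <- res$treedepth
    stepsize[ch] <- res$stepsize
    n_grad[ch] <- res$n_grad_evals
  }
  nat <- natural_draws(draws_unc, packed)
  structure(list(
    draws = nat, draws_unc = draws_unc,
    spec = spec, bundle = bundle, mask = mask,
    packed = packed, detections = detections,
    sampler = list(energy = energy, divergent = divergent,
                   treedepth = treedepth, stepsize = stepsize,
                   n_grad_evals = n_grad, chains = chains,
                   warmup = warmup, iter = draws, seed = seed,
                   target_accept = target_accept,
                   max_treedepth = max_treedepth)
  ), class = "bmsom_fit")
}

#' @export
print.bmsom_fit <- function(x, ...) {
  s <- x$sampler
  cat(sprintf("<bmsom fit: variant \"%s\", %d species x %d sites; %d chain(s) x %d draws>\n",
              x$spec$variant, length(x$packed$species_all),
              length(x$bundle$site_ids), s$chains, s$iter))
  cat(sprintf("  divergences: %d; stepsize: %s\n", sum(x$sampler$divergent),
              paste(signif(s$stepsize, 3), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# data packing for the compiled model
# ---------------------------------------------------------------------------

pack_model_data <- function(spec, bundle, detections, mask, visit_array = NULL) {
  species <- bundle$species
  sites <- bundle$site_ids
  J <- length(sites); K <- bundle$n_visits
  da <- as_detection_array(detections, species, sites, K)
  vis <- da$observed
  if (!is.null(visit_array)) {
    if (!all(dim(visit_array) == dim(vis))) abort("`visit_array` has wrong dimensions.")
    vis <- vis & visit_array
  }
  keep <- clip_mask_matrix(mask)
  y <- da$y

  n_pseudo <- spec$n_pseudospecies
  species_all <- species
  if (spec$variant == "augmented" && n_pseudo > 0) {
    # pseudospecies: all-zero histories over each site's realized visit pattern
    site_vis <- apply(vis, c(2, 3), any) # J x K
    pseudo <- sprintf("pseudo%04d", seq_len(n_pseudo))
    species_all <- c(species, pseudo)
    S <- length(species_all)
    y2 <- array(0L, c(S, J, K)); vis2 <- array(FALSE, c(S, J, K))
    y2[seq_along(species), , ] <- y
    vis2[seq_along(species), , ] <- vis
    for (m in seq_len(n_pseudo)) vis2[length(species) + m, , ] <- site_vis
    y <- y2; vis <- vis2
    keep <- rbind(keep, matrix(TRUE, n_pseudo, J))
  }
  S <- length(species_all)

  u_vals <- list(); u_is_matrix <- logical(0); u_random <- logical(0)
  for (nm in names(bundle$psi_covs)) {
    cov <- bundle$psi_covs[[nm]]
    if (is.matrix(cov)) {
      if (nrow(cov) != S) abort("species-site covariates cannot be used with pseudospecies.")
      u_vals[[nm]] <- as.numeric(t(cov)) # site-fastest layout for the C++ core
      u_is_matrix <- c(u_is_matrix, TRUE)
    } else {
      u_vals[[nm]] <- as.numeric(cov)
      u_is_matrix <- c(u_is_matrix, FALSE)
    }
    u_random <- c(u_random, unname(spec$occupancy[nm] == "random"))
  }
  w_vals <- lapply(bundle$theta_covs, as.numeric)

  observed <- vapply(seq_len(S), function(i) {
    any(y[i, , ][vis[i, , ]] == 1L)
  }, logical(1))

  data <- list(
    S = S, J = J, K = K,
    y = as.integer(y), vis = as.integer(vis), keep = as.integer(t(keep)),
    u_vals = unname(u_vals), u_is_matrix = u_is_matrix, u_random = u_random,
    w_vals = unname(w_vals),
    augmented = spec$variant == "augmented",
    observed = as.integer(observed),
    mean_loc = spec$priors$mean_loc, mean_scale = spec$priors$mean_scale,
    sd_scale = spec$priors$sd_scale
  )

  # parameter names, natural-scale names, and prior-mean initialization
  u_names <- names(bundle$psi_covs)
  rand <- u_names[u_random]; fixed <- u_names[!u_random]
  par_names <- c("mu_a", "mu_c", "log_sigma_a", "log_sigma_c", "atanh_rho",
                 paste0("z_a[", species_all, "]"),
                 paste0("z_c[", species_all, "]"))
  init <- c(0, 0, log(0.5), log(0.5), 0, rep(0, 2 * S))
  for (nm in rand) {
    par_names <- c(par_names, paste0("mu_beta_", nm), paste0("log_sigma_beta_", nm),
                   paste0("z_beta_", nm, "[", species_all, "]"))
    init <- c(init, 0, log(0.5), rep(0, S))
  }
  for (nm in fixed) {
    par_names <- c(par_names, paste0("b_", nm))
    init <- c(init, 0)
  }
  for (nm in names(bundle$theta_covs)) {
    par_names <- c(par_names, paste0("d_", nm))
    init <- c(init, 0)
  }
  if (data$augmented) {
    par_names <- c(par_names, "logit_omega")
    init <- c(init, 0)
  }

  # C++ iterates i (species) outer, j (site) inner over retained cells
  cells <- tidyr::expand_grid(species_id = species_all, site_id = sites)
  cells$keep <- as.logical(t(keep))
  cells <- cells[cells$keep, c("species_id", "site_id")]

  list(data = data, par_names = par_names, init = init,
       species_all = species_all, sites = sites,
       n_pseudo = n_pseudo, rand_terms = rand, fixed_terms = fixed,
       det_terms = names(bundle$theta_covs), cells = cells)
}

# transform unconstrained draws to the natural scale with field-style names
natural_draws <- function(draws_unc, packed) {
  sp <- packed$species_all
  S <- length(sp)
  dn <- dimnames(draws_unc)[[3]]
  get <- function(nm) draws_unc[, , match(nm, dn), drop = FALSE]
  out <- list()
  out[["mu_a"]] <- get("mu_a")
  out[["mu_c"]] <- get("mu_c")
  sigma_a <- exp(get("log_sigma_a")); out[["sigma_a"]] <- sigma_a
  sigma_c <- exp(get("log_sigma_c")); out[["sigma_c"]] <- sigma_c
  rho <- tanh(get("atanh_rho")); out[["rho_ac"]] <- rho
  za <- draws_unc[, , paste0("z_a[", sp, "]"), drop = FALSE]
  zc <- draws_unc[, , paste0("z_c[", sp, "]"), drop = FALSE]
  a <- zc; cdev <- zc
  for (i in seq_len(S)) {
    a[, , i] <- out$mu_a[, , 1] + sigma_a[, , 1] * za[, , i]
    cdev[, , i] <- out$mu_c[, , 1] +
      sigma_c[, , 1] * (rho[, , 1] * za[, , i] + sqrt(1 - rho[, , 1]^2) * zc[, , i])
  }
  for (i in seq_len(S)) out[[paste0("a[", sp[i], "]")]] <- a[, , i, drop = FALSE]
  for (i in seq_len(S)) out[[paste0("c[", sp[i], "]")]] <- cdev[, , i, drop = FALSE]
  for (nm in packed$rand_terms) {
    mu <- get(paste0("mu_beta_", nm))
    sg <- exp(get(paste0("log_sigma_beta_", nm)))
    out[[paste0("mu_beta_", nm)]] <- mu
    out[[paste0("sigma_beta_", nm)]] <- sg
    z <- draws_unc[, , paste0("z_beta_", nm, "[", sp, "]"), drop = FALSE]
    for (i in seq_len(S)) {
      out[[paste0("beta_", nm, "[", sp[i], "]")]] <-
        mu[, , 1, drop = FALSE] + sg[, , 1, drop = FALSE] * z[, , i, drop = FALSE]
    }
  }
  for (nm in packed$fixed_terms) out[[paste0("b_", nm)]] <- get(paste0("b_", nm))
  for (nm in packed$det_terms) out[[paste0("d_", nm)]] <- get(paste0("d_", nm))
  if ("logit_omega" %in% dn) out[["omega"]] <- plogis(get("logit_omega"))
  nms <- names(out)
  arr <- array(NA_real_, c(dim(draws_unc)[1], dim(draws_unc)[2], length(out)),
               dimnames = list(NULL, NULL, nms))
  for (p in seq_along(out)) arr[, , p] <- out[[p]]
  arr
}

# pull one named parameter as an iterations x chains matrix
fit_param <- function(fit, name) {
  dn <- dimnames(fit$draws)[[3]]
  if (!name %in% dn) abort(paste0("no parameter `", name, "` in the fit."))
  fit$draws[, , match(name, dn)]
}

# stacked draws (chains concatenated) of one parameter
fit_param_vec <- function(fit, name) as.numeric(fit_param(fit, name))

#' Convergence report: split R-hat, divergences, E-BFMI
#'
#' Computes the rank-normalized split R-hat for every parameter, the
#' divergence count, and the energy-based fraction of missing information
#' (E-BFMI) per chain. The fit passes when the maximum R-hat is below 1.03,
#' there are no divergences, and every chain's E-BFMI exceeds 0.2.
#'
#' @param fit a [fit_occupancy()] result with >= 2 chains.
#' @return an object of class `bmsom_convergence`: list with `parameters`
#'   (tibble: `parameter`, `rhat`), `max_rhat`, `n_divergent`, `ebfmi`,
#'   `pass`.
#' @export
convergence_report <- function(fit) {
  if (fit$sampler$chains < 2) {
    abort("convergence diagnostics need >= 2 chains (split R-hat is undefined for 1 chain).")
  }
  dn <- dimnames(fit$draws)[[3]]
  rhats <- vapply(seq_along(dn), function(p) rhat_rank(fit$draws[, , p]),
                  numeric(1))
  tab <- tibble(parameter = dn, rhat = rhats)
  ebfmi <- apply(fit$sampler$energy, 2, function(e) {
    if (var(e) == 0) return(NA_real_)
    mean(diff(e)^2) / var(e)
  })
  max_rhat <- suppressWarnings(max(rhats, na.rm = TRUE))
  n_div <- sum(fit$sampler$divergent)
  pass <- is.finite(max_rhat) && max_rhat < 1.03 && n_div == 0 &&
    all(is.na(ebfmi) | ebfmi > 0.2)
  structure(list(parameters = tab, max_rhat = max_rhat, n_divergent = n_div,
                 ebfmi = ebfmi, pass = pass),
            class = "bmsom_convergence")
}

#' @export
print.bmsom_convergence <- function(x, ...) {
  cat(sprintf("convergence: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  max R-hat: %.4f (gate < 1.03)\n", x$max_rhat))
  cat(sprintf("  divergences: %d (gate 0)\n", x$n_divergent))
  cat(sprintf("  E-BFMI by chain: %s (gate > 0.2)\n",
              paste(signif(x$ebfmi, 3), collapse = ", ")))
  invisible(x)
}

# rank-normalized split R-hat (bulk and folded; the max of the two)
rhat_rank <- function(x) {
  # x: iterations x chains
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  half <- floor(n / 2)
  sm <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  if (all(abs(sm - sm[1]) < .Machine$double.eps * 100)) return(NA_real_)
  bulk <- rhat_basic(z_scale(sm))
  folded <- rhat_basic(z_scale(abs(sm - median(sm))))
  max(bulk, folded)
}

z_scale <- function(x) {
  r <- matrix(rank(x, ties.method = "average"), nrow(x), ncol(x))
  qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

rhat_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  mns <- colMeans(x)
  vars <- apply(x, 2, var)
  B <- n * var(mns)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Per-draw, per-cell marginalized log-likelihoods
#'
#' Evaluates the marginalized cell log-likelihood for every retained
#' species-site cell and every posterior draw. The species-site
#' detection-history vector is the prediction unit: visits within a cell
#' share the latent occupancy state, so leave-one-out removes whole cells,
#' not single visits.
#'
#' @param fit a [fit_occupancy()] result (`msom`/`bmsom` variants; the
#'   augmented variant's cells are not independent given Omega).
#' @return an object of class `bmsom_pointwise`: list with `ll` (draws x
#'   cells matrix, chains stacked) and `cells` (tibble `species_id`,
#'   `site_id`).
#' @export
pointwise_loglik <- function(fit) {
  if (fit$spec$variant == "augmented") {
    abort("pointwise cell log-likelihoods are defined for msom/bmsom variants only.")
  }
  d <- fit$draws_unc
  flat <- matrix(aperm(d, c(1, 2, 3)), dim(d)[1] * dim(d)[2], dim(d)[3])
  ll <- .cpp_pointwise(fit$packed$data, flat)
  structure(list(ll = ll, cells = fit$packed$cells),
            class = "bmsom_pointwise")
}

#' @export
print.bmsom_pointwise <- function(x, ...) {
  cat(sprintf("<pointwise log-likelihood: %d draws x %d cells>\n",
              nrow(x$ll), ncol(x$ll)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fit
#'
#' @param x a `bmsom_fit`.
#' @param pars optional character vector of parameter names to keep.
#' @param probs quantiles to report.
#' @param ... unused.
#' @return a tibble: `parameter`, `mean`, `sd`, one column per quantile, and
#'   `rhat` (NA for single-chain fits).
#' @export
tidy.bmsom_fit <- function(x, pars = NULL, probs = c(0.05, 0.5, 0.95), ...) {
  dn <- dimnames(x$draws)[[3]]
  if (!is.null(pars)) dn <- intersect(dn, pars)
  rows <- lapply(dn, function(nm) {
    v <- fit_param_vec(x, nm)
    q <- quantile(v, probs, names = FALSE)
    rh <- if (x$sampler$chains >= 2) rhat_rank(fit_param(x, nm)) else NA_real_
    tibble(parameter = nm, mean = mean(v), sd = sd(v),
           !!!setNames(as.list(q), paste0("q", probs * 100)), rhat = rh)
  })
  dplyr::bind_rows(rows)
}

#' One-row fit summary
#'
#' @param x a `bmsom_fit`.
#' @param ... unused.
#' @export
glance.bmsom_fit <- function(x, ...) {
  rep_ <- if (x$sampler$chains >= 2) convergence_report(x) else NULL
  tibble(
    variant = x$spec$variant,
    n_species = length(x$packed$species_all),
    n_sites = length(x$bundle$site_ids),
    n_cells = nrow(x$packed$cells),
    chains = x$sampler$chains,
    iter = x$sampler$iter,
    n_divergent = sum(x$sampler$divergent),
    max_rhat = if (is.null(rep_)) NA_real_ else rep_$max_rhat,
    min_ebfmi = if (is.null(rep_)) NA_real_ else suppressWarnings(min(rep_$ebfmi, na.rm = TRUE)),
    converged = if (is.null(rep_)) NA else rep_$pass
  )
}
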