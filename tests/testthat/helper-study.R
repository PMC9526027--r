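# Replicated simulation study shared by several acceptance checks:
# 50 species x 200 sites x 4 visits simulated from the bMSOM, 20 replicates;
# each replicate fits the bMSOM and the traditional MSOM, compares them by
# PSIS-LOO, and measures in-range occupancy bias. Computed once and cached.

study_replicate <- function(r, chains = 2, warmup = 250, draws = 250) {
  cfg <- community_config(det_time_effect = 0, seed = 100)
  sim <- simulate_community(cfg, replicate = r)
  spec_b <- model_spec(occupancy = c(elev_m = "random", dist_range = "random"),
                       variant = "bmsom")
  spec_m <- model_spec(occupancy = c(elev_m = "random"), variant = "msom")
  bundle_b <- build_covariate_bundle(sim$ranges, sim$sites, spec_b,
                                     n_visits = cfg$n_visits)
  bundle_m <- build_covariate_bundle(sim$ranges, sim$sites, spec_m,
                                     n_visits = cfg$n_visits)
  fit_b <- fit_occupancy(spec_b, bundle_b, sim$detections, chains = chains,
                         warmup = warmup, draws = draws, seed = 500 + r)
  fit_m <- fit_occupancy(spec_m, bundle_m, sim$detections, chains = chains,
                         warmup = warmup, draws = draws, seed = 700 + r)

  # distance-slope hyperparameter recovery (90% central intervals)
  mu_d <- as.numeric(fit_b$draws[, , "mu_beta_dist_range"])
  sd_d <- as.numeric(fit_b$draws[, , "sigma_beta_dist_range"])
  ci_mu <- quantile(mu_d, c(0.05, 0.95), names = FALSE)
  ci_sd <- quantile(sd_d, c(0.05, 0.95), names = FALSE)

  # per-species slope recovery
  sp <- bundle_b$species
  post_beta <- vapply(sp, function(s) {
    mean(fit_b$draws[, , paste0("beta_dist_range[", s, "]")])
  }, numeric(1))
  slope_corr <- cor(post_beta, sim$truth$species$beta_dist)
  post_beta_e <- vapply(sp, function(s) {
    mean(fit_b$draws[, , paste0("beta_elev_m[", s, "]")])
  }, numeric(1))
  slope_corr_elev <- cor(post_beta_e, sim$truth$species$beta_elev)

  # PSIS-LOO comparison over the shared (unclipped) cell set
  lo_b <- loo_psis(pointwise_loglik(fit_b))
  lo_m <- loo_psis(pointwise_loglik(fit_m))
  cmp <- elpd_compare(lo_b, lo_m)

  # in-range bias: posterior mean psi vs truth at in-range cells
  in_range <- sim$truth$distances_km < 0
  truth_psi <- sim$truth$psi
  mean_psi <- function(fit, bundle) {
    pc <- list(values = bundle$psi_covs, site_ids = bundle$site_ids,
               template = matrix(0, 1, length(bundle$site_ids)))
    out <- matrix(NA_real_, length(bundle$species), length(bundle$site_ids),
                  dimnames = list(bundle$species, bundle$site_ids))
    for (s in bundle$species) {
      out[s, ] <- colMeans(plogis(bmsom:::species_logit_psi_all(fit, s, pc,
                                                                fit$packed)))
    }
    out
  }
  psi_b <- mean_psi(fit_b, bundle_b)
  psi_m <- mean_psi(fit_m, bundle_m)
  tibble::tibble(
    replicate = r,
    cover_mu = ci_mu[1] <= cfg$mu_beta_dist && cfg$mu_beta_dist <= ci_mu[2],
    cover_sd = ci_sd[1] <= cfg$sigma_beta_dist && cfg$sigma_beta_dist <= ci_sd[2],
    slope_corr = slope_corr,
    slope_corr_elev = slope_corr_elev,
    elpd_diff = cmp$elpd_diff,
    se_diff = cmp$se_diff,
    truth_inrange = mean(truth_psi[in_range]),
    bmsom_inrange = mean(psi_b[in_range]),
    msom_inrange = mean(psi_m[in_range]),
    bmsom_abs_err = mean(abs(psi_b[in_range] - truth_psi[in_range])),
    msom_abs_err = mean(abs(psi_m[in_range] - truth_psi[in_range]))
  )
}

acceptance_study <- local({
  val <- NULL
  function(n_replicates = 20) {
    if (is.null(val)) {
      val <<- purrr::map_dfr(seq_len(n_replicates), study_replicate)
    }
    val
  }
})
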