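test_that("the compiled gradient matches numerical differentiation", {
  s <- small_sim()
  for (spec in list(
    model_spec(occupancy = c(elev_m = "random", dist_range = "random"),
               detection = c(time = "fixed"), variant = "bmsom"),
    model_spec(occupancy = c(elev_m = "random"), detection = c(time = "fixed"),
               variant = "augmented", n_pseudospecies = 4),
    model_spec(variant = "msom")
  )) {
    bundle <- small_bundle(spec = spec)
    packed <- bmsom:::pack_model_data(spec, bundle, s$sim$detections,
                                      full_mask(bundle$species, bundle$site_ids))
    npar <- bmsom:::.cpp_n_params(packed$data)
    set.seed(1)
    th <- rnorm(npar, 0, 0.4)
    res <- bmsom:::.cpp_model_lp_grad(packed$data, th, TRUE)
    num <- vapply(seq_len(npar), function(p) {
      h <- 1e-6
      tp <- th; tp[p] <- tp[p] + h
      tm <- th; tm[p] <- tm[p] - h
      (bmsom:::.cpp_model_lp_grad(packed$data, tp, FALSE)$lp -
         bmsom:::.cpp_model_lp_grad(packed$data, tm, FALSE)$lp) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(num - res$grad) / pmax(1, abs(num))), 1e-5)
  }
})

test_that("compiled cell log-likelihoods agree with the R implementation", {
  s <- small_sim()
  bundle <- small_bundle()
  spec <- bundle$spec
  mask <- clip_by_distance(bundle$distances_km, 600)
  # the mask may clip detected cells for this seed; drop those detections
  viol <- validate_mask_against_detections(mask, s$sim$detections)
  det <- dplyr::anti_join(s$sim$detections, viol, by = c("species_id", "site_id"))
  packed <- bmsom:::pack_model_data(spec, bundle, det, mask)
  S <- length(bundle$species)
  set.seed(5)
  pars <- list(a = rnorm(S), c = rnorm(S),
               coefs = list(elev_m = rnorm(S), dist_range = rnorm(S)),
               d = list(time = -0.4))
  th <- numeric(bmsom:::.cpp_n_params(packed$data))
  names(th) <- packed$par_names
  th[paste0("z_a[", bundle$species, "]")] <- pars$a
  th[paste0("z_c[", bundle$species, "]")] <- pars$c
  th[paste0("z_beta_elev_m[", bundle$species, "]")] <- pars$coefs$elev_m
  th[paste0("z_beta_dist_range[", bundle$species, "]")] <- pars$coefs$dist_range
  th["d_time"] <- -0.4
  res <- bmsom:::.cpp_model_lp_grad(packed$data, th, FALSE, TRUE)
  ll_r <- dataset_logprob(pars, bundle, det, mask, include_priors = FALSE)
  expect_equal(sum(res$cell_loglik), ll_r, tolerance = 1e-9)
  expect_equal(length(res$cell_loglik), sum(mask$retained))
})

test_that("fits are deterministic given the seed and record sampler state", {
  sf <- small_fit()
  fit2 <- fit_occupancy(sf$spec, sf$bundle, sf$sim$detections, chains = 2,
                        warmup = 200, draws = 200, seed = 42)
  expect_identical(sf$fit$draws, fit2$draws)
  expect_identical(sf$fit$sampler$energy, fit2$sampler$energy)
  expect_equal(dim(sf$fit$draws)[1:2], c(200, 2))
  expect_true(all(is.finite(sf$fit$sampler$energy)))
})

test_that("a single chain fits with a warning but refuses diagnostics", {
  s <- small_sim()
  spec <- model_spec(variant = "msom")
  bundle <- small_bundle(spec = spec)
  expect_warning(
    fit1 <- fit_occupancy(spec, bundle, s$sim$detections, chains = 1,
                          warmup = 100, draws = 80, seed = 9),
    "single chain")
  expect_s3_class(fit1, "bmsom_fit")
  expect_error(convergence_report(fit1), "2 chains")
})

test_that("the convergence report enforces the three gates", {
  sf <- small_fit()
  rep_ <- convergence_report(sf$fit)
  expect_true(all(c("max_rhat", "n_divergent", "ebfmi", "pass") %in% names(rep_)))
  expect_true(is.finite(rep_$max_rhat))
  # iid chains: split R-hat near 1
  set.seed(2)
  x <- matrix(rnorm(2000), 1000, 2)
  expect_lt(bmsom:::rhat_rank(x), 1.03)
  # non-mixing chains: R-hat far above the gate
  y <- cbind(rnorm(1000), rnorm(1000, 10))
  expect_gt(bmsom:::rhat_rank(y), 1.5)
  # divergences alone fail the report regardless of R-hat
  fake <- sf$fit
  fake$sampler$divergent[1, 1] <- 1L
  rep2 <- convergence_report(fake)
  expect_false(rep2$pass)
  expect_equal(rep2$n_divergent, sum(sf$fit$sampler$divergent) + 1L)
})

test_that("a small simulated fit recovers the detection intercept", {
  cfg <- community_config(n_species = 5, n_sites = 20, n_visits = 4,
                          frac_never_observable = 0, det_time_effect = 0,
                          mu_c = 0.5, seed = 77)
  sim <- simulate_community(cfg)
  spec <- model_spec(occupancy = c(elev_m = "random", dist_range = "random"),
                     variant = "bmsom")
  bundle <- build_covariate_bundle(sim$ranges, sim$sites, spec, n_visits = 4)
  fit <- fit_occupancy(spec, bundle, sim$detections, chains = 2,
                       warmup = 250, draws = 250, seed = 15)
  mu_c <- as.numeric(fit$draws[, , "mu_c"])
  expect_lt(abs(mean(mu_c) - cfg$mu_c), 3 * sd(mu_c))
})

test_that("pointwise log-likelihoods are consistent with the joint density", {
  sf <- small_fit()
  pw <- pointwise_loglik(sf$fit)
  expect_equal(ncol(pw$ll), nrow(sf$fit$packed$cells))
  expect_equal(nrow(pw$ll), 200 * 2)
  # one draw, summed over cells, equals the model's likelihood part
  th <- sf$fit$draws_unc[7, 2, ]
  res <- bmsom:::.cpp_model_lp_grad(sf$fit$packed$data, th, FALSE, TRUE)
  d <- sf$fit$draws_unc
  flat_idx <- 7 + 200 * (2 - 1)
  expect_equal(sum(pw$ll[flat_idx, ]), sum(res$cell_loglik), tolerance = 1e-12)
  # constant draws give zero variance per cell
  d2 <- sf$fit
  d2$draws_unc <- d2$draws_unc[rep(1, 8), , , drop = FALSE]
  for (ch in 1:2) d2$draws_unc[, ch, ] <- rep(sf$fit$draws_unc[1, 1, ], each = 8)
  pw2 <- pointwise_loglik(d2)
  expect_true(all(apply(pw2$ll, 2, var) < 1e-20))
  # the augmented variant has no independent cells
  expect_error(pointwise_loglik(structure(list(spec = list(variant = "augmented")),
                                          class = "bmsom_fit")),
               "msom/bmsom variants only")
})

test_that("posterior matches an independent Gibbs implementation (rjags)", {
  # same intercept-only MSOM with correlated species intercepts, fit by JAGS
  # with the latent Z sampled explicitly: posterior means must agree
  cfg <- community_config(n_species = 8, n_sites = 40, n_visits = 4,
                          frac_never_observable = 0, det_time_effect = 0,
                          mu_beta_dist = 0, sigma_beta_dist = 0,
                          mu_beta_elev = 0, sigma_beta_elev = 0, seed = 123)
  sim <- simulate_community(cfg)
  spec <- model_spec(variant = "msom")
  bundle <- build_covariate_bundle(sim$ranges, sim$sites, spec, n_visits = 4)
  fit <- fit_occupancy(spec, bundle, sim$detections, chains = 2,
                       warmup = 400, draws = 600, seed = 3)

  library(rjags)
  da <- as_detection_array(sim$detections, bundle$species, bundle$site_ids, 4)
  jags_code <- "
  model {
    for (i in 1:S) {
      a[i] ~ dnorm(mu_a, 1 / (sigma_a * sigma_a))
      c[i] ~ dnorm(mu_c + rho * sigma_c / sigma_a * (a[i] - mu_a),
                   1 / (sigma_c * sigma_c * (1 - rho * rho)))
      for (j in 1:J) {
        Z[i, j] ~ dbern(ilogit(a[i]))
        for (k in 1:K) { y[i, j, k] ~ dbern(Z[i, j] * ilogit(c[i])) }
      }
    }
    mu_a ~ dnorm(0, 1 / 6.25)
    mu_c ~ dnorm(0, 1 / 6.25)
    sigma_a ~ dnorm(0, 1) T(0, )
    sigma_c ~ dnorm(0, 1) T(0, )
    rho ~ dunif(-1, 1)
  }"
  set.seed(4)
  yarr <- da$y
  dimnames(yarr) <- NULL
  jm <- jags.model(textConnection(jags_code),
                   data = list(y = yarr, S = dim(yarr)[1], J = dim(yarr)[2],
                               K = dim(yarr)[3]),
                   inits = list(
                     list(Z = matrix(1L, dim(yarr)[1], dim(yarr)[2]),
                          .RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
                     list(Z = matrix(1L, dim(yarr)[1], dim(yarr)[2]),
                          .RNG.name = "base::Mersenne-Twister", .RNG.seed = 2)),
                   n.chains = 2, quiet = TRUE)
  update(jm, 1500, progress.bar = "none")
  js <- coda.samples(jm, c("mu_a", "mu_c", "sigma_a", "sigma_c"), 3000,
                     progress.bar = "none")
  jmeans <- colMeans(do.call(rbind, js))
  for (p in c("mu_a", "mu_c", "sigma_a", "sigma_c")) {
    ours <- as.numeric(fit$draws[, , p])
    expect_lt(abs(mean(ours) - jmeans[[p]]),
              0.25 + 0.25 * sd(ours))
  }
})

test_that("rank statistics of the truth are uniform over prior replicates (SBC)", {
  # reduced simulation-based calibration on an intercept-only MSOM
  n_rep <- 50
  S <- 6; J <- 12; K <- 3
  ranks <- matrix(NA_real_, n_rep, 2)
  spec <- model_spec(variant = "msom")
  for (r in seq_len(n_rep)) {
    set.seed(9000 + r)
    mu_a <- rnorm(1, 0, 2.5); mu_c <- rnorm(1, 0, 2.5)
    sigma_a <- abs(rnorm(1)); sigma_c <- abs(rnorm(1))
    rho <- runif(1, -1, 1)
    z1 <- rnorm(S); z2 <- rnorm(S)
    a <- mu_a + sigma_a * z1
    cc <- mu_c + sigma_c * (rho * z1 + sqrt(1 - rho^2) * z2)
    psi <- plogis(a); th <- plogis(cc)
    Z <- matrix(rbinom(S * J, 1, psi), S, J)
    y <- array(rbinom(S * J * K, 1, rep(th, J * K)), c(S, J, K)) * as.numeric(Z)
    det <- tidyr::expand_grid(species_id = sprintf("s%02d", 1:S),
                              site_id = sprintf("p%02d", 1:J),
                              visit = 1:K)
    det$y <- as.integer(y[cbind(match(det$species_id, sprintf("s%02d", 1:S)),
                                match(det$site_id, sprintf("p%02d", 1:J)),
                                det$visit)])
    sites <- tibble::tibble(site_id = sprintf("p%02d", 1:J), x_km = 0, y_km = 0)
    ranges <- range_table(sprintf("s%02d", 1:S))
    bundle <- build_covariate_bundle(ranges, sites, spec, n_visits = K)
    suppressWarnings(
      fit <- fit_occupancy(spec, bundle, det, chains = 1, warmup = 150,
                           draws = 240, seed = 9000 + r))
    thin <- seq(1, 240, by = 4) # 60 roughly independent draws
    ranks[r, 1] <- mean(fit$draws[thin, 1, "mu_a"] < mu_a)
    ranks[r, 2] <- mean(fit$draws[thin, 1, "mu_c"] < mu_c)
  }
  # under correct computation the normalized ranks are uniform on [0, 1]
  # (ties from the discrete rank grid are expected; the KS p-value is still
  # a valid conservative screen at alpha = 0.01)
  p1 <- suppressWarnings(stats::ks.test(ranks[, 1], "punif")$p.value)
  p2 <- suppressWarnings(stats::ks.test(ranks[, 2], "punif")$p.value)
  expect_gt(p1, 0.01)
  expect_gt(p2, 0.01)
})
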