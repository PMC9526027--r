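test_that("cell log-likelihood matches hand-enumerated values", {
  expect_equal(cell_loglik(1, c(0.5, 0.5), c(1, 0)), log(0.25))
  expect_equal(cell_loglik(0.5, 0.5, 0), log(0.5 * 0.5 + 0.5))
  expect_equal(cell_loglik(0.5, 0.5, 0), log(0.75))
  # all visits masked: unit probability
  expect_equal(cell_loglik(0.3, c(0.5, 0.6), c(0, 1), visit_mask = c(FALSE, FALSE)), 0)
  # detection with psi = 0 is impossible
  expect_warning(v <- cell_loglik(0, 0.5, 1), "psi = 0")
  expect_identical(v, -Inf)
})

test_that("exp(cell_loglik) is normalized over all histories", {
  set.seed(7)
  for (K in c(1, 3, 6)) {
    psi <- runif(1); theta <- runif(K)
    total <- sum(vapply(0:(2^K - 1), function(h) {
      y <- as.integer(intToBits(h))[seq_len(K)]
      exp(cell_loglik(psi, theta, y))
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("linear predictors reduce to known values", {
  s <- small_sim()
  bundle <- small_bundle()
  S <- length(bundle$species)
  zero <- list(a = rep(0, S), c = rep(0, S),
               coefs = list(elev_m = rep(0, S), dist_range = rep(0, S)),
               d = list(time = 0))
  lp <- linear_predictors(zero, bundle)
  expect_true(all(lp$psi == 0.5))
  expect_true(all(lp$theta == 0.5))
  # a -4 slope on a covariate step of 1 moves the logit by exactly -4
  p1 <- zero; p1$coefs$dist_range <- rep(-4, S)
  cov <- bundle$psi_covs$dist_range
  lp1 <- linear_predictors(p1, bundle)
  expect_equal(qlogis(lp1$psi) - qlogis(lp$psi), -4 * cov, tolerance = 1e-9)
})

test_that("linear predictors match a naive scalar oracle on a random instance", {
  bundle <- small_bundle()
  S <- length(bundle$species); J <- length(bundle$site_ids); K <- bundle$n_visits
  set.seed(12)
  pars <- list(a = rnorm(S), c = rnorm(S),
               coefs = list(elev_m = rnorm(S), dist_range = rnorm(S)),
               d = list(time = rnorm(1)))
  lp <- linear_predictors(pars, bundle)
  for (trial in 1:25) {
    i <- sample(S, 1); j <- sample(J, 1); k <- sample(K, 1)
    psi_ij <- plogis(pars$a[i] +
                       pars$coefs$elev_m[i] * bundle$psi_covs$elev_m[j] +
                       pars$coefs$dist_range[i] * bundle$psi_covs$dist_range[i, j])
    th_ijk <- plogis(pars$c[i] + pars$d$time * bundle$theta_covs$time[j, k])
    expect_equal(lp$psi[i, j], unname(psi_ij))
    expect_equal(lp$theta[i, j, k], unname(th_ijk))
  }
})

test_that("marginalized dataset log-probability equals exhaustive enumeration", {
  # randomized property: 100 tiny instances, <= 12 cells, tol 1e-10
  for (trial in 1:100) {
    set.seed(trial)
    S <- sample(1:3, 1); J <- sample(1:4, 1); K <- sample(1:3, 1)
    inst <- random_instance(S, J, K, seed = trial + 1000)
    ll <- 0
    for (i in seq_len(S)) for (j in seq_len(J)) {
      ll <- ll + cell_loglik(inst$psi[i, j], inst$theta[i, j, ], inst$y[i, j, ])
    }
    oracle <- enumeration_loglik(inst$psi, inst$theta, inst$y)
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
})

test_that("clip masks drop cells from the likelihood exactly", {
  inst <- random_instance(2, 2, 2, seed = 99)
  inst$y[1, 2, ] <- 0 # the clipped cell must hold no detections
  keep <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  sp <- c("a", "b"); st <- c("s1", "s2")
  dimnames(keep) <- list(sp, st)
  reason <- matrix(NA_character_, 2, 2); reason[!keep] <- "geographic_distance"
  ll_masked <- 0
  for (i in 1:2) for (j in 1:2) {
    if (!keep[i, j]) next
    ll_masked <- ll_masked + cell_loglik(inst$psi[i, j], inst$theta[i, j, ],
                                         inst$y[i, j, ])
  }
  oracle <- enumeration_loglik(inst$psi, inst$theta, inst$y, keep = keep)
  expect_equal(ll_masked, oracle, tolerance = 1e-10)
})

test_that("dataset log-probability is invariant to species and site relabeling", {
  s <- small_sim()
  bundle <- small_bundle()
  S <- length(bundle$species)
  set.seed(31)
  pars <- list(a = rnorm(S), c = rnorm(S),
               coefs = list(elev_m = rnorm(S), dist_range = rnorm(S)),
               d = list(time = 0.2))
  ll1 <- dataset_logprob(pars, bundle, s$sim$detections, include_priors = FALSE)
  # shuffle the rows of the detection table; the likelihood is a set sum
  det2 <- s$sim$detections[sample(nrow(s$sim$detections)), ]
  ll2 <- dataset_logprob(pars, bundle, det2, include_priors = FALSE)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("bMSOM with range slopes pinned at zero reproduces the MSOM exactly", {
  s <- small_sim()
  spec_b <- model_spec(occupancy = c(elev_m = "random", dist_range = "random"),
                       detection = c(time = "fixed"), variant = "bmsom")
  spec_m <- model_spec(occupancy = c(elev_m = "random"),
                       detection = c(time = "fixed"), variant = "msom")
  b_b <- small_bundle(spec = spec_b)
  b_m <- small_bundle(spec = spec_m)
  S <- length(b_b$species)
  set.seed(8)
  base <- list(a = rnorm(S), c = rnorm(S), d = list(time = 0.1))
  p_b <- c(base, list(coefs = list(elev_m = rnorm(S), dist_range = rep(0, S))))
  p_m <- c(base, list(coefs = list(elev_m = p_b$coefs$elev_m)))
  ll_b <- dataset_logprob(p_b, b_b, s$sim$detections, include_priors = FALSE)
  ll_m <- dataset_logprob(p_m, b_m, s$sim$detections, include_priors = FALSE)
  expect_identical(ll_b, ll_m)
})

test_that("augmented species log-probability matches hand enumeration", {
  # 1 site, 1 visit, psi = theta = 0.5, omega = 0.5, all-zero history:
  # P = (1-w) + w (psi (1-th) + 1-psi) = 0.5 + 0.5 * 0.75 = 0.875
  cl0 <- cell_loglik(0.5, 0.5, 0)
  expect_equal(augmented_species_logprob(0.5, cl0, observed = FALSE), log(0.875))
  # omega = 1 reduces to the plain sum
  expect_equal(augmented_species_logprob(1, c(-1.2, -0.3), observed = TRUE), -1.5)
  expect_equal(augmented_species_logprob(1, cl0, observed = FALSE), cl0)
  # psi = 0 everywhere: pseudospecies contributes log((1-w) + w) = 0
  cl_zero_psi <- cell_loglik(0, c(0.5, 0.5), c(0, 0))
  expect_equal(augmented_species_logprob(0.7, cl_zero_psi, observed = FALSE),
               log(0.3 + 0.7 * exp(cl_zero_psi)))
  expect_equal(cl_zero_psi, 0)
  expect_equal(augmented_species_logprob(0.7, 0, observed = FALSE), 0)
})

test_that("fitting refuses masks that clip detected cells", {
  s <- small_sim()
  bundle <- small_bundle()
  det1 <- dplyr::filter(s$sim$detections, y == 1)[1, ]
  keep <- matrix(TRUE, length(bundle$species), length(bundle$site_ids),
                 dimnames = list(bundle$species, bundle$site_ids))
  keep[det1$species_id, det1$site_id] <- FALSE
  reason <- matrix(NA_character_, nrow(keep), ncol(keep))
  reason[!keep] <- "barrier"
  bad_mask <- new_clip_mask(keep, reason)
  S <- length(bundle$species)
  pars <- list(a = rep(0, S), c = rep(0, S),
               coefs = list(elev_m = rep(0, S), dist_range = rep(0, S)),
               d = list(time = 0))
  expect_error(dataset_logprob(pars, bundle, s$sim$detections, bad_mask),
               "errors of omission")
  spec <- model_spec(occupancy = c(elev_m = "random", dist_range = "random"),
                     detection = c(time = "fixed"), variant = "bmsom")
  expect_error(fit_occupancy(spec, bundle, s$sim$detections, bad_mask,
                             chains = 2, warmup = 10, draws = 10),
               "refusing to fit")
})
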