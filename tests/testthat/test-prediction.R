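test_that("conditional occupancy follows the Bayes update", {
  expect_equal(conditional_occupancy(0.5, 0.5, 0), 1 / 3)
  expect_equal(conditional_occupancy(0.5, c(0.5, 0.7), c(1, 0)), 1)
  # no information: prior returned
  expect_equal(conditional_occupancy(0.42, 0.9, 0, visit_mask = FALSE), 0.42)
  # monotone non-increasing in the number of zero visits
  z <- vapply(1:8, function(K) {
    conditional_occupancy(0.6, rep(0.4, K), rep(0, K))
  }, numeric(1))
  expect_true(all(diff(z) < 0))
  # K -> Inf with theta bounded away from 0: limit 0
  expect_lt(conditional_occupancy(0.6, rep(0.4, 60), rep(0, 60)), 1e-10)
})

test_that("occupancy surfaces honor clipped and projected modes", {
  sf <- small_fit()
  mask <- clip_by_distance(sf$bundle$distances_km, 500)
  surf_c <- occupancy_surface(sf$fit, mask = mask, mode = "clipped")
  surf_p <- occupancy_surface(sf$fit, mask = mask, mode = "projected")
  keep <- clip_mask_matrix(mask)
  kc <- keep[cbind(surf_c$species_id, surf_c$site_id)]
  # removed cells are exactly zero in clipped mode
  expect_true(all(surf_c$psi_mean[!kc] == 0))
  # the two modes differ only at removed cells
  expect_equal(surf_c$psi_mean[kc], surf_p$psi_mean[kc])
  expect_true(all(surf_p$psi_mean > 0))
  expect_true(all(surf_p$psi_mean >= surf_p$q5 & surf_p$psi_mean <= surf_p$q95))
})

test_that("prediction covariates reuse the training scaling", {
  sf <- small_fit()
  new_sites <- sf$sim$sites[1:5, ]
  pc <- prediction_covariates(sf$bundle, new_sites, sf$sim$ranges)
  expect_equal(pc$values$elev_m, sf$bundle$psi_covs$elev_m[1:5])
  expect_equal(pc$values$dist_range[, 1:5], sf$bundle$psi_covs$dist_range[, 1:5])
  surf <- occupancy_surface(sf$fit, new_sites = new_sites, ranges = sf$sim$ranges)
  surf0 <- occupancy_surface(sf$fit)
  joined <- dplyr::inner_join(surf, surf0, by = c("species_id", "site_id"))
  expect_equal(joined$psi_mean.x, joined$psi_mean.y)
})

test_that("richness respects its bounds and both modes agree in expectation", {
  sf <- small_fit()
  rich_e <- richness_profile(sf$fit, mode = "expectation")
  rich_b <- richness_profile(sf$fit, mode = "bernoulli", seed = 2)
  S <- length(sf$bundle$species)
  det_by_site <- sf$sim$detections |>
    dplyr::filter(y == 1) |>
    dplyr::distinct(species_id, site_id) |>
    dplyr::count(site_id)
  j <- dplyr::left_join(rich_e, det_by_site, by = "site_id") |>
    dplyr::mutate(n = ifelse(is.na(n), 0L, n))
  # richness >= number of species detected at the site, <= retained species
  expect_true(all(j$q10 >= j$n - 1e-9))
  expect_true(all(j$q90 <= S + 1e-9))
  # Bernoulli draws average to the expectation within Monte-Carlo error
  expect_lt(max(abs(rich_e$richness_mean - rich_b$richness_mean)), 1.0)
  expect_lt(mean(abs(rich_e$richness_mean - rich_b$richness_mean)), 0.25)
  # never-observed-only richness is bounded by the total
  rich_n <- richness_profile(sf$fit, include = "never_observed")
  expect_true(all(rich_n$richness_mean <= rich_e$richness_mean + 1e-9))
})

test_that("the land-use contrast recovers guild structure and pools never-observed species", {
  # bespoke community: half forest specialists (contrast -2), half generalists
  set.seed(55)
  S <- 12; J <- 60; K <- 4
  sp <- sprintf("g%02d", 1:S)
  habitat <- rep(c(0, 1), length.out = J) # forest 0 / pasture 1
  specialist <- rep(c(TRUE, FALSE), each = S / 2)
  beta_hab <- ifelse(specialist, -2, 0) + rnorm(S, 0, 0.2)
  a <- rnorm(S, 0.5, 0.5); cc <- rnorm(S, 0.5, 0.5)
  psi <- plogis(outer(a, rep(1, J)) + outer(beta_hab, habitat))
  Z <- matrix(rbinom(S * J, 1, psi), S, J)
  y <- array(rbinom(S * J * K, 1, rep(plogis(cc), J * K)), c(S, J, K)) *
    as.numeric(Z)
  det <- tidyr::expand_grid(species_id = sp, site_id = sprintf("q%02d", 1:J),
                            visit = 1:K)
  det$y <- as.integer(y[cbind(match(det$species_id, sp),
                              match(det$site_id, sprintf("q%02d", 1:J)),
                              det$visit)])
  sites <- tibble::tibble(site_id = sprintf("q%02d", 1:J), x_km = 0, y_km = 0,
                          habitat = habitat)
  ranges <- range_table(sp)
  spec <- model_spec(occupancy = c(habitat = "random"), variant = "msom")
  bundle <- build_covariate_bundle(ranges, sites, spec, n_visits = K)
  fit <- fit_occupancy(spec, bundle, det, chains = 2, warmup = 250,
                       draws = 250, seed = 77)
  tab <- pasture_effect_table(fit, term = "habitat", level_values = c(0, 1))
  med_spec <- median(tab$median[match(sp[specialist], tab$species_id)])
  med_gen <- median(tab$median[match(sp[!specialist], tab$species_id)])
  expect_lt(med_spec, med_gen)
  expect_lt(med_spec, -0.5)
  # a never-observed species still gets a finite, pooled contrast
  pool <- never_observed_species(det)
  if (length(pool) > 0) {
    expect_true(all(is.finite(tab$median[tab$species_id %in% pool])))
  }
  expect_error(pasture_effect_table(fit, term = "landuse"), "landuse")
})
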