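test_that("scaled inverse logit has the documented closed forms", {
  expect_equal(scaled_inverse_logit(0, 200), 0.5)
  expect_equal(scaled_inverse_logit(0, 50), 0.5)
  expect_equal(scaled_inverse_logit(200, 200), 1 / (1 + exp(-1)))
  expect_equal(scaled_inverse_logit(200, 200), 0.731059, tolerance = 1e-6)
  expect_lt(scaled_inverse_logit(-2000, 200), 1e-4)
  expect_error(scaled_inverse_logit(0, -1), "positive")
})

test_that("scaled inverse logit is increasing and satisfies f(-x) = 1 - f(x)", {
  x <- seq(-1000, 1000, by = 25)
  f <- scaled_inverse_logit(x, 200)
  expect_true(all(diff(f) > 0))
  expect_equal(scaled_inverse_logit(-x, 200), 1 - f)
})

test_that("standardized elevation maps range limits to +/-1 exactly", {
  expect_identical(standardize_elevation(2000, 1000, 2000), 1)
  expect_identical(standardize_elevation(1000, 1000, 2000), -1)
  expect_identical(standardize_elevation(1500, 1000, 2000), 0)
  expect_identical(standardize_elevation(2500, 1000, 2000), 2)
  expect_error(standardize_elevation(1, 2000, 1000), "below")
})

test_that("standardize then unstandardize is the identity", {
  set.seed(4)
  e <- runif(200, -500, 5000)
  s <- standardize_elevation(e, 800, 3100)
  expect_equal(unstandardize_elevation(s, 800, 3100), e, tolerance = 1e-12)
})

test_that("distance matrix has id dimnames and NA rows for unmapped species", {
  ranges <- range_table(c("a", "b"),
                        list(geom_disc(c(0, 0), 100), NULL),
                        elev_lower_m = c(100, 500),
                        elev_upper_m = c(1100, 1500))
  sites <- tibble::tibble(site_id = c("s1", "s2"), x_km = c(0, 200),
                          y_km = 0, elev_m = c(600, 1100))
  d <- signed_distance_matrix(ranges, sites)
  expect_equal(d["a", ], c(s1 = -100, s2 = 100))
  expect_true(all(is.na(d["b", ])))
  s <- std_elevation_matrix(ranges, sites)
  expect_equal(s["a", "s1"], 0)
  expect_equal(s["b", "s2"], 0.2)
})

test_that("the linearization diagnostic recovers the generative scale", {
  # occupancy generated as a logit-linear function of the 200-km transform;
  # naive occupancy observed without detection error
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6000
    d_km <- runif(n, -800, 800)
    p <- plogis(2 - 7 * scaled_inverse_logit(d_km, 200))
    occ <- rbinom(n, 1, p)
    det <- tibble::tibble(species_id = sprintf("c%04d", seq_len(n)),
                          site_id = "s1", visit = 1L, y = occ)
    dist <- matrix(d_km, n, 1,
                   dimnames = list(det$species_id, "s1"))
    diag_ <- linearization_diagnostic(det, dist,
                                      candidate_scales_km = c(50, 100, 200, 400))
    if (diag_$selected_scale_km == 200) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("degenerate binning errors and constant proportions tie-break small", {
  det <- tibble::tibble(species_id = c("a", "b"), site_id = "s1",
                        visit = 1L, y = c(1L, 0L))
  dist <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_error(linearization_diagnostic(det, dist), "insufficient occupancy variation")

  set.seed(9)
  n <- 400
  det2 <- tibble::tibble(species_id = sprintf("c%03d", 1:n), site_id = "s1",
                         visit = 1L, y = rep(c(0L, 1L), n / 2))
  dist2 <- matrix(seq(-400, 400, length.out = n), n, 1,
                  dimnames = list(det2$species_id, "s1"))
  # constant 50% occupancy in every bin
  expect_warning(res <- linearization_diagnostic(det2, dist2,
                                                 candidate_scales_km = c(100, 200)),
                 "constant")
  expect_true(res$constant_proportions)
  expect_equal(res$selected_scale_km, 100)
})

test_that("covariate bundles expose the terms the model specification requests", {
  s <- small_sim()
  spec1 <- model_spec(occupancy = c(elev_m = "random"), variant = "msom")
  b1 <- build_covariate_bundle(s$sim$ranges, s$sim$sites, spec1,
                               n_visits = s$cfg$n_visits)
  # site-level elevation only: no species-site occupancy matrices
  expect_false(any(vapply(b1$psi_covs, is.matrix, logical(1))))

  spec2 <- model_spec(occupancy = c(elev_m = "random", dist_range = "random"),
                      variant = "bmsom")
  b2 <- build_covariate_bundle(s$sim$ranges, s$sim$sites, spec2,
                               n_visits = s$cfg$n_visits)
  expect_true(is.matrix(b2$psi_covs$dist_range))
  expect_true(all(b2$psi_covs$dist_range > 0 & b2$psi_covs$dist_range < 1))

  expect_error(build_covariate_bundle(s$sim$ranges[0, ], s$sim$sites, spec2,
                                      n_visits = 3), "empty species")
  # elevational covariates need limits
  spec3 <- model_spec(occupancy = c(elev_range = "random"), variant = "bmsom")
  expect_error(build_covariate_bundle(s$sim$ranges, s$sim$sites, spec3,
                                      n_visits = 3), "limits are missing")
})
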