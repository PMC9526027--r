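test_that("distance clipping retains the boundary and removes beyond it", {
  d <- matrix(c(-50, 400, 401, 1000), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  m <- clip_by_distance(d, 400)
  mm <- clip_mask_matrix(m)
  expect_true(mm["a", "s1"])
  expect_true(mm["a", "s2"]) # exactly at the threshold: retained
  expect_false(mm["b", "s1"])
  expect_equal(m$reason[!m$retained], rep("geographic_distance", 2))
  # all in-range -> full mask
  m2 <- clip_by_distance(matrix(-abs(d), 2, 2, dimnames = dimnames(d)), 400)
  expect_true(all(m2$retained))
})

test_that("standardized-elevation clipping keeps [-3, 3] and warns on NA rows", {
  s <- matrix(c(3, 3.5, -3, -3.01, NA, NA), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "nolim"), c("s1", "s2")))
  expect_warning(m <- clip_by_std_elevation(s), "nolim")
  mm <- clip_mask_matrix(m)
  expect_true(mm["a", "s1"]) # boundary retained
  expect_false(mm["a", "s2"])
  expect_true(mm["b", "s1"])
  expect_false(mm["b", "s2"])
  expect_true(all(mm["nolim", ]))
  expect_equal(unique(m$reason[!m$retained]), "standardized_elevation")
})

test_that("temporal clipping handles residents, windows and wrap-around", {
  ranges <- range_table(c("res", "mig", "wrap"),
                        season_start = c(NA, 100, 300),
                        season_end = c(NA, 200, 60))
  doy <- matrix(c(150, 250, 20, 150, 250, 20), 3, 2)
  tm <- clip_temporal(doy, ranges, sites = c("s1", "s2", "s3"), n_visits = 2)
  vr <- tm$visit_retained
  get <- function(sp, st) vr$retained[vr$species_id == sp & vr$site_id == st][1]
  expect_true(get("res", "s1") && get("res", "s2") && get("res", "s3"))
  expect_true(get("mig", "s1"))
  expect_false(get("mig", "s2"))
  expect_false(get("wrap", "s1")) # day 150 outside 300..60
  expect_true(get("wrap", "s3"))  # day 20 inside the wrap-around window
  # brute-force day-by-day membership for the wrap-around window
  days <- 1:366
  manual <- days >= 300 | days <= 60
  expect_identical(bmsom:::in_season(days, 300, 60), manual)
  # fully out-of-window cells are removed with reason temporal
  cm <- clip_mask_matrix(tm$cell_mask)
  expect_false(cm["mig", "s2"])
  expect_equal(tm$cell_mask$reason[!tm$cell_mask$retained] |> unique(), "temporal")
})

test_that("mask combination is an AND with precedence-ordered reasons", {
  sp <- c("a", "b"); st <- c("s1", "s2")
  m1 <- new_clip_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2,
                             dimnames = list(sp, st)),
                      matrix(c(NA, "temporal", NA, NA), 2, 2))
  m2 <- new_clip_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
                             dimnames = list(sp, st)),
                      matrix(c(NA, "geographic_distance", "standardized_elevation", NA), 2, 2))
  cmb <- combine_masks(m1, m2)
  mm <- clip_mask_matrix(cmb)
  expect_identical(as.logical(mm), c(TRUE, FALSE, FALSE, TRUE))
  # cell removed by both temporal and geographic: geographic wins
  expect_equal(cmb$reason[cmb$species_id == "b" & cmb$site_id == "s1"],
               "geographic_distance")
  expect_equal(cmb$reason[cmb$species_id == "a" & cmb$site_id == "s2"],
               "standardized_elevation")
  # single mask -> identity
  expect_identical(clip_mask_matrix(combine_masks(m1)), clip_mask_matrix(m1))
  m3 <- new_clip_mask(matrix(TRUE, 3, 3, dimnames = list(letters[1:3], 1:3)))
  expect_error(combine_masks(m1, m3), "mismatched")
})

test_that("counts are conserved and clipping is monotone in the threshold", {
  s <- small_sim()
  d <- signed_distance_matrix(s$sim$ranges, s$sim$sites)
  m_tight <- clip_by_distance(d, 200)
  m_wide <- clip_by_distance(d, 600)
  expect_equal(sum(m_tight$retained) + sum(!m_tight$retained),
               nrow(s$sim$ranges) * nrow(s$sim$sites))
  # every cell the tight mask keeps, the wide mask keeps
  expect_true(all(!m_tight$retained | m_wide$retained))
})

test_that("detections at clipped cells are flagged and fixed by widening the range", {
  ranges <- range_table("sp1", list(geom_disc(c(0, 0), 50)))
  sites <- tibble::tibble(site_id = c("near", "far"), x_km = c(0, 600), y_km = 0)
  det <- tibble::tibble(species_id = "sp1", site_id = c("near", "far"),
                        visit = 1L, y = c(1L, 1L))
  d <- signed_distance_matrix(ranges, sites)
  mask <- clip_by_distance(d, 400)
  viol <- validate_mask_against_detections(mask, det)
  expect_equal(nrow(viol), 1)
  expect_equal(viol$site_id, "far")
  # widening the offending species' range clears the violation
  ranges2 <- range_table("sp1", list(geom_disc(c(0, 0), 300)))
  mask2 <- clip_by_distance(signed_distance_matrix(ranges2, sites), 400)
  expect_equal(nrow(validate_mask_against_detections(mask2, det)), 0)
})

test_that("max detection distance report summarizes the empirical support", {
  s <- small_sim()
  d <- signed_distance_matrix(s$sim$ranges, s$sim$sites)
  rep_ <- max_detection_distance(s$sim$detections, d)
  expect_equal(nrow(rep_), 1)
  expect_true(rep_$n_detected_cells > 0)
  expect_true(is.finite(rep_$max_detection_distance_km))
  det_cells <- dplyr::distinct(dplyr::filter(s$sim$detections, y == 1),
                               species_id, site_id)
  expect_equal(rep_$max_detection_distance_km,
               max(d[cbind(det_cells$species_id, det_cells$site_id)]))
})
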