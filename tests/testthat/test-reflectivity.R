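test_that("masked mean matches brute force and rejects empty masks", {
  set.seed(101)
  for (i in 1:10) {
    q <- matrix(runif(64, 0, 255), 8, 8)
    m <- matrix(runif(64) < 0.4, 8, 8)
    if (!any(m)) m[1, 1] <- TRUE
    expect_equal(mean_reflectivity_on_mask(q, m), sum(q[m]) / sum(m))
  }
  expect_equal(mean_reflectivity_on_mask(matrix(140, 4, 4),
                                         matrix(c(TRUE, FALSE), 4, 4)), 140)
  expect_error(mean_reflectivity_on_mask(matrix(1, 4, 4),
                                         matrix(FALSE, 4, 4)),
               class = "perivasc_no_hss_error")
  expect_error(mean_reflectivity_on_mask(matrix(1, 4, 4),
                                         matrix(TRUE, 3, 3)),
               class = "perivasc_geometry_error")
})

test_that("constant structural image gives corrected reflectivity exactly 1", {
  pair <- make_test_pair(16, block = 3:5, struct_on = 140, struct_off = 140)
  r <- corrected_reflectivity(pair$structural, pair$octa, "Q1")
  expect_identical(r$corrected, 1)
  expect_equal(r$mean_on_hss, 140)
})

test_that("two-level mixture with 10% HSS gives 200/110", {
  # bright block = 40 px = 10% of a 20 x 20 image, all inside Q1;
  # whole-image threshold statistics select exactly the block
  octa <- matrix(0, 20, 20); octa[1:5, 1:8] <- 200
  st <- matrix(100, 20, 20); st[1:5, 1:8] <- 200
  r <- corrected_reflectivity(enface_image(st, "structural"),
                              enface_image(octa, "angiography"), "Q1",
                              threshold_scope = "image")
  expect_equal(r$hss_area_px, 40)
  expect_equal(r$corrected, 200 / 110, tolerance = 1e-12)
})

test_that("corrected reflectivity is invariant under uniform structural gain", {
  pair <- make_test_pair()
  base <- corrected_reflectivity(pair$structural, pair$octa, "Q1")$corrected
  for (k in c(0.35, 0.8, 1.3)) {
    scaled <- enface_image(pair$structural$pixels * k, "structural")
    r <- corrected_reflectivity(scaled, pair$octa, "Q1")$corrected
    expect_equal(r, base, tolerance = 1e-12)
  }
})

test_that("raising structural intensity only on the HSS area strictly increases the ratio", {
  pair <- make_test_pair()
  r0 <- corrected_reflectivity(pair$structural, pair$octa, "Q1")
  # rebuild the HSS mask in image coordinates and bump only those pixels
  q_octa <- split_quadrants(pair$octa$pixels)$Q1
  hss <- filter_particles(binarize(q_octa, compute_threshold(q_octa)))
  st <- pair$structural$pixels
  bumped <- st
  bumped[1:8, 1:8][hss$mask] <- bumped[1:8, 1:8][hss$mask] + 10
  r1 <- corrected_reflectivity(enface_image(bumped, "structural"),
                               pair$octa, "Q1")
  expect_gt(r1$corrected, r0$corrected)
})

test_that("degenerate inputs raise typed errors", {
  # constant OCTA: strict threshold leaves nothing above mean + 2 SD
  st <- enface_image(matrix(100, 8, 8), "structural")
  oc <- enface_image(matrix(50, 8, 8), "angiography")
  expect_error(corrected_reflectivity(st, oc, "Q1"),
               class = "perivasc_no_hss_error")
  # all-zero structural image: denominator undefined
  pair <- make_test_pair(16, struct_on = 0, struct_off = 0)
  expect_error(corrected_reflectivity(pair$structural, pair$octa, "Q1"),
               class = "perivasc_degenerate_error")
  # swapped modalities
  expect_error(corrected_reflectivity(pair$octa, pair$octa, "Q1"),
               class = "perivasc_input_error")
})
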