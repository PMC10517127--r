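test_that("vessel density splits a two-level histogram at the mean", {
  px <- matrix(0, 16, 16); px[, 9:16] <- 255
  oc <- enface_image(px, "angiography")
  expect_equal(vessel_density(oc), 50)
  expect_warning(vessel_density(enface_image(matrix(7, 8, 8), "angiography")),
                 class = "perivasc_degenerate_warning")
})

test_that("vessel density is invariant under positive-gain affine transforms", {
  set.seed(202)
  px <- matrix(round(runif(256, 0, 200)), 16, 16)
  oc1 <- enface_image(px, "angiography")
  oc2 <- enface_image(px * 0.8 + 10, "angiography")
  expect_equal(vessel_density(oc1), vessel_density(oc2))
})

test_that("FAZ exclusion removes pixels from threshold and denominator", {
  set.seed(203)
  px <- matrix(round(runif(400, 0, 255)), 20, 20)
  fz <- matrix(FALSE, 20, 20); fz[8:13, 8:13] <- TRUE
  oc <- enface_image(px, "angiography")
  got <- vessel_density(oc, faz_mask(fz))
  keep <- px[!fz]
  expect_equal(got, 100 * sum(keep > mean(keep)) / length(keep))
  expect_error(vessel_density(oc, faz_mask(matrix(TRUE, 20, 20))),
               class = "perivasc_input_error")
})

test_that("FAZ morphometrics: disc, line and square behave as closed forms say", {
  pitch <- 3 / 320 # mm per pixel at the standard geometry
  # digital disc: area ~ pi r^2, circularity ~ 1 within digitization error
  r <- 40
  disc <- outer(-50:50, -50:50, function(i, j) i^2 + j^2 <= r^2)
  fm <- faz_metrics(disc, extent_mm = 3, side_px = 320)
  expect_equal(fm$area_mm2, sum(disc) * pitch^2)
  expect_equal(fm$perimeter_mm, 2 * pi * r * pitch, tolerance = 0.02)
  expect_gt(fm$circularity, 0.95)
  expect_lt(fm$circularity, 1.05)
  # 1-pixel line: heavily elongated
  line <- matrix(FALSE, 50, 50); line[25, 5:45] <- TRUE
  expect_lt(faz_metrics(line, 3, 320)$circularity, 0.2)
  # square: area exact, circularity between line and disc
  sq <- matrix(FALSE, 60, 60); sq[11:40, 11:40] <- TRUE
  fmsq <- faz_metrics(sq, 3, 320)
  expect_equal(fmsq$area_mm2, 30^2 * pitch^2)
  expect_error(faz_metrics(matrix(FALSE, 4, 4)),
               class = "perivasc_input_error")
})

test_that("circularity of regular shapes increases with vertex count", {
  grid <- expand.grid(x = -60:60, y = -60:60)
  R <- 45
  sq <- matrix(abs(grid$x) <= R / sqrt(2) & abs(grid$y) <= R / sqrt(2),
               121, 121)
  a <- R * sqrt(3) / 2 # hexagon apothem
  hexa <- matrix(abs(grid$y) <= a &
                   abs(sqrt(3) * grid$x + grid$y) / 2 <= a &
                   abs(sqrt(3) * grid$x - grid$y) / 2 <= a, 121, 121)
  disc <- matrix(grid$x^2 + grid$y^2 <= R^2, 121, 121)
  circ <- vapply(list(sq, hexa, disc),
                 function(m) faz_metrics(m, 3, 320)$circularity, 0)
  expect_true(all(diff(circ) > 0))
  expect_lt(circ[3], 1.05)
})

test_that("FAZ area scales quadratically with physical extent", {
  m <- outer(-20:20, -20:20, function(i, j) i^2 + j^2 <= 10^2)
  f1 <- faz_metrics(m, extent_mm = 3, side_px = 320)
  f2 <- faz_metrics(m, extent_mm = 6, side_px = 320)
  expect_equal(f2$area_mm2 / f1$area_mm2, 4)
  expect_equal(f2$circularity, f1$circularity)
})

test_that("faz_mask warns on fragmented or off-centre regions", {
  m <- matrix(FALSE, 20, 20); m[2:3, 2:3] <- TRUE; m[15:16, 15:16] <- TRUE
  expect_warning(faz_mask(m), class = "perivasc_faz_warning")
  ok <- matrix(FALSE, 20, 20); ok[8:13, 8:13] <- TRUE
  expect_silent(faz_mask(ok))
})
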