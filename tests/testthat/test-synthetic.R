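test_that("the generator is fully deterministic given (seed, config)", {
  cfg <- synthetic_config(seed = 9, side_px = 128,
                          n_per_group = c(recurrent = 2L, indolent = 1L,
                                          control = 2L))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  for (i in seq_along(a$eyes)) {
    expect_identical(a$eyes[[i]]$structural$pixels,
                     b$eyes[[i]]$structural$pixels)
    expect_identical(a$eyes[[i]]$octa$pixels, b$eyes[[i]]$octa$pixels)
  }
  expect_identical(generate_vessel_tree(cfg, seed = 5),
                   generate_vessel_tree(cfg, seed = 5))
})

test_that("vessel trees hit the coverage target and stay connected", {
  cfg <- synthetic_config(seed = 1, side_px = 128, target_coverage = 0.15)
  for (s in 1:5) {
    v <- generate_vessel_tree(cfg, seed = s)
    expect_gte(mean(v), 0.12)
    expect_lte(mean(v), 0.18)
    expect_equal(max(label_components(v, 8)), 1)
  }
  # zero coverage: empty mask
  cfg0 <- synthetic_config(seed = 1, side_px = 64, target_coverage = 0)
  expect_false(any(generate_vessel_tree(cfg0, seed = 1)))
})

test_that("rendered images are 8-bit quantized and carry the right metadata", {
  cfg <- synthetic_config(seed = 2, side_px = 128)
  v <- generate_vessel_tree(cfg, seed = 2)
  p <- render_pair(v, cfg, delta = 30, obstructive_quadrant = "Q2",
                   quality = 77)
  for (img in list(p$structural, p$octa)) {
    px <- img$pixels
    expect_true(all(px == round(px)))
    expect_gte(min(px), 0)
    expect_lte(max(px), 255)
    expect_equal(img$quality, 77)
  }
  expect_identical(p$structural$modality, "structural")
  expect_identical(p$octa$modality, "angiography")
  # the rim never overlaps the vessel core
  expect_false(any(p$rim & p$vessel))
})

test_that("planted elevation is recovered: null, strong and monotone cases", {
  cfg <- synthetic_config(seed = 3, side_px = 128)
  measure <- function(delta, seed) {
    set.seed(seed)
    v <- generate_vessel_tree(cfg)
    p <- render_pair(v, cfg, delta = delta, obstructive_quadrant = "Q1")
    c(obs = corrected_reflectivity(p$structural, p$octa, "Q1")$corrected,
      con = corrected_reflectivity(p$structural, p$octa, "Q4")$corrected)
  }
  # delta = 0: obstructive and contralateral agree within 2 SE over 30 seeds
  d0 <- t(vapply(1:30, function(s) measure(0, s), c(obs = 0, con = 0)))
  diffs <- d0[, "obs"] - d0[, "con"]
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
  # large delta: strictly higher in the obstructive quadrant, every seed
  d60 <- t(vapply(31:40, function(s) measure(60, s), c(obs = 0, con = 0)))
  expect_true(all(d60[, "obs"] > d60[, "con"]))
  # mean effect non-decreasing in delta
  mean_eff <- vapply(c(0, 10, 20, 40), function(delta) {
    mean(vapply(41:60, function(s) {
      m <- measure(delta, s); m["obs"] - m["con"]
    }, 0))
  }, 0)
  expect_true(all(diff(mean_eff) > 0))
})

test_that("cohort structure mirrors the study arms and covariate links", {
  cfg <- synthetic_config(seed = 4, side_px = 128)
  expect_equal(unname(cfg$n_per_group), c(45L, 30L, 45L))
  co <- generate_cohort(synthetic_config(seed = 4, side_px = 64,
                                         n_per_group = c(recurrent = 4L,
                                                         indolent = 3L,
                                                         control = 4L)))
  rec <- co$records
  expect_equal(nrow(rec), 11)
  expect_true(all(is.na(rec$obstructive_quadrant[rec$group == "control"])))
  expect_true(all(rec$measure_quadrant %in% quadrant_labels()))
  truths <- vapply(co$eyes, function(e) e$truth$delta, 0)
  expect_true(all(truths[rec$group == "control"] == 0))
  expect_true(all(truths[rec$group != "control"] > 0))
  expect_true(all(is.na(rec$injections_per_year[rec$group == "control"])))

  # injections/year tracks the planted elevation in the tabular arm
  tab <- simulate_records(synthetic_config(
    seed = 11, n_per_group = c(recurrent = 400L, indolent = 0L,
                               control = 0L)))
  expect_gt(cor(tab$injections_per_year, tab$delta), 0.4)
  # and the derived-noise mode plants a chosen correlation
  cfg_b <- synthetic_config(seed = 12, inj_beta = 0.5, inj_intercept = 5,
                            n_per_group = c(recurrent = 2000L,
                                            indolent = 0L, control = 0L))
  tab_b <- simulate_records(cfg_b)
  expect_equal(cor(tab_b$injections_per_year, tab_b$delta), 0.5,
               tolerance = 0.06)
})

test_that("unreachable coverage targets raise a typed error", {
  cfg <- synthetic_config(seed = 1, side_px = 64, target_coverage = 0.4,
                          max_walks = 3L)
  expect_error(generate_vessel_tree(cfg, seed = 1),
               class = "perivasc_coverage_error")
})
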