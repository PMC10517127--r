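#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the simulator: image geometry, vessel-tree shape,
#' the intensity model for both modalities, the per-group perivascular
#' elevation planted in the obstructive quadrant, and the coefficients
#' linking clinical covariates to that elevation. Defaults reproduce the
#' study conditions the analysis chain expects: arm sizes 45/30/45
#' (recurrent BRVO, indolent BRVO, control), 320 x 320 px over 3.0 x 3.0 mm,
#' and group elevations ordered recurrent > indolent > control = 0,
#' calibrated so the measured corrected reflectivity group means fall near
#' 1.31 / 1.22 / 1.19.
#'
#' @param seed integer seed; the same (seed, config) pair yields
#'   byte-identical cohorts.
#' @param side_px image side in pixels (default 320).
#' @param extent_mm physical side length in mm (default 3.0).
#' @param n_per_group named integer triple
#'   `c(recurrent = , indolent = , control = )`.
#' @param target_coverage vessel-mask coverage fraction the tree generator
#'   aims for (default 0.15); 0 produces an empty vessel mask.
#' @param vessel_halfwidth_px half-width of the stamped vessel in pixels.
#' @param walk_wiggle angular diffusion (radians/step) of the vessel walk.
#' @param max_walks bound on trunk + branch walks before the generator gives
#'   up on the coverage target.
#' @param struct_bg_mean,struct_bg_sd structural background intensity model.
#' @param struct_vessel_contrast structural elevation on vessel and
#'   1-px margin pixels (all eyes; sets the control-level baseline ratio).
#' @param octa_bg_mean,octa_bg_sd OCTA background (Gaussian part).
#' @param octa_vessel_signal,octa_margin_signal mean OCTA flow signal on the
#'   vessel core and its 1-px margin.
#' @param octa_noise_sd per-pixel SD of the flow signal; flow in real
#'   angiograms is heterogeneous, and this spread is what gives the
#'   mean + 2 SD threshold a smooth top tail to select from.
#' @param speckle_scale Rayleigh speckle scale added to OCTA background.
#' @param delta_mean,delta_sd named per-group mean and SD of the perivascular
#'   structural elevation delta (8-bit intensity units), drawn per eye from a
#'   Gamma distribution (delta >= 0 by construction); controls get exactly 0.
#' @param rim_px radius of the perivascular rim: dilation of the vessel mask
#'   by `rim_px` minus the vessel itself; delta is added there, only inside
#'   the obstructive quadrant.
#' @param inj_intercept,inj_slope,inj_sd linear-Gaussian link from delta to
#'   injections per year (truncated at 0).
#' @param inj_beta optional target correlation between injections/year and
#'   delta; when set, `inj_sd` is derived from `inj_slope` and the recurrent
#'   delta SD so the planted standardized beta equals `inj_beta`.
#' @param se_slope link from delta to refractive spherical equivalent.
#' @param faz_radius_frac FAZ disc radius as a fraction of `side_px`.
#' @param quality_range range of simulated image-quality scores.
#' @param record_model intercept/slope/sd of the tabular (image-free)
#'   reflectivity approximation used by [simulate_records()].
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             side_px = 320L,
                             extent_mm = 3.0,
                             n_per_group = c(recurrent = 45L, indolent = 30L,
                                             control = 45L),
                             target_coverage = 0.12,
                             vessel_halfwidth_px = 1L,
                             walk_wiggle = 0.25,
                             max_walks = 400L,
                             struct_bg_mean = 100, struct_bg_sd = 12,
                             struct_vessel_contrast = 23.5,
                             octa_bg_mean = 30, octa_bg_sd = 10,
                             octa_vessel_signal = 175,
                             octa_margin_signal = 155,
                             octa_noise_sd = 40,
                             speckle_scale = 8,
                             delta_mean = c(recurrent = 53, indolent = 13,
                                            control = 0),
                             delta_sd = c(recurrent = 18, indolent = 10,
                                          control = 0),
                             rim_px = 2L,
                             inj_intercept = 0,
                             inj_slope = 0.045,
                             inj_sd = 0.8,
                             inj_beta = NULL,
                             se_slope = 0.02,
                             faz_radius_frac = 0.115,
                             quality_range = c(70, 95),
                             record_model = list(intercept = 1.19,
                                                 slope = 0.0023,
                                                 sd = 0.007)) {
  groups <- c("recurrent", "indolent", "control")
  stopifnot(all(groups %in% names(n_per_group)),
            all(groups %in% names(delta_mean)),
            all(groups %in% names(delta_sd)),
            side_px %% 2L == 0L, side_px > 0L, extent_mm > 0,
            target_coverage >= 0, target_coverage < 0.5)
  if (!is.null(inj_beta)) {
    stopifnot(inj_beta > 0, inj_beta < 1)
    sig <- inj_slope * delta_sd[["recurrent"]]
    inj_sd <- sig * sqrt(1 / inj_beta^2 - 1)
  }
  structure(list(
    seed = as.integer(seed), side_px = as.integer(side_px),
    extent_mm = extent_mm, n_per_group = n_per_group[groups],
    target_coverage = target_coverage,
    vessel_halfwidth_px = as.integer(vessel_halfwidth_px),
    walk_wiggle = walk_wiggle, max_walks = as.integer(max_walks),
    struct_bg_mean = struct_bg_mean, struct_bg_sd = struct_bg_sd,
    struct_vessel_contrast = struct_vessel_contrast,
    octa_bg_mean = octa_bg_mean, octa_bg_sd = octa_bg_sd,
    octa_vessel_signal = octa_vessel_signal,
    octa_margin_signal = octa_margin_signal,
    octa_noise_sd = octa_noise_sd, speckle_scale = speckle_scale,
    delta_mean = delta_mean[groups], delta_sd = delta_sd[groups],
    rim_px = as.integer(rim_px),
    inj_intercept = inj_intercept, inj_slope = inj_slope, inj_sd = inj_sd,
    inj_beta = inj_beta, se_slope = se_slope,
    faz_radius_frac = faz_radius_frac, quality_range = quality_range,
    record_model = record_model), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> seed %d, %d x %d px, %.1f mm\n",
              x$seed, x$side_px, x$side_px, x$extent_mm))
  cat(sprintf("  arms (rec/ind/ctl): %d/%d/%d, delta means %.0f/%.0f/%.0f\n",
              x$n_per_group[1], x$n_per_group[2], x$n_per_group[3],
              x$delta_mean[1], x$delta_mean[2], x$delta_mean[3]))
  invisible(x)
}

# Chebyshev (square structuring element) binary dilation by radius r,
# implemented with matrix shifts.
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(FALSE, n, m)
  for (di in -r:r) {
    rs <- max(1, 1 + di):min(n, n + di)
    ro <- max(1, 1 - di):min(n, n - di)
    for (dj in -r:r) {
      cs <- max(1, 1 + dj):min(m, m + dj)
      co <- max(1, 1 - dj):min(m, m - dj)
      out[ro, co] <- out[ro, co] | mask[rs, cs]
    }
  }
  out
}

# Stamp a centerline (integer rows/cols) thickened by half-width hw.
stamp_walk <- function(mask, rows, cols, hw) {
  n <- nrow(mask)
  off <- -hw:hw
  for (di in off) {
    r <- rows + di
    for (dj in off) {
      c <- cols + dj
      ok <- r >= 1L & r <= n & c >= 1L & c <= n
      mask[cbind(r[ok], c[ok])] <- TRUE
    }
  }
  mask
}

#' Generate a synthetic vessel-tree mask
#'
#' Draws one trunk from a random border point through the field and grows
#' branches from points of the existing tree until the thickened mask reaches
#' the target coverage fraction. Each walk is a correlated random walk (unit
#' steps, Gaussian angular diffusion), so the mask is a connected, branching,
#' curvilinear structure. Branch origins are steered towards the quadrant
#' with the lowest current coverage, keeping the network spatially even the
#' way a healthy capillary plexus is; without this the mean + 2 SD threshold
#' of a vessel-saturated quadrant can exceed the 8-bit ceiling. Uses the
#' current RNG state unless `seed` is given; identical seeds yield identical
#' masks.
#'
#' @param config a [synthetic_config()].
#' @param seed optional integer seed applied locally.
#' @return logical `side_px` x `side_px` vessel mask.
#' @export
generate_vessel_tree <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$side_px
  h <- n %/% 2L
  mask <- matrix(FALSE, n, n)
  if (config$target_coverage == 0) return(mask)
  hw <- config$vessel_halfwidth_px
  centerline_r <- integer(0); centerline_c <- integer(0)
  coverage <- 0; walks <- 0L
  target <- config$target_coverage
  quad_centers <- rbind(Q1 = c(h / 2, h / 2), Q2 = c(h / 2, n - h / 2),
                        Q3 = c(n - h / 2, h / 2), Q4 = c(n - h / 2, n - h / 2))
  while (coverage < 0.95 * target && walks < config$max_walks) {
    walks <- walks + 1L
    if (length(centerline_r) == 0L) {
      # trunk: start on a border, head towards the centre
      side <- sample.int(4L, 1L)
      pos <- runif(1, 0.2, 0.8) * n
      start <- switch(side,
                      c(1, pos), c(n, pos), c(pos, 1), c(pos, n))
      ang <- atan2(n / 2 - start[1], n / 2 - start[2]) + rnorm(1, 0, 0.2)
      len <- round(runif(1, 0.8, 1.4) * n)
    } else {
      # branch from the quadrant currently poorest in vessels
      q <- split_quadrants(mask)
      lightest <- names(q)[which.min(vapply(q, mean, 0))]
      pt_quad <- paste0("Q", 1L + (centerline_c > h) + 2L * (centerline_r > h))
      in_quad <- which(pt_quad == lightest)
      if (length(in_quad)) {
        i <- in_quad[sample.int(length(in_quad), 1L)]
        start <- c(centerline_r[i], centerline_c[i])
        ang <- runif(1, 0, 2 * pi)
      } else {
        # no vessel there yet: grow from the closest point towards it
        ctr <- quad_centers[lightest, ]
        d2 <- (centerline_r - ctr[1])^2 + (centerline_c - ctr[2])^2
        i <- which.min(d2)
        start <- c(centerline_r[i], centerline_c[i])
        ang <- atan2(ctr[1] - start[1], ctr[2] - start[2]) +
          rnorm(1, 0, 0.2)
      }
      len <- round(runif(1, 0.15, 0.35) * n)
    }
    dang <- cumsum(rnorm(len, 0, config$walk_wiggle))
    angs <- ang + dang
    rows <- round(start[1] + cumsum(sin(angs)))
    cols <- round(start[2] + cumsum(cos(angs)))
    inside <- rows >= 1L & rows <= n & cols >= 1L & cols <= n
    # stop the walk at the border, or when it crosses into a quadrant
    # already holding more than 1.4x its share of the coverage target
    # (the origin quadrant is exempt so walks can always escape it)
    dense <- vapply(split_quadrants(mask), mean, 0) > 1.4 * target
    origin_quad <- paste0("Q", 1L + (start[2] > h) + 2L * (start[1] > h))
    step_quad <- paste0("Q", 1L + (pmin(pmax(cols, 1L), n) > h) +
                          2L * (pmin(pmax(rows, 1L), n) > h))
    stop_at <- which(!inside |
                       (dense[step_quad] & step_quad != origin_quad))[1]
    if (!is.na(stop_at)) {
      if (stop_at == 1L) next
      rows <- rows[seq_len(stop_at - 1L)]
      cols <- cols[seq_len(stop_at - 1L)]
    }
    centerline_r <- c(centerline_r, rows)
    centerline_c <- c(centerline_c, cols)
    mask <- stamp_walk(mask, rows, cols, hw)
    coverage <- sum(mask) / (n * n)
  }
  if (coverage < 0.8 * target) {
    pv_stop(sprintf(
      "vessel coverage target %.3f unreachable (%.3f after %d walks)",
      target, coverage, walks), "perivasc_coverage_error")
  }
  mask
}

clip8 <- function(x) {
  matrix(pmin(255, pmax(0, round(x))), nrow(x), ncol(x))
}

quadrant_mask <- function(label, n) {
  m <- matrix(FALSE, n, n)
  idx <- quadrant_indices(label, n)
  m[idx$rows, idx$cols] <- TRUE
  m
}

#' Render one synthetic structural/OCTA image pair
#'
#' Builds the two co-registered modalities from a vessel mask. The OCTA image
#' is Gaussian background plus Rayleigh-like speckle, with a bright flow
#' signal on the vessel core and a slightly dimmer 1-px margin. The
#' structural image is Gaussian background with a fixed vessel-associated
#' elevation everywhere, plus the planted perivascular elevation `delta` on
#' the dilated rim around vessels (dilation by `rim_px` minus the vessel),
#' restricted to the obstructive quadrant. Both images are quantized to
#' 8 bits.
#'
#' @param vessel logical vessel mask from [generate_vessel_tree()].
#' @param config a [synthetic_config()].
#' @param delta non-negative perivascular elevation for this eye.
#' @param obstructive_quadrant quadrant label receiving the elevation, or
#'   `NA` for none.
#' @param quality image quality score stored on both images.
#' @return list with `structural` and `octa` [enface_image()]s and the
#'   ground-truth pieces `vessel`, `rim`, `delta`, `obstructive_quadrant`.
#' @export
render_pair <- function(vessel, config, delta = 0,
                        obstructive_quadrant = NA_character_,
                        quality = 80) {
  stopifnot(inherits(config, "synthetic_config"), delta >= 0)
  n <- nrow(vessel)
  core <- vessel
  margin <- dilate_mask(core, 1L) & !core
  rim <- dilate_mask(core, config$rim_px) & !core

  octa <- matrix(rnorm(n * n, config$octa_bg_mean, config$octa_bg_sd), n, n) +
    config$speckle_scale * sqrt(-2 * log(matrix(runif(n * n), n, n)))
  nv <- sum(core); nm <- sum(margin)
  if (nv) octa[core] <- config$octa_vessel_signal +
      rnorm(nv, 0, config$octa_noise_sd)
  if (nm) octa[margin] <- config$octa_margin_signal +
      rnorm(nm, 0, config$octa_noise_sd)

  struct <- matrix(rnorm(n * n, config$struct_bg_mean, config$struct_bg_sd),
                   n, n)
  perivascular <- core | margin
  struct[perivascular] <- struct[perivascular] + config$struct_vessel_contrast
  if (!is.na(obstructive_quadrant) && delta > 0) {
    tgt <- rim & quadrant_mask(obstructive_quadrant, n)
    struct[tgt] <- struct[tgt] + delta
  }
  list(structural = enface_image(clip8(struct), "structural",
                                 extent_mm = config$extent_mm,
                                 quality = quality),
       octa = enface_image(clip8(octa), "angiography",
                           extent_mm = config$extent_mm, quality = quality),
       vessel = core, rim = rim, delta = delta,
       obstructive_quadrant = obstructive_quadrant)
}

draw_gamma <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, scale = sd^2 / mean)
}

#' Generate a full synthetic cohort
#'
#' Produces, for each eye, a paired structural/OCTA image, a FAZ mask, the
#' per-eye covariate record, and the retained ground truth (delta, the
#' obstructive quadrant, the vessel mask). Group elevations follow the
#' configured ordering (recurrent > indolent > control = 0); injections per
#' year and refractive error are linked linearly to each eye's delta;
#' remaining covariates are drawn from group-typical normals. Control eyes
#' carry no obstructive quadrant but are assigned a measurement quadrant so
#' the same procedure can be run on them. The whole cohort is a deterministic
#' function of `(seed, config)`.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_cohort`: list with `eyes` (list of
#'   per-eye lists: `structural`, `octa`, `faz`, `truth`), `records` (the
#'   covariate data frame), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$side_px
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n_eyes <- length(groups)
  if (n_eyes < 1L) pv_stop("cohort is empty", "perivasc_input_error")

  # central FAZ disc, cleared of vessels
  r_faz <- max(2L, round(config$faz_radius_frac * n))
  ctr <- (n + 1) / 2
  faz <- outer(seq_len(n), seq_len(n),
               function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r_faz^2)

  eyes <- vector("list", n_eyes)
  records <- vector("list", n_eyes)
  for (i in seq_len(n_eyes)) {
    g <- groups[i]
    eye_id <- sprintf("eye%03d", i)
    vessel <- generate_vessel_tree(config)
    vessel[faz] <- FALSE
    delta <- if (g == "control") 0 else
      draw_gamma(1, config$delta_mean[[g]], config$delta_sd[[g]])
    quad <- sample(quadrant_labels(), 1L)
    obstructive <- if (g == "control") NA_character_ else quad
    quality <- runif(1, config$quality_range[1], config$quality_range[2])
    pair <- render_pair(vessel, config, delta = delta,
                        obstructive_quadrant = obstructive,
                        quality = quality)

    is_brvo <- g != "control"
    age <- rnorm(1, if (is_brvo) 64.5 else 62.0, if (is_brvo) 10.3 else 8.3)
    inj <- if (is_brvo) {
      max(0, config$inj_intercept + config$inj_slope * delta +
            rnorm(1, 0, config$inj_sd))
    } else NA_real_
    duration <- if (is_brvo) round(rlnorm(1, meanlog = 3.3, sdlog = 0.75))
                else NA_real_
    bcva_mean <- c(recurrent = 0.336, indolent = 0.251, control = 0.048)[[g]]
    bcva_sd <- c(recurrent = 0.26, indolent = 0.19, control = 0.07)[[g]]
    records[[i]] <- data.frame(
      eye_id = eye_id, group = g,
      measure_quadrant = quad,
      obstructive_quadrant = obstructive,
      quality = quality,
      age = round(age, 1),
      sex = sample(c("M", "F"), 1L, prob = c(0.37, 0.63)),
      laterality = sample(c("OD", "OS"), 1L),
      hypertension = rbinom(1, 1, c(recurrent = 0.40, indolent = 0.60,
                                    control = 0.29)[[g]]),
      diabetes = rbinom(1, 1, 0.19),
      iop = round(rnorm(1, 14.7, 3.1), 1),
      refractive_error_se = round(rnorm(1, -1.2, 2.0) +
                                    config$se_slope * delta, 2),
      bcva_logmar = round(max(0, rnorm(1, bcva_mean, bcva_sd)), 3),
      injections_per_year = if (is.na(inj)) NA_real_ else round(inj, 2),
      duration_months = duration,
      sfct_um = round(rnorm(1, 295, 90)),
      cmt_um = if (is_brvo) round(rnorm(1,
        if (g == "recurrent") 466 else 336, 155)) else NA_real_,
      stringsAsFactors = FALSE)
    eyes[[i]] <- list(eye_id = eye_id,
                      structural = pair$structural, octa = pair$octa,
                      faz = faz_mask(faz, provenance = "synthetic"),
                      truth = list(delta = delta,
                                   obstructive_quadrant = obstructive,
                                   vessel = vessel))
  }
  structure(list(eyes = eyes, records = do.call(rbind, records),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$records$group)
  cat(sprintf("<synthetic_cohort> %d eyes (%s), %d x %d px, seed %d\n",
              nrow(x$records),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$config$side_px, x$config$side_px, x$config$seed))
  invisible(x)
}

#' Record-level cohort simulation (no images)
#'
#' Tabular arm of the generator: draws the same per-eye covariates and
#' planted elevations as [generate_cohort()], but maps delta to a
#' reflectivity value through the configured linear approximation
#' (`record_model`: intercept + slope * delta + Gaussian noise) instead of
#' rendering and measuring images. Useful for statistical power and type-I
#' error studies where thousands of replicates are needed.
#'
#' @param config a [synthetic_config()].
#' @param seed optional integer seed applied locally (defaults to
#'   `config$seed`).
#' @return data frame shaped like `generate_cohort()$records` plus
#'   `corrected_reflectivity` and the truth column `delta`.
#' @export
simulate_records <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(groups)
  delta <- numeric(n)
  for (g in unique(groups)) {
    idx <- groups == g
    delta[idx] <- if (g == "control") 0 else
      draw_gamma(sum(idx), config$delta_mean[[g]], config$delta_sd[[g]])
  }
  rm_ <- config$record_model
  refl <- rm_$intercept + rm_$slope * delta + rnorm(n, 0, rm_$sd)
  inj <- ifelse(groups == "control", NA_real_,
                pmax(0, config$inj_intercept + config$inj_slope * delta +
                       rnorm(n, 0, config$inj_sd)))
  data.frame(
    eye_id = sprintf("eye%03d", seq_len(n)),
    group = groups,
    corrected_reflectivity = refl,
    delta = delta,
    age = round(rnorm(n, 64, 10), 1),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.37, 0.63)),
    iop = round(rnorm(n, 14.7, 3.1), 1),
    refractive_error_se = round(rnorm(n, -1.2, 2.0) +
                                  config$se_slope * delta, 2),
    injections_per_year = round(inj, 2),
    duration_months = ifelse(groups == "control", NA_real_,
                             round(rlnorm(n, 3.3, 0.75))),
    stringsAsFactors = FALSE)
}
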