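#' Construct a foveal avascular zone mask
#'
#' @param mask logical matrix aligned to the OCTA raster (`TRUE` inside the
#'   FAZ).
#' @param provenance `"supplied"` (drawn on a real scan) or `"synthetic"`.
#' @return object of class `faz_mask`.
#' @export
faz_mask <- function(mask, provenance = c("supplied", "synthetic")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(mask) || !is.logical(mask) || anyNA(mask)) {
    pv_stop("FAZ mask must be a logical matrix without NA",
            "perivasc_input_error")
  }
  if (sum(mask) == 0L) {
    pv_stop("FAZ mask is empty", "perivasc_input_error")
  }
  lab <- label_components(mask, connectivity = 8)
  ctr <- mask[max(1L, nrow(mask) %/% 2L), max(1L, ncol(mask) %/% 2L)]
  if (max(lab) > 1L || !isTRUE(ctr)) {
    pv_warn("FAZ mask is not a single central region",
            "perivasc_faz_warning")
  }
  structure(list(mask = mask, provenance = provenance), class = "faz_mask")
}

#' Vessel density with FAZ exclusion
#'
#' Binarizes the OCTA image at the arithmetic mean of the in-scope pixels
#' (the classic "Mean" auto-threshold) and returns the percentage of white
#' pixels. When a FAZ mask is supplied its pixels are excluded first, so the
#' avascular centre affects neither the threshold nor the denominator.
#'
#' @param octa angiography [enface_image()].
#' @param faz optional [faz_mask()] to exclude.
#' @param strict logical; threshold comparison `>` (default) or `>=`.
#' @return vessel density in percent (0-100).
#' @export
vessel_density <- function(octa, faz = NULL, strict = TRUE) {
  stopifnot(inherits(octa, "enface_image"))
  px <- octa$pixels
  if (!is.null(faz)) {
    stopifnot(inherits(faz, "faz_mask"))
    if (!all(dim(faz$mask) == dim(px))) {
      pv_stop("FAZ mask and OCTA image must have identical shape",
              "perivasc_geometry_error")
    }
    px <- px[!faz$mask]
  }
  if (length(px) == 0L) {
    pv_stop("FAZ mask covers the entire image; no pixels left for vessel density",
            "perivasc_input_error")
  }
  thr <- mean(px)
  white <- if (strict) px > thr else px >= thr
  if (max(px) == min(px)) {
    pv_warn("degenerate image: constant intensity outside FAZ, vessel density is 0",
            "perivasc_degenerate_warning")
  }
  100 * sum(white) / length(px)
}

# Crofton perimeter of a binary region, in pixel units. Counts 2 x 2
# neighbourhood configurations on the zero-padded mask and weights them by
# the expected number of intercepts with random lines in 4 directions
# (0, 45, 90, 135 degrees). Unlike a crack-length (edge-count) perimeter,
# this estimator is asymptotically unbiased for smooth shapes: a digitized
# disc comes out within ~1% of 2*pi*r.
perimeter_crofton_px <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  P <- matrix(0, n + 2L, m + 2L)
  P[2:(n + 1L), 2:(m + 1L)] <- mask * 1
  A <- P[2:(n + 2L), 2:(m + 2L)]
  B <- P[2:(n + 2L), 1:(m + 1L)]
  D <- P[1:(n + 1L), 2:(m + 2L)]
  E <- P[1:(n + 1L), 1:(m + 1L)]
  code <- A + 4 * B + 2 * D + 8 * E
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

#' FAZ morphometrics
#'
#' Computes the physical area, perimeter and circularity of the foveal
#' avascular zone from its binary mask. Area is the pixel count times the
#' squared pixel pitch; the perimeter uses a Crofton (intercept-count)
#' estimator, which is close to unbiased for smooth digitized outlines;
#' circularity is `4 * pi * area / perimeter^2`, 1 for a perfect disc and
#' smaller for elongated or irregular shapes. The device software whose FAZ
#' readings this mirrors does not document its perimeter estimator, so
#' absolute circularity values are comparable within, not across, estimators.
#'
#' @param faz a [faz_mask()] or logical matrix.
#' @param extent_mm physical side length of the raster in mm (default 3.0).
#' @param side_px raster side in pixels (defaults to `nrow` of the mask).
#' @return list with `area_mm2`, `perimeter_mm`, `circularity`.
#' @export
#' @examples
#' m <- outer(1:64, 1:64, function(i, j) (i - 32)^2 + (j - 32)^2 <= 20^2)
#' faz_metrics(m, extent_mm = 3, side_px = 320)
faz_metrics <- function(faz, extent_mm = 3.0, side_px = NULL) {
  mask <- if (inherits(faz, "faz_mask")) faz$mask else faz
  if (!is.matrix(mask) || !is.logical(mask)) {
    pv_stop("FAZ must be a logical matrix", "perivasc_input_error")
  }
  if (sum(mask) == 0L) pv_stop("FAZ mask is empty", "perivasc_input_error")
  if (is.null(side_px)) side_px <- nrow(mask)
  pitch_mm <- pixel_pitch_um(extent_mm, side_px) / 1000
  area_mm2 <- sum(mask) * pitch_mm^2
  perim_mm <- perimeter_crofton_px(mask) * pitch_mm
  list(area_mm2 = area_mm2,
       perimeter_mm = perim_mm,
       circularity = 4 * pi * area_mm2 / perim_mm^2)
}
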