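#' Mean structural reflectivity over a mask
#'
#' @param structural numeric matrix of structural OCT intensities.
#' @param hss an [filter_particles()] result (`hss_mask`) or a logical matrix
#'   of the same shape as `structural`.
#' @return scalar mean intensity over mask-true pixels.
#' @export
mean_reflectivity_on_mask <- function(structural, hss) {
  mask <- if (inherits(hss, "hss_mask")) hss$mask else hss
  if (!all(dim(structural) == dim(mask))) {
    pv_stop("structural raster and mask must have identical shape",
            "perivasc_geometry_error")
  }
  if (!any(mask)) {
    pv_stop("no HSS area: mask is empty", "perivasc_no_hss_error")
  }
  mean(structural[mask])
}

#' Corrected perivascular reflectivity of one quadrant
#'
#' The central quantification of the package. One quadrant of the OCTA image
#' is binarized at its mean + 2 SD, connected particles of at least
#' `min_particle_px` pixels are retained as the high-signal-strength (HSS)
#' area, the HSS mask is transferred onto the co-registered structural
#' en-face OCT image, and the corrected perivascular reflectivity is returned
#' as the ratio
#'
#'   mean structural reflectivity on the HSS area /
#'   overall structural en-face mean reflectivity.
#'
#' Dividing by the overall en-face mean makes the metric invariant to uniform
#' gain of the structural image, so values are comparable across scans with
#' different global brightness. The denominator is the mean over the full
#' structural image by default (one overall value per eye); set
#' `denominator_scope = "quadrant"` to normalize within the quadrant instead.
#' Likewise the threshold statistics come from the analyzed quadrant by
#' default (`threshold_scope = "image"` uses the whole OCTA frame).
#'
#' @param structural structural-modality [enface_image()].
#' @param octa angiography-modality [enface_image()] of the same shape.
#' @param quadrant quadrant label `"Q1".."Q4"` (see [quadrant_labels()]).
#' @param min_particle_px minimum HSS particle area in pixels (default 3).
#' @param connectivity particle connectivity, 8 (default) or 4.
#' @param sd_type SD convention for the threshold, `"sample"` or
#'   `"population"`.
#' @param strict logical; binarize with `>` (default) or `>=`.
#' @param threshold_scope `"quadrant"` (default) or `"image"`: region whose
#'   mean and SD define the binarization threshold.
#' @param denominator_scope `"image"` (default) or `"quadrant"`: region whose
#'   structural mean forms the denominator.
#' @return an object of class `reflectivity_result` with fields
#'   `corrected`, `mean_on_hss`, `overall_mean`, `threshold`,
#'   `hss_area_px`, `particle_count`, `quadrant`.
#' @export
#' @examples
#' set.seed(1)
#' octa <- matrix(runif(64, 0, 80), 8, 8)
#' octa[3:5, 2:6] <- 220
#' st <- matrix(120, 8, 8); st[3:5, 2:6] <- 180
#' corrected_reflectivity(enface_image(st, "structural"),
#'                        enface_image(octa, "angiography"), "Q1")
corrected_reflectivity <- function(structural, octa, quadrant,
                                   min_particle_px = 3L, connectivity = 8L,
                                   sd_type = c("sample", "population"),
                                   strict = TRUE,
                                   threshold_scope = c("quadrant", "image"),
                                   denominator_scope = c("image", "quadrant")) {
  sd_type <- match.arg(sd_type)
  threshold_scope <- match.arg(threshold_scope)
  denominator_scope <- match.arg(denominator_scope)
  stopifnot(inherits(structural, "enface_image"),
            inherits(octa, "enface_image"))
  if (structural$modality != "structural" || octa$modality != "angiography") {
    pv_stop("expected a structural image and an angiography image",
            "perivasc_input_error")
  }
  if (!all(dim(structural$pixels) == dim(octa$pixels))) {
    pv_stop("structural and OCTA images must have identical shape",
            "perivasc_geometry_error")
  }
  n <- nrow(octa$pixels)
  idx <- quadrant_indices(quadrant, n)
  q_octa <- octa$pixels[idx$rows, idx$cols, drop = FALSE]
  q_struct <- structural$pixels[idx$rows, idx$cols, drop = FALSE]

  thr_src <- if (threshold_scope == "quadrant") q_octa else octa$pixels
  thr <- compute_threshold(thr_src, sd_type = sd_type)
  hss <- filter_particles(binarize(q_octa, thr, strict = strict),
                          min_particle_px = min_particle_px,
                          connectivity = connectivity, threshold = thr)
  if (hss$hss_area_px == 0L) {
    pv_stop(sprintf("no HSS area in quadrant %s (threshold %.3f)",
                    quadrant, thr),
            "perivasc_no_hss_error")
  }
  mean_on_hss <- mean_reflectivity_on_mask(q_struct, hss)
  overall <- if (denominator_scope == "image") mean(structural$pixels)
             else mean(q_struct)
  if (overall == 0) {
    pv_stop("degenerate structural image: overall mean reflectivity is 0",
            "perivasc_degenerate_error")
  }
  structure(
    list(corrected = mean_on_hss / overall,
         mean_on_hss = mean_on_hss,
         overall_mean = overall,
         threshold = thr,
         hss_area_px = hss$hss_area_px,
         particle_count = hss$particle_count,
         quadrant = quadrant),
    class = "reflectivity_result"
  )
}

#' @export
print.reflectivity_result <- function(x, ...) {
  cat(sprintf("<reflectivity_result> quadrant %s\n", x$quadrant))
  cat(sprintf("  corrected reflectivity : %.4f\n", x$corrected))
  cat(sprintf("  mean on HSS            : %.3f\n", x$mean_on_hss))
  cat(sprintf("  overall en-face mean   : %.3f\n", x$overall_mean))
  cat(sprintf("  threshold (mean + 2SD) : %.3f\n", x$threshold))
  cat(sprintf("  HSS area / particles   : %d px / %d\n",
              x$hss_area_px, x$particle_count))
  invisible(x)
}

#' @export
as.data.frame.reflectivity_result <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  data.frame(quadrant = x$quadrant, corrected = x$corrected,
             mean_on_hss = x$mean_on_hss, overall_mean = x$overall_mean,
             threshold = x$threshold, hss_area_px = x$hss_area_px,
             particle_count = x$particle_count,
             stringsAsFactors = FALSE, row.names = row.names)
}
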