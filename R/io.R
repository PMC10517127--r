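#' Read an en-face image from TIFF or PNG
#'
#' Accepts single-channel 8-bit grayscale files. Pixel values are returned on
#' the 0-255 scale. The modality can be given explicitly or inferred from the
#' file naming convention `<eye_id>_struct.<ext>` / `<eye_id>_octa.<ext>`.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param modality `"structural"`, `"angiography"`, or `NULL` to infer from
#'   the filename.
#' @param extent_mm physical side length in mm (default 3.0).
#' @param quality image quality score to attach (default `NA`).
#' @return an [enface_image()].
#' @export
read_enface <- function(path, modality = NULL, extent_mm = 3.0,
                        quality = NA_real_) {
  if (!file.exists(path)) {
    pv_stop(sprintf("file not found: %s", path), "perivasc_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
                png = png::readPNG(path) * 255,
                pv_stop(sprintf("unsupported image format '.%s' (use TIFF or PNG)",
                                ext), "perivasc_io_error"))
  # PNG decoders return [0, 1]; snap 8-bit data back to exact integers
  if (is.numeric(raw) && length(dim(raw)) == 2L &&
      max(abs(raw - round(raw))) < 1e-6) {
    raw <- round(raw)
  }
  if (length(dim(raw)) == 3L) {
    pv_stop(sprintf(
      "%s has %d channels; expected single-channel 8-bit grayscale (convert with e.g. ImageJ: Image > Type > 8-bit)",
      basename(path), dim(raw)[3]), "perivasc_io_error")
  }
  if (max(raw) > 255 || min(raw) < 0) {
    pv_stop(sprintf("%s is not 8-bit (intensity range %.0f..%.0f); rescale to 0-255 first",
                    basename(path), min(raw), max(raw)),
            "perivasc_io_error")
  }
  if (is.null(modality)) {
    base <- tolower(basename(path))
    modality <- if (grepl("_struct", base)) "structural"
                else if (grepl("_octa", base)) "angiography"
                else pv_stop(sprintf(
                  "cannot infer modality from filename '%s' (expected *_struct.* or *_octa.*)",
                  basename(path)), "perivasc_io_error")
  }
  enface_image(raw, modality = modality, extent_mm = extent_mm,
               quality = quality)
}

#' Write an en-face image to TIFF or PNG
#'
#' Writes the raster as single-channel 8-bit grayscale; a read/write
#' round-trip is bit-identical for integer-valued rasters.
#'
#' @param image an [enface_image()] or a logical/numeric matrix (logical
#'   masks are written as 0/255).
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_enface <- function(image, path) {
  px <- if (inherits(image, "enface_image")) image$pixels else image
  if (is.logical(px)) px <- px * 255
  scaled <- round(px) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
         png = png::writePNG(scaled, path),
         pv_stop(sprintf("unsupported image format '.%s'", ext),
                 "perivasc_io_error"))
  invisible(path)
}

#' Analysis run configuration
#'
#' Collects every analysis option with its default set to the documented
#' reference choice: quadrant-scope mean + 2 sample-SD threshold, strict
#' binarization, particles of at least 3 pixels under 8-connectivity, image
#' quality gate at 65, full-image denominator, diagonally opposite
#' contralateral quadrant, ICC(2,.) agreement, Student post-hoc t-tests, and
#' a 0.2 univariate entry rule.
#'
#' @param min_particle_px minimum HSS particle area (default 3).
#' @param connectivity 8 or 4.
#' @param sd_type `"sample"` or `"population"`.
#' @param strict strict (`>`) binarization.
#' @param threshold_scope `"quadrant"` or `"image"`.
#' @param denominator_scope `"image"` or `"quadrant"`.
#' @param min_quality image-quality gate (default 65).
#' @param icc_model `"agreement"` or `"consistency"`.
#' @param posthoc `"student"` or `"welch"`.
#' @param entry_p multivariate entry threshold on univariate P (default 0.2).
#' @param split_months duration sub-analysis cut (default 36).
#' @param seed integer seed recorded for provenance.
#' @return object of class `perivasc_config` (a validated named list).
#' @export
run_config <- function(min_particle_px = 3L, connectivity = 8L,
                       sd_type = "sample", strict = TRUE,
                       threshold_scope = "quadrant",
                       denominator_scope = "image",
                       min_quality = 65, icc_model = "agreement",
                       posthoc = "student", entry_p = 0.2,
                       split_months = 36, seed = 1L) {
  cfg <- list(min_particle_px = as.integer(min_particle_px),
              connectivity = as.integer(connectivity),
              sd_type = match.arg(sd_type, c("sample", "population")),
              strict = isTRUE(strict),
              threshold_scope = match.arg(threshold_scope,
                                          c("quadrant", "image")),
              denominator_scope = match.arg(denominator_scope,
                                            c("image", "quadrant")),
              min_quality = min_quality,
              icc_model = match.arg(icc_model,
                                    c("agreement", "consistency")),
              posthoc = match.arg(posthoc, c("student", "welch")),
              entry_p = entry_p, split_months = split_months,
              seed = as.integer(seed))
  class(cfg) <- "perivasc_config"
  cfg
}

#' Analyze one eye
#'
#' Runs the full per-eye quantification: corrected perivascular reflectivity
#' in the measurement quadrant and in its contralateral quadrant, plus vessel
#' density and FAZ morphometrics when a FAZ mask is available.
#'
#' @param structural,octa the paired [enface_image()]s.
#' @param quadrant measurement (obstructive) quadrant label.
#' @param faz optional [faz_mask()].
#' @param config a [run_config()].
#' @return one-row data frame with the measured metrics.
#' @export
analyze_eye <- function(structural, octa, quadrant, faz = NULL,
                        config = run_config()) {
  main <- corrected_reflectivity(
    structural, octa, quadrant,
    min_particle_px = config$min_particle_px,
    connectivity = config$connectivity, sd_type = config$sd_type,
    strict = config$strict, threshold_scope = config$threshold_scope,
    denominator_scope = config$denominator_scope)
  contra <- corrected_reflectivity(
    structural, octa, contralateral_quadrant(quadrant),
    min_particle_px = config$min_particle_px,
    connectivity = config$connectivity, sd_type = config$sd_type,
    strict = config$strict, threshold_scope = config$threshold_scope,
    denominator_scope = config$denominator_scope)
  out <- data.frame(
    measure_quadrant = quadrant,
    corrected_reflectivity = main$corrected,
    contralateral_reflectivity = contra$corrected,
    mean_on_hss = main$mean_on_hss,
    overall_mean = main$overall_mean,
    binarization_threshold = main$threshold,
    hss_area_px = main$hss_area_px,
    particle_count = main$particle_count,
    vessel_density_pct = NA_real_, faz_area_mm2 = NA_real_,
    faz_perimeter_mm = NA_real_, faz_circularity = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(faz)) {
    out$vessel_density_pct <- vessel_density(octa, faz,
                                             strict = config$strict)
    fm <- faz_metrics(faz, extent_mm = octa$extent_mm,
                      side_px = nrow(octa$pixels))
    out$faz_area_mm2 <- fm$area_mm2
    out$faz_perimeter_mm <- fm$perimeter_mm
    out$faz_circularity <- fm$circularity
  }
  out
}

#' Analyze a synthetic cohort in memory
#'
#' Applies [analyze_eye()] to every eye of a [generate_cohort()] result and
#' joins the measurements onto the covariate records. Eyes failing the image
#' quality gate are excluded and listed in the `exclusions` attribute. The
#' analysis consumes only the images and covariates, never the retained
#' ground truth.
#'
#' @param cohort a `synthetic_cohort`.
#' @param config a [run_config()].
#' @param faz logical, include vessel density / FAZ metrics (default TRUE).
#' @return data frame of per-eye records with measured metrics; excluded eyes
#'   are in `attr(, "exclusions")`.
#' @export
analyze_cohort <- function(cohort, config = run_config(), faz = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rec <- cohort$records
  rows <- vector("list", nrow(rec))
  excl <- list()
  for (i in seq_len(nrow(rec))) {
    eye <- cohort$eyes[[i]]
    if (!quality_gate(eye$structural, config$min_quality)) {
      excl[[length(excl) + 1L]] <- data.frame(
        eye_id = eye$eye_id,
        reason = sprintf("image quality %.1f below minimum %s",
                         eye$structural$quality, config$min_quality),
        stringsAsFactors = FALSE)
      next
    }
    m <- analyze_eye(eye$structural, eye$octa, rec$measure_quadrant[i],
                     faz = if (faz) eye$faz else NULL, config = config)
    rows[[i]] <- cbind(rec[i, setdiff(names(rec), "measure_quadrant"),
                           drop = FALSE], m)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl)
                             else data.frame(eye_id = character(),
                                             reason = character())
  out
}

write_provenance <- function(dir, name, config, extra = list()) {
  info <- c(list(package = "perivasc",
                 version = as.character(packageVersion("perivasc")),
                 config = unclass(config)), extra)
  jsonlite::write_json(info, file.path(dir, paste0(name, ".provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Write a synthetic cohort to disk
#'
#' Materializes a cohort as the on-disk layout the `analyze` workflow reads:
#' per-eye `<eye_id>_struct.tif` / `<eye_id>_octa.tif` pairs, a shared
#' `<eye_id>_faz.png` mask, `metadata.csv` with the covariate records, and
#' `truth.json` with the retained ground truth.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (eye in cohort$eyes) {
    write_enface(eye$structural, file.path(dir, paste0(eye$eye_id,
                                                       "_struct.tif")))
    write_enface(eye$octa, file.path(dir, paste0(eye$eye_id, "_octa.tif")))
    write_enface(eye$faz$mask, file.path(dir, paste0(eye$eye_id,
                                                     "_faz.png")))
  }
  write.csv(cohort$records, file.path(dir, "metadata.csv"),
            row.names = FALSE)
  truth <- lapply(cohort$eyes, function(e) {
    list(eye_id = e$eye_id, delta = e$truth$delta,
         obstructive_quadrant = e$truth$obstructive_quadrant)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(dir, "simulate", cohort$config,
                   list(n_eyes = nrow(cohort$records)))
  invisible(dir)
}

#' Run the per-eye analysis over an input directory
#'
#' Reads paired `<eye_id>_struct.tif` / `<eye_id>_octa.tif` images (plus
#' optional `<eye_id>_faz.png` masks) and a `metadata.csv` with at least
#' `eye_id`, `group`, `measure_quadrant` and `quality` columns, applies the
#' quality gate, measures each passing eye in its measurement and
#' contralateral quadrants, and writes `results.csv`, `exclusions.csv` and a
#' provenance JSON to the output directory. Rows are ordered by `eye_id`, so
#' reruns on the same inputs are byte-identical.
#'
#' @param input_dir directory with images and `metadata.csv`.
#' @param output_dir directory for results (created if missing).
#' @param config a [run_config()].
#' @return the results data frame, invisibly.
#' @export
run_analyze <- function(input_dir, output_dir, config = run_config()) {
  meta_path <- file.path(input_dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    pv_stop(sprintf("metadata.csv not found in %s", input_dir),
            "perivasc_io_error")
  }
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("eye_id", "group", "measure_quadrant", "quality")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    pv_stop(paste("metadata.csv lacks columns:", paste(miss, collapse = ", ")),
            "perivasc_io_error")
  }
  meta <- meta[order(meta$eye_id), , drop = FALSE]
  rows <- list(); excl <- list()
  log_line <- function(...) message(sprintf(...))
  for (i in seq_len(nrow(meta))) {
    id <- meta$eye_id[i]
    sp <- file.path(input_dir, paste0(id, "_struct.tif"))
    op <- file.path(input_dir, paste0(id, "_octa.tif"))
    fp <- file.path(input_dir, paste0(id, "_faz.png"))
    if (!file.exists(sp) || !file.exists(op)) {
      excl[[length(excl) + 1L]] <- data.frame(
        eye_id = id, reason = "missing image pair member",
        stringsAsFactors = FALSE)
      log_line("[analyze] %s: skipped (missing image pair member)", id)
      next
    }
    st <- read_enface(sp, quality = meta$quality[i])
    oc <- read_enface(op, quality = meta$quality[i])
    if (!quality_gate(st, config$min_quality)) {
      excl[[length(excl) + 1L]] <- data.frame(
        eye_id = id,
        reason = sprintf("image quality %.1f below minimum %s",
                         meta$quality[i], config$min_quality),
        stringsAsFactors = FALSE)
      log_line("[analyze] %s: excluded (quality %.1f < %s)", id,
               meta$quality[i], config$min_quality)
      next
    }
    faz <- if (file.exists(fp)) {
      faz_mask(png::readPNG(fp) > 0.5, provenance = "supplied")
    } else NULL
    m <- analyze_eye(st, oc, meta$measure_quadrant[i], faz = faz,
                     config = config)
    rows[[length(rows) + 1L]] <- cbind(
      meta[i, setdiff(names(meta), "measure_quadrant"), drop = FALSE], m)
    log_line("[analyze] %s: quadrant %s corrected %.4f", id,
             meta$measure_quadrant[i], m$corrected_reflectivity)
  }
  if (!length(rows)) {
    pv_stop("no eyes passed the gates; empty cohort", "perivasc_io_error")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(out, file.path(output_dir, "results.csv"), row.names = FALSE)
  excl_df <- if (length(excl)) do.call(rbind, excl)
             else data.frame(eye_id = character(), reason = character())
  write.csv(excl_df, file.path(output_dir, "exclusions.csv"),
            row.names = FALSE)
  write_provenance(output_dir, "analyze", config,
                   list(n_analyzed = nrow(out), n_excluded = nrow(excl_df)))
  invisible(out)
}

group_summary_table <- function(data, metrics, config) {
  out <- list()
  for (m in metrics) {
    ok <- tapply(!is.na(data[[m]]), data$group, sum)
    usable <- names(ok)[!is.na(ok) & ok >= 2]
    row <- data.frame(metric = m, stringsAsFactors = FALSE)
    for (g in c("recurrent", "indolent", "control")) {
      v <- data[[m]][data$group == g]
      row[[paste0(g, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(g, "_sd")]] <- sd(v, na.rm = TRUE)
    }
    row$p_value <- if (length(usable) >= 2) {
      gc <- group_comparison(data[data$group %in% usable, ], m,
                             posthoc = config$posthoc)
      gc$anova$p
    } else NA_real_
    out[[m]] <- row
  }
  do.call(rbind, out)
}

#' Build the cohort report tables
#'
#' Produces the three report tables of the analysis chain from a per-eye
#' results table: the group summary (per-group mean and SD with the omnibus
#' ANOVA P per metric), the univariate/multivariate standardized-beta
#' regression table for the BRVO eyes, and the disease-duration sub-analysis.
#' When `output_dir` is given the tables are written as
#' `table1_group_summary.csv`, `table2_regression.csv`,
#' `table3_duration.csv` plus a JSON run summary.
#'
#' @param results per-eye results data frame (from [run_analyze()] or
#'   [analyze_cohort()]).
#' @param config a [run_config()].
#' @param output_dir optional output directory.
#' @return list with `group_summary`, `regression`, `duration`,
#'   `paired_quadrants`.
#' @export
run_report <- function(results, config = run_config(), output_dir = NULL) {
  metrics <- intersect(
    c("corrected_reflectivity", "mean_on_hss", "overall_mean",
      "binarization_threshold", "hss_area_px", "particle_count",
      "vessel_density_pct", "faz_area_mm2", "faz_perimeter_mm",
      "faz_circularity", "age", "iop", "refractive_error_se",
      "bcva_logmar", "injections_per_year", "duration_months",
      "sfct_um", "cmt_um"),
    names(results))
  n_groups <- length(unique(results$group))
  grp <- if (n_groups >= 2) {
    group_summary_table(results, metrics, config)
  } else {
    message("[report] single-group input: group comparison table skipped")
    NULL
  }
  brvo <- results[results$group != "control", , drop = FALSE]
  preds <- intersect(
    c("sex", "age", "laterality", "hypertension", "diabetes", "iop",
      "refractive_error_se", "bcva_logmar", "binarization_threshold",
      "injections_per_year", "duration_months", "sfct_um", "cmt_um",
      "vessel_density_pct", "faz_area_mm2", "faz_perimeter_mm",
      "faz_circularity"),
    names(brvo))
  reg <- regression_suite(brvo, outcome = "corrected_reflectivity",
                          predictors = preds, entry_p = config$entry_p)
  dur <- if ("duration_months" %in% names(brvo) &&
             any(!is.na(brvo$duration_months))) {
    tryCatch(duration_subanalysis(brvo, split_months = config$split_months),
             perivasc_error = function(e) {
               message("[report] duration sub-analysis skipped: ",
                       conditionMessage(e))
               NULL
             })
  } else NULL
  paired <- if ("contralateral_reflectivity" %in% names(brvo) &&
                nrow(brvo) >= 2) {
    paired_quadrant_test(brvo$corrected_reflectivity,
                         brvo$contralateral_reflectivity)
  } else NULL

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(grp)) {
      write.csv(grp, file.path(output_dir, "table1_group_summary.csv"),
                row.names = FALSE)
    }
    reg_tab <- merge(reg$univariate, reg$multivariate, by = "predictor",
                     all.x = TRUE, suffixes = c("_univariate",
                                                "_multivariate"))
    write.csv(reg_tab[match(reg$univariate$predictor, reg_tab$predictor), ],
              file.path(output_dir, "table2_regression.csv"),
              row.names = FALSE)
    if (!is.null(dur)) {
      write.csv(merge(dur$strata, dur$regressions, by = "stratum"),
                file.path(output_dir, "table3_duration.csv"),
                row.names = FALSE)
    }
    summary_json <- list(
      n_eyes = nrow(results),
      groups = as.list(table(results$group)),
      paired_quadrant_p = if (!is.null(paired)) paired$p else NULL,
      multivariate_predictors = reg$entered)
    jsonlite::write_json(summary_json,
                         file.path(output_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_provenance(output_dir, "report", config)
  }
  list(group_summary = grp, regression = reg, duration = dur,
       paired_quadrants = paired)
}
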