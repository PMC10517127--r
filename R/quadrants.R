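#' Quadrant labels
#'
#' The en-face field is divided into four equal corner blocks, labelled in
#' row-major order with the origin at the top-left of the scan:
#' `Q1` top-left, `Q2` top-right, `Q3` bottom-left, `Q4` bottom-right.
#'
#' @return character vector `c("Q1", "Q2", "Q3", "Q4")`.
#' @export
quadrant_labels <- function() c("Q1", "Q2", "Q3", "Q4")

# Row/column index ranges of one quadrant of an n x n raster.
quadrant_indices <- function(label, n) {
  h <- n %/% 2L
  switch(label,
         Q1 = list(rows = 1:h,       cols = 1:h),
         Q2 = list(rows = 1:h,       cols = (h + 1L):n),
         Q3 = list(rows = (h + 1L):n, cols = 1:h),
         Q4 = list(rows = (h + 1L):n, cols = (h + 1L):n),
         pv_stop(sprintf("unknown quadrant label '%s'", label),
                 "perivasc_input_error"))
}

#' Split an en-face raster into four quadrants
#'
#' @param image an [enface_image()] or a plain numeric matrix with even side
#'   length.
#' @return named list of four quadrant sub-matrices (`Q1`..`Q4`).
#'   Reassembling them with [assemble_quadrants()] reproduces the input
#'   exactly.
#' @export
#' @examples
#' q <- split_quadrants(matrix(1:16, 4, 4, byrow = TRUE))
#' q$Q1
split_quadrants <- function(image) {
  px <- if (inherits(image, "enface_image")) image$pixels else image
  n <- nrow(px)
  if (n != ncol(px)) pv_stop("image must be square", "perivasc_geometry_error")
  if (n %% 2L != 0L) {
    pv_stop("image side length must be even to split into quadrants",
            "perivasc_geometry_error")
  }
  out <- lapply(quadrant_labels(), function(q) {
    idx <- quadrant_indices(q, n)
    px[idx$rows, idx$cols, drop = FALSE]
  })
  names(out) <- quadrant_labels()
  out
}

#' Reassemble four quadrants into one raster
#'
#' Inverse of [split_quadrants()].
#'
#' @param quadrants named list with elements `Q1`..`Q4`.
#' @return the reassembled matrix.
#' @export
assemble_quadrants <- function(quadrants) {
  stopifnot(all(quadrant_labels() %in% names(quadrants)))
  rbind(cbind(quadrants$Q1, quadrants$Q2),
        cbind(quadrants$Q3, quadrants$Q4))
}

#' Contralateral quadrant
#'
#' The reference quadrant compared against the obstructive quadrant. By
#' default it is the diagonally opposite corner (Q1-Q4, Q2-Q3), which is the
#' quadrant geometrically farthest from the occlusion.
#'
#' @param quadrant one of `"Q1".."Q4"`.
#' @return the opposite quadrant label.
#' @export
contralateral_quadrant <- function(quadrant) {
  map <- c(Q1 = "Q4", Q2 = "Q3", Q3 = "Q2", Q4 = "Q1")
  if (!quadrant %in% names(map)) {
    pv_stop(sprintf("unknown quadrant label '%s'", quadrant),
            "perivasc_input_error")
  }
  unname(map[quadrant])
}
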