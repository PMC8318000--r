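#' Segment the cell footprint from F-actin staining
#'
#' The actin channel defines the cell edge: Otsu thresholding, retention of
#' the largest connected component, and filling of interior holes (the
#' actin-depleted center of a spread cell is part of the footprint).
#'
#' @param actin_img a [calibrated_image] (or matrix) of the F-actin channel.
#' @param pixel_size_um pixel size; taken from the image when calibrated.
#' @return An object of class `cell_mask`: list with `mask` (logical
#'   matrix), `centroid` (x, y), `n_px`, `area_um2` and `found`. A blank
#'   image yields `found = FALSE` with an empty mask.
#' @export
segment_cell_footprint <- function(actin_img, pixel_size_um = NULL) {
    ps <- pixel_size_um %||% attr(actin_img, "pixel_size_um")
    if (is.null(ps)) stop("pixel_size_um required (image is uncalibrated)")
    m <- as_intensity_matrix(actin_img)
    bw <- suppressWarnings(otsu_binarize(m))
    empty <- structure(list(mask = matrix(FALSE, nrow(m), ncol(m)),
                            centroid = c(NA_real_, NA_real_), n_px = 0L,
                            area_um2 = NA_real_, found = FALSE,
                            pixel_size_um = ps), class = "cell_mask")
    if (!any(bw)) return(empty)
    labm <- .label_components_cpp(unclass(bw), 8L)
    counts <- tabulate(labm[labm > 0L])
    keep <- which.max(counts)
    mask <- .fill_holes_cpp(labm == keep)
    ij <- which(mask, arr.ind = TRUE)
    structure(list(mask = mask,
                   centroid = c(mean(ij[, 2]), mean(ij[, 1])),
                   n_px = sum(mask), area_um2 = sum(mask) * ps^2,
                   found = TRUE, pixel_size_um = ps),
              class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
    if (!x$found) cat("cell_mask: no cell found\n")
    else cat(sprintf("cell_mask: %d px, %.2f um^2, centroid (%.1f, %.1f)\n",
                     x$n_px, x$area_um2, x$centroid[1], x$centroid[2]))
    invisible(x)
}

#' Cell spreading area in square micrometres
#'
#' @param mask a `cell_mask` from [segment_cell_footprint()], or a logical
#'   matrix.
#' @param pixel_size_um pixel size; required when `mask` is a plain matrix.
#' @return Area = pixel count x pixel_size_um^2, or `NA` with a warning for
#'   an empty mask (not evaluable).
#' @export
cell_area <- function(mask, pixel_size_um = NULL) {
    if (inherits(mask, "cell_mask")) {
        ps <- pixel_size_um %||% mask$pixel_size_um
        n <- mask$n_px
    } else {
        ps <- pixel_size_um
        n <- sum(mask != 0)
    }
    if (is.null(ps)) stop("pixel_size_um required")
    if (n == 0L) {
        warning("empty mask: area not evaluable")
        return(NA_real_)
    }
    n * ps^2
}
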