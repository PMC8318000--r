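#' Calibrated fluorescence image
#'
#' A 2D intensity matrix carrying its physical pixel size and a channel
#' label. All quantification operations in the package consume and return
#' this class; plain matrices are accepted by most functions and are treated
#' as uncalibrated (pixel size must then be supplied explicitly).
#'
#' @param intensities numeric matrix of nonnegative, finite intensities
#'   (rows = y, columns = x).
#' @param pixel_size_um physical size of one pixel in micrometres (> 0).
#' @param channel optional channel label (e.g. `"Ag"`, `"pCD79"`, `"actin"`).
#' @return An object of class `calibrated_image`: the matrix with
#'   `pixel_size_um` and `channel` attributes.
#' @export
calibrated_image <- function(intensities, pixel_size_um, channel = NA_character_) {
    if (!is.matrix(intensities) || !is.numeric(intensities))
        stop("'intensities' must be a numeric matrix")
    if (any(!is.finite(intensities)))
        stop("'intensities' must be finite")
    if (any(intensities < 0))
        stop("'intensities' must be nonnegative")
    stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
    structure(intensities,
              pixel_size_um = pixel_size_um,
              channel = channel,
              class = c("calibrated_image", "matrix", "array"))
}

#' @export
print.calibrated_image <- function(x, ...) {
    cat(sprintf("calibrated_image: %d x %d px, %.4g um/px, channel '%s'\n",
                nrow(x), ncol(x), attr(x, "pixel_size_um"),
                attr(x, "channel")))
    cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
    invisible(x)
}

#' Pixel size of a calibrated image
#' @param x a `calibrated_image`, `multichannel_frame` or `time_lapse`.
#' @return pixel size in micrometres.
#' @export
pixel_size <- function(x) {
    ps <- attr(x, "pixel_size_um")
    if (is.null(ps) && inherits(x, "multichannel_frame"))
        ps <- attr(x$channels[[1]], "pixel_size_um")
    ps
}

as_intensity_matrix <- function(img) {
    m <- unclass(img)
    attributes(m) <- list(dim = dim(m))
    m
}

#' Multi-channel microscopy frame
#'
#' A named set of [calibrated_image]s sharing shape and calibration, with an
#' optional binary cell ROI mask restricting per-cell quantification.
#'
#' @param channels named list of `calibrated_image`s (same shape, same pixel
#'   size).
#' @param roi_mask optional logical matrix (same shape) marking the cell.
#' @return An object of class `multichannel_frame`.
#' @export
multichannel_frame <- function(channels, roi_mask = NULL) {
    if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
        stop("'channels' must be a nonempty named list of calibrated_image")
    d <- dim(channels[[1]])
    ps <- attr(channels[[1]], "pixel_size_um")
    for (ch in channels) {
        if (!inherits(ch, "calibrated_image"))
            stop("every channel must be a calibrated_image")
        if (!identical(dim(ch), d))
            stop("all channels must share the same shape")
        if (!isTRUE(all.equal(attr(ch, "pixel_size_um"), ps)))
            stop("all channels must share the same pixel size")
    }
    if (!is.null(roi_mask)) {
        if (!identical(dim(roi_mask), d)) stop("roi_mask shape mismatch")
        roi_mask <- roi_mask != 0
    }
    structure(list(channels = channels, roi_mask = roi_mask),
              class = "multichannel_frame")
}

#' @export
print.multichannel_frame <- function(x, ...) {
    cat(sprintf("multichannel_frame: %d x %d px, %.4g um/px, channels: %s\n",
                nrow(x$channels[[1]]), ncol(x$channels[[1]]),
                pixel_size(x), paste(names(x$channels), collapse = ", ")))
    invisible(x)
}

#' Time-lapse image stack
#'
#' An ordered list of frames sharing calibration, with a uniform frame
#' interval. Live-cell interface movies are acquired at 2-s intervals by
#' default.
#'
#' @param frames list of numeric matrices (or `calibrated_image`s) of equal
#'   shape.
#' @param pixel_size_um pixel size in micrometres.
#' @param frame_interval_s seconds between consecutive frames (> 0),
#'   default 2.
#' @return An object of class `time_lapse`.
#' @export
time_lapse <- function(frames, pixel_size_um, frame_interval_s = 2) {
    if (!is.list(frames) || length(frames) < 2L)
        stop("'frames' must be a list of at least 2 frames")
    stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
    if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
        stop("'frame_interval_s' must be > 0")
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
        stop("all frames must share the same shape")
    structure(list(frames = lapply(frames, as_intensity_matrix)),
              pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s,
              class = "time_lapse")
}

#' @export
print.time_lapse <- function(x, ...) {
    cat(sprintf("time_lapse: %d frames, %d x %d px, %.4g um/px, dt = %g s\n",
                length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
                pixel_size(x), attr(x, "frame_interval_s")))
    invisible(x)
}
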