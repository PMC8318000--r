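## TIFF I/O with a JSON calibration sidecar.
##
## Multi-page TIFF holds one page per channel (frames) or per time point
## (movies). Intensities are stored as 16-bit after scaling by the recorded
## intensity_scale, which the sidecar preserves together with pixel size,
## frame interval and channel names.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multi-channel frame as TIFF plus calibration sidecar
#'
#' @param frame a [multichannel_frame].
#' @param path output TIFF path; calibration metadata is written to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(frame, path) {
    stopifnot(inherits(frame, "multichannel_frame"))
    mats <- lapply(frame$channels, as_intensity_matrix)
    mx <- max(1e-12, vapply(mats, max, numeric(1)))
    tiff::writeTIFF(lapply(mats, function(m) m / mx), path,
                    bits.per.sample = 16L)
    meta <- list(kind = "multichannel_frame",
                 pixel_size_um = pixel_size(frame),
                 channels = names(frame$channels),
                 intensity_scale = mx)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read a multi-channel frame written by [write_frame_tiff()]
#'
#' @param path TIFF path with an accompanying `<path>.json` sidecar.
#' @return A [multichannel_frame].
#' @export
read_frame_tiff <- function(path) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    chans <- lapply(pages, function(p)
        calibrated_image(p * meta$intensity_scale, meta$pixel_size_um))
    names(chans) <- meta$channels
    for (i in seq_along(chans)) attr(chans[[i]], "channel") <- meta$channels[i]
    multichannel_frame(chans)
}

#' Write a time-lapse movie as multi-page TIFF plus calibration sidecar
#'
#' @param movie a [time_lapse].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
    stopifnot(inherits(movie, "time_lapse"))
    mx <- max(1e-12, vapply(movie$frames, max, numeric(1)))
    tiff::writeTIFF(lapply(movie$frames, function(m) m / mx), path,
                    bits.per.sample = 16L)
    meta <- list(kind = "time_lapse",
                 pixel_size_um = pixel_size(movie),
                 frame_interval_s = attr(movie, "frame_interval_s"),
                 n_frames = length(movie$frames),
                 intensity_scale = mx)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read a time-lapse movie written by [write_movie_tiff()]
#'
#' @param path TIFF path with an accompanying `<path>.json` sidecar.
#' @return A [time_lapse].
#' @export
read_movie_tiff <- function(path) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    time_lapse(lapply(pages, function(p) p * meta$intensity_scale),
               pixel_size_um = meta$pixel_size_um,
               frame_interval_s = meta$frame_interval_s)
}
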