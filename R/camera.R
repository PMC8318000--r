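#' Camera / acquisition model for synthetic microscopy
#'
#' Parameterizes the optical blur and noise applied to a noiseless rendered
#' scene: Gaussian PSF blur, Poisson shot noise scaled by the photon gain,
#' additive Gaussian read noise, clipping at zero, and a constant camera
#' baseline offset.
#'
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels (>= 0;
#'   0 disables blur).
#' @param photon_gain expected photons per intensity unit (>= 0). Shot noise
#'   variance in intensity units is mean / `photon_gain`; a gain of 0 (or
#'   `Inf`) disables shot noise entirely.
#' @param read_noise_sd additive Gaussian read-noise SD in intensity units
#'   (>= 0).
#' @param offset camera baseline added after clipping (>= 0).
#' @return An object of class `camera_model`.
#' @seealso [apply_camera_model()]
#' @export
camera_model <- function(psf_sigma_px = 1, photon_gain = 1,
                         read_noise_sd = 2, offset = 100) {
    stopifnot_scalar_pos(psf_sigma_px, "psf_sigma_px", strict = FALSE)
    if (!is.numeric(photon_gain) || length(photon_gain) != 1L || photon_gain < 0)
        stop("'photon_gain' must be a single nonnegative number")
    stopifnot_scalar_pos(read_noise_sd, "read_noise_sd", strict = FALSE)
    stopifnot_scalar_pos(offset, "offset", strict = FALSE)
    structure(list(psf_sigma_px = psf_sigma_px, photon_gain = photon_gain,
                   read_noise_sd = read_noise_sd, offset = offset),
              class = "camera_model")
}

#' Noiseless identity camera
#'
#' Convenience constructor for the noiseless limit: no blur, no shot noise,
#' no read noise, zero offset. `apply_camera_model` with this camera is the
#' identity on nonnegative images.
#'
#' @return A `camera_model`.
#' @export
noiseless_camera <- function() {
    camera_model(psf_sigma_px = 0, photon_gain = 0, read_noise_sd = 0,
                 offset = 0)
}

#' Apply the camera model to a clean rendered image
#'
#' The acquisition chain is: Gaussian blur by `psf_sigma_px`; Poisson draw of
#' `image * photon_gain` photons, scaled back to intensity units; additive
#' Gaussian read noise; clipping at 0; plus the baseline offset. Averaging
#' many noisy renders of the same scene converges to the blurred clean image
#' plus the offset.
#'
#' @param clean_image nonnegative numeric matrix (or [calibrated_image]).
#' @param camera a [camera_model].
#' @param seed integer seed; the global RNG state is left untouched.
#' @return A matrix of the same shape (a `calibrated_image` if the input was
#'   one), nonnegative.
#' @export
apply_camera_model <- function(clean_image, camera, seed) {
    stopifnot(inherits(camera, "camera_model"))
    m <- as_intensity_matrix(clean_image)
    if (any(!is.finite(m)) || any(m < 0))
        stop("'clean_image' must be finite and nonnegative")
    if (camera$psf_sigma_px > 0)
        m <- .gauss_blur_cpp(m, camera$psf_sigma_px)
    with_seed(seed, {
        g <- camera$photon_gain
        if (g > 0 && is.finite(g)) {
            v <- rpois(length(m), lambda = as.vector(m) * g) / g
            m <- matrix(v, nrow(m), ncol(m))
        }
        if (camera$read_noise_sd > 0)
            m <- m + matrix(rnorm(length(m), sd = camera$read_noise_sd),
                            nrow(m), ncol(m))
    })
    m <- pmax(m, 0) + camera$offset
    if (inherits(clean_image, "calibrated_image"))
        m <- calibrated_image(m, attr(clean_image, "pixel_size_um"),
                              attr(clean_image, "channel"))
    m
}
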