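## Synthetic fluorescence-microscopy generator.
##
## Three scene types mirror the three imaging experiments the quantification
## stages serve: (1) a radially spreading cell with a bright peripheral
## F-actin ring and a GMFg distribution peaking interior to it; (2) a B
## cell-APC interface frame containing antigen microclusters with designed
## per-cluster intensity fractions and a designed pCD79:Ag intensity ratio;
## (3) a TIRF-like time-lapse whose texture translates centripetally at a
## known speed. All scenes are rendered noiselessly from analytic shapes
## (isotropic Gaussians and smooth radial profiles), then passed through the
## camera model, so every ground-truth quantity is known exactly.

#' Ground truth for a synthetic spreading B cell
#'
#' Describes a radially spread cell: a bright peripheral actin ring at
#' `actin_ring_radius_px` and a GMFg channel whose radial peak sits interior
#' to the ring (`gmf_peak_radius_px < actin_ring_radius_px`), matching the
#' observed localization of GMFg abutting the inner face of the peripheral
#' actin ring.
#'
#' @param center numeric length-2 (x, y) pixel coordinates of the cell
#'   center.
#' @param cell_radius_px footprint radius in pixels.
#' @param actin_ring_radius_px radial location of the actin intensity peak
#'   (<= `cell_radius_px`).
#' @param actin_ring_width_px Gaussian radial width of the actin ring.
#' @param gmf_peak_radius_px radial location of the GMFg peak
#'   (0 < gmf < actin ring radius).
#' @param gmf_width_px Gaussian radial width of the GMFg annulus.
#' @param amplitudes named numeric: peak intensities for the `actin` and
#'   `GMFg` channels.
#' @param pixel_size_um pixel size in micrometres.
#' @return An object of class `spreading_cell_truth`.
#' @export
spreading_cell_truth <- function(center = c(64, 64), cell_radius_px = 50,
                                 actin_ring_radius_px = 40,
                                 actin_ring_width_px = 3,
                                 gmf_peak_radius_px = 30,
                                 gmf_width_px = 5,
                                 amplitudes = c(actin = 500, GMFg = 400),
                                 pixel_size_um = 0.1) {
    if (!(gmf_peak_radius_px > 0 &&
          gmf_peak_radius_px < actin_ring_radius_px &&
          actin_ring_radius_px <= cell_radius_px))
        stop("require 0 < gmf_peak_radius_px < actin_ring_radius_px <= cell_radius_px")
    stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
    structure(list(center = center, cell_radius_px = cell_radius_px,
                   actin_ring_radius_px = actin_ring_radius_px,
                   actin_ring_width_px = actin_ring_width_px,
                   gmf_peak_radius_px = gmf_peak_radius_px,
                   gmf_width_px = gmf_width_px,
                   amplitudes = amplitudes,
                   pixel_size_um = pixel_size_um),
              class = "spreading_cell_truth")
}

radius_map <- function(image_size, center) {
    nr <- image_size[1]; nc <- image_size[2]
    x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    y <- matrix(seq_len(nr), nr, nc)
    sqrt((x - center[1])^2 + (y - center[2])^2)
}

#' Render a synthetic spreading cell
#'
#' The actin channel is a dim cell body plus an annular Gaussian intensity
#' peak at the designed ring radius; the GMFg channel is a brighter cell body
#' plus an annular peak interior to the actin ring. Both are attenuated by a
#' soft cell-edge envelope and passed through the camera model.
#'
#' @param truth a [spreading_cell_truth].
#' @param camera a [camera_model].
#' @param image_size integer (rows, cols) of the rendered image.
#' @param seed integer seed for the noise draws.
#' @return A list with elements `frame` (a [multichannel_frame] with channels
#'   `actin` and `GMFg`, `roi_mask` set to the true footprint) and `truth`
#'   (unchanged).
#' @export
simulate_spreading_cell <- function(truth, camera, image_size = c(128, 128),
                                    seed = 1) {
    stopifnot(inherits(truth, "spreading_cell_truth"))
    cx <- truth$center[1]; cy <- truth$center[2]; R <- truth$cell_radius_px
    if (cx - R < 1 || cx + R > image_size[2] ||
        cy - R < 1 || cy + R > image_size[1])
        stop("cell footprint (center +/- cell_radius_px) exceeds image bounds")
    r <- radius_map(image_size, truth$center)
    edge <- 1 / (1 + exp((r - R) / 1.5))          # soft footprint envelope
    actin <- truth$amplitudes[["actin"]] *
        (0.15 + exp(-(r - truth$actin_ring_radius_px)^2 /
                        (2 * truth$actin_ring_width_px^2))) * edge
    gmf <- truth$amplitudes[["GMFg"]] *
        (0.30 + exp(-(r - truth$gmf_peak_radius_px)^2 /
                        (2 * truth$gmf_width_px^2))) * edge
    chans <- list(
        actin = calibrated_image(
            pmax(apply_camera_model(actin, camera, derive_seed(seed, 1)), 0),
            truth$pixel_size_um, "actin"),
        GMFg = calibrated_image(
            pmax(apply_camera_model(gmf, camera, derive_seed(seed, 2)), 0),
            truth$pixel_size_um, "GMFg"))
    list(frame = multichannel_frame(chans, roi_mask = r <= R), truth = truth)
}

#' Ground truth for a synthetic B cell-APC synapse frame
#'
#' Designed antigen microclusters with known centers, widths and integrated
#' intensities. `designed_fractions` are the per-cluster shares of total Ag
#' intensity; `csmac_truth` applies the cSMAC rule (> 90% of Ag intensity in
#' at most two clusters) to those designed fractions. The pCD79 channel is a
#' scaled copy of the clean Ag channel with ratio `pcd79_per_ag`, the
#' designed per-cell signal-amplification ratio.
#'
#' @param centers n x 2 matrix of (x, y) cluster centers in pixels.
#' @param ag_intensities integrated Ag intensity per cluster (> 0).
#' @param sigma_px Gaussian radius of each cluster (scalar or length n).
#' @param pcd79_per_ag designed ratio of pCD79 to Ag intensity (>= 0).
#' @param pixel_size_um pixel size in micrometres.
#' @return An object of class `synapse_truth` with fields
#'   `designed_fractions`, `csmac_truth` and an `overlapping` flag (TRUE when
#'   two clusters sit closer than 3 summed sigmas; such frames are valid but
#'   their clusters may merge at segmentation).
#' @export
synapse_truth <- function(centers, ag_intensities, sigma_px = 2,
                          pcd79_per_ag = 1, pixel_size_um = 0.1) {
    centers <- matrix(as.numeric(centers), ncol = 2)
    n <- nrow(centers)
    if (length(ag_intensities) != n) stop("one intensity per cluster required")
    if (n > 0 && any(ag_intensities <= 0)) stop("intensities must be > 0")
    sigma_px <- rep_len(sigma_px, n)
    fr <- if (n > 0) ag_intensities / sum(ag_intensities) else numeric(0)
    overlap <- FALSE
    if (n >= 2) {
        dmat <- as.matrix(dist(centers))
        lim <- outer(sigma_px, sigma_px, "+") * 3
        overlap <- any(dmat[upper.tri(dmat)] < lim[upper.tri(lim)])
    }
    structure(list(centers = centers, ag_intensities = ag_intensities,
                   sigma_px = sigma_px, pcd79_per_ag = pcd79_per_ag,
                   designed_fractions = fr,
                   csmac_truth = if (n > 0) csmac_rule(fr)$is_csmac else NA,
                   overlapping = overlap,
                   pixel_size_um = pixel_size_um),
              class = "synapse_truth")
}

#' Draw a random synapse ground truth
#'
#' Cluster centers are placed by rejection sampling with a minimum pairwise
#' separation (so designed clusters stay resolvable), intensities are
#' log-normal, and the cSMAC state follows from the drawn fractions. The
#' default intensity spread (`intensity_sdlog = 0.35`, a few-fold range
#' within one cell) keeps every designed cluster bright enough to be
#' segmentable, so the designed fractions describe what is actually
#' recoverable from the rendered image.
#'
#' @param seed integer seed.
#' @param n_clusters number of clusters; if `NULL`, drawn uniformly from 1:6.
#' @param image_size image shape the truth must fit into, with a margin.
#' @param sigma_px cluster Gaussian radius.
#' @param pcd79_per_ag designed amplification ratio.
#' @param intensity_meanlog,intensity_sdlog log-normal parameters of the
#'   per-cluster integrated intensities.
#' @param min_separation_px minimum center-to-center distance.
#' @param pixel_size_um pixel size in micrometres.
#' @return A `synapse_truth`.
#' @export
random_synapse_truth <- function(seed, n_clusters = NULL,
                                 image_size = c(96, 96), sigma_px = 2,
                                 pcd79_per_ag = 1,
                                 intensity_meanlog = log(2e4),
                                 intensity_sdlog = 0.35,
                                 min_separation_px = 14,
                                 pixel_size_um = 0.1) {
    with_seed(seed, {
        if (is.null(n_clusters)) n_clusters <- sample.int(6, 1)
        margin <- 12
        pts <- matrix(NA_real_, 0, 2)
        tries <- 0
        while (nrow(pts) < n_clusters && tries < 2000) {
            p <- c(runif(1, margin, image_size[2] - margin),
                   runif(1, margin, image_size[1] - margin))
            ok <- nrow(pts) == 0 ||
                all(sqrt(rowSums(sweep(pts, 2, p)^2)) >= min_separation_px)
            if (ok) pts <- rbind(pts, p)
            tries <- tries + 1
        }
        n_clusters <- nrow(pts)
        ints <- rlnorm(n_clusters, intensity_meanlog, intensity_sdlog)
        synapse_truth(pts, ints, sigma_px = sigma_px,
                      pcd79_per_ag = pcd79_per_ag,
                      pixel_size_um = pixel_size_um)
    })
}

#' Render a synthetic synapse frame
#'
#' Each cluster is rendered as an isotropic 2D Gaussian whose integral equals
#' its designed intensity; the clean pCD79 channel is `pcd79_per_ag` times
#' the clean Ag channel. Both channels then pass through the camera model
#' with independent noise.
#'
#' @param truth a [synapse_truth]; zero clusters yields a valid blank frame.
#' @param camera a [camera_model].
#' @param image_size integer (rows, cols).
#' @param seed integer seed.
#' @return A list with `frame` (channels `Ag`, `pCD79`) and `truth`.
#' @export
simulate_synapse_frame <- function(truth, camera, image_size = c(96, 96),
                                   seed = 1) {
    stopifnot(inherits(truth, "synapse_truth"))
    n <- nrow(truth$centers)
    if (n > 0) {
        s <- truth$sigma_px
        if (any(truth$centers[, 1] < 1 + 2 * s) ||
            any(truth$centers[, 1] > image_size[2] - 2 * s) ||
            any(truth$centers[, 2] < 1 + 2 * s) ||
            any(truth$centers[, 2] > image_size[1] - 2 * s))
            stop("cluster centers must lie inside the image with a 2-sigma margin")
    }
    ag <- matrix(0, image_size[1], image_size[2])
    for (k in seq_len(n)) {
        r2 <- radius_map(image_size, truth$centers[k, ])^2
        sg <- truth$sigma_px[k]
        ag <- ag + truth$ag_intensities[k] / (2 * pi * sg^2) *
            exp(-r2 / (2 * sg^2))
    }
    pc <- truth$pcd79_per_ag * ag
    chans <- list(
        Ag = calibrated_image(
            apply_camera_model(ag, camera, derive_seed(seed, 1)),
            truth$pixel_size_um, "Ag"),
        pCD79 = calibrated_image(
            apply_camera_model(pc, camera, derive_seed(seed, 2)),
            truth$pixel_size_um, "pCD79"))
    list(frame = multichannel_frame(chans), truth = truth)
}

#' Ground truth for a synthetic retrograde-flow movie
#'
#' @param v_true_nm_s true centripetal speed in nm/s.
#' @param frame_interval_s seconds between frames (> 0), default 2 as in
#'   live-cell TIRF acquisition.
#' @param pixel_size_um pixel size in micrometres.
#' @param n_frames number of frames.
#' @param amplitude,baseline intensity scale of the moving texture and the
#'   static background level.
#' @return An object of class `flow_movie_truth` including the implied
#'   per-frame displacement in pixels
#'   (`v_true_nm_s * frame_interval_s / (1000 * pixel_size_um)`).
#' @export
flow_movie_truth <- function(v_true_nm_s = 100, frame_interval_s = 2,
                             pixel_size_um = 0.1, n_frames = 40,
                             amplitude = 300, baseline = 20) {
    if (frame_interval_s <= 0) stop("'frame_interval_s' must be > 0")
    stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
    if (v_true_nm_s < 0) stop("'v_true_nm_s' must be >= 0")
    d <- v_true_nm_s * frame_interval_s / (1000 * pixel_size_um)
    structure(list(v_true_nm_s = v_true_nm_s,
                   frame_interval_s = frame_interval_s,
                   pixel_size_um = pixel_size_um, n_frames = n_frames,
                   displacement_px_per_frame = d,
                   amplitude = amplitude, baseline = baseline),
              class = "flow_movie_truth")
}

#' Render a synthetic retrograde-flow movie
#'
#' A 1D band texture (a sum of random-phase cosines, analytic so sub-pixel
#' translation is exact) is modulated by a static lamellipodial envelope in y
#' and translated toward the cell center (decreasing x) by exactly
#' `displacement_px_per_frame` each frame, then imaged through the camera
#' model. Per-frame displacements below 0.05 px are rejected as
#' indistinguishable from a static scene (zero motion itself is allowed).
#'
#' @param truth a [flow_movie_truth].
#' @param camera a [camera_model].
#' @param image_size integer (rows, cols).
#' @param seed integer seed (texture and noise).
#' @return A list with `movie` (a [time_lapse]) and `truth`.
#' @export
simulate_flow_movie <- function(truth, camera, image_size = c(48, 128),
                                seed = 1) {
    stopifnot(inherits(truth, "flow_movie_truth"))
    d <- truth$displacement_px_per_frame
    if (d > 0 && d < 0.05)
        stop("per-frame displacement below 0.05 px; motion indistinguishable from static")
    nr <- image_size[1]; nc <- image_size[2]
    tex <- with_seed(derive_seed(seed, 0), list(
        f = runif(12, 0.03, 0.12), a = runif(12, 0.5, 1),
        phi = runif(12, 0, 2 * pi)))
    band <- function(x) {     # values roughly in [-K, K]; rescaled below
        v <- 0
        for (k in seq_along(tex$f))
            v <- v + tex$a[k] * cos(2 * pi * tex$f[k] * x + tex$phi[k])
        v
    }
    # normalize the texture over the swept x-range so frames share one scale
    xs <- seq(1, nc + d * truth$n_frames + 1, by = 0.25)
    vs <- band(xs)
    lo <- min(vs); hi <- max(vs)
    env <- exp(-((seq_len(nr) - (nr + 1) / 2)^2) / (2 * (nr / 4)^2))
    frames <- vector("list", truth$n_frames)
    for (t in seq_len(truth$n_frames)) {
        prof <- (band(seq_len(nc) + d * (t - 1)) - lo) / (hi - lo)
        clean <- truth$baseline + truth$amplitude * outer(env, prof)
        frames[[t]] <- apply_camera_model(clean, camera, derive_seed(seed, t))
    }
    list(movie = time_lapse(frames, truth$pixel_size_um,
                            truth$frame_interval_s),
         truth = truth)
}
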