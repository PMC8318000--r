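#' Otsu binarization
#'
#' Computes the Otsu threshold and returns the binary foreground mask of
#' pixels strictly above it. Candidate thresholds are the boundaries of a
#' 256-bin quantization of the intensity range; for each candidate the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2` is computed exactly from
#' the data (via cumulative sums over the sorted intensities, not from
#' binned approximations), and the lowest maximizing candidate is chosen.
#'
#' @param img a [calibrated_image] or numeric matrix with at least two
#'   distinct values.
#' @return A logical matrix with attribute `threshold`. A constant image
#'   yields an empty mask with a warning (degenerate histogram).
#' @export
otsu_binarize <- function(img) {
    m <- as_intensity_matrix(img)
    rng <- range(m)
    if (rng[1] == rng[2]) {
        warning("constant image: degenerate histogram, empty foreground")
        out <- matrix(FALSE, nrow(m), ncol(m))
        attr(out, "threshold") <- rng[1]
        return(out)
    }
    cand <- seq(rng[1], rng[2], length.out = 257)
    cand <- cand[2:256]                  # interior bin boundaries
    s <- sort(as.vector(m))
    n <- length(s)
    cs <- cumsum(s)
    n0 <- findInterval(cand, s)          # pixels at or below each candidate
    valid <- n0 > 0L & n0 < n
    sum0 <- ifelse(n0 > 0L, cs[pmax(n0, 1L)], 0)
    mu0 <- sum0 / n0
    mu1 <- (cs[n] - sum0) / (n - n0)
    w0 <- n0 / n
    sigma2b <- ifelse(valid, w0 * (1 - w0) * (mu0 - mu1)^2, -Inf)
    th <- cand[which.max(sigma2b)]       # ties break toward lower threshold
    out <- m > th
    attr(out, "threshold") <- th
    out
}

#' Segment fluorescent clusters from a binary mask
#'
#' Connected components of the mask (8-connectivity by default, matching the
#' diagonal-inclusive particle-analysis convention) are filtered by physical
#' area: only components strictly larger than `min_area_um2` are retained.
#' The retained masks are mapped back onto `img` and the pixel intensities
#' within each mask are summed, giving per-cluster integrated intensities and
#' their fractions of the total clustered intensity.
#'
#' @param mask logical/binary matrix (e.g. from [otsu_binarize()]).
#' @param img the image the mask is mapped onto for intensity quantification
#'   (normally the background-subtracted image).
#' @param min_area_um2 minimum cluster area in um^2; components of exactly
#'   this area are excluded (strict inequality). Default 0.05.
#' @param pixel_size_um pixel size; taken from `img` when it is a
#'   [calibrated_image].
#' @param connectivity 8 (default) or 4.
#' @return An object of class `cluster_set`: a list with `clusters` (a
#'   data.frame with columns id, n_px, area_um2, intensity, fraction),
#'   `total_clustered_intensity`, `label` (the labelled image of retained
#'   clusters) and `pixel_size_um`. An empty mask yields zero clusters with
#'   total 0.
#' @export
segment_clusters <- function(mask, img, min_area_um2 = 0.05,
                             pixel_size_um = NULL, connectivity = 8) {
    m <- as_intensity_matrix(img)
    if (!identical(dim(mask), dim(m))) stop("mask and image shape mismatch")
    ps <- pixel_size_um %||% attr(img, "pixel_size_um")
    if (is.null(ps)) stop("pixel_size_um required (image is uncalibrated)")
    stopifnot_scalar_pos(ps, "pixel_size_um")
    mk <- mask != 0
    if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
    lab <- .label_components_cpp(mk, as.integer(connectivity))
    n_all <- max(lab, 0L)
    px_area <- ps^2
    if (n_all == 0L) {
        return(structure(list(
            clusters = data.frame(id = integer(0), n_px = integer(0),
                                  area_um2 = numeric(0),
                                  intensity = numeric(0),
                                  fraction = numeric(0)),
            total_clustered_intensity = 0,
            label = lab, pixel_size_um = ps), class = "cluster_set"))
    }
    counts <- tabulate(lab[lab > 0L], nbins = n_all)
    sums <- as.numeric(rowsum(as.vector(m)[lab > 0L], lab[lab > 0L],
                              reorder = TRUE))
    areas <- counts * px_area
    # strict inequality, robust to floating-point round-off: a component of
    # exactly min_area_um2 (e.g. 5 px of 0.01 um^2 against 0.05) is excluded
    keep <- which(areas - min_area_um2 > 1e-9 * max(min_area_um2, px_area))
    relab <- integer(n_all); relab[keep] <- seq_along(keep)
    lab2 <- lab
    lab2[lab > 0L] <- relab[lab[lab > 0L]]
    intensity <- sums[keep]
    total <- sum(intensity)
    cl <- data.frame(id = seq_along(keep), n_px = counts[keep],
                     area_um2 = areas[keep], intensity = intensity,
                     fraction = if (total > 0) intensity / total
                                else rep(NA_real_, length(keep)))
    structure(list(clusters = cl, total_clustered_intensity = total,
                   label = lab2, pixel_size_um = ps),
              class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
    cat(sprintf("cluster_set: %d clusters, total clustered intensity %.6g\n",
                nrow(x$clusters), x$total_clustered_intensity))
    if (nrow(x$clusters)) print(head(x$clusters, 10))
    invisible(x)
}

#' The cSMAC rule on a vector of intensity fractions
#'
#' Internal core shared by truth construction and classification: sort the
#' fractions in decreasing order and find the smallest number k of top
#' clusters whose cumulative fraction exceeds 0.90; a cSMAC means k <= 2.
#'
#' @param fractions numeric vector of per-cluster intensity fractions.
#' @param threshold cumulative-fraction threshold, default 0.9.
#' @param max_clusters maximum cluster count for a cSMAC call, default 2.
#' @return list(is_csmac, n_clusters_to_90).
#' @keywords internal
csmac_rule <- function(fractions, threshold = 0.9, max_clusters = 2) {
    cs <- cumsum(sort(fractions, decreasing = TRUE))
    k <- which(cs > threshold)[1]
    if (is.na(k)) k <- length(fractions)   # guards rounding at the tail
    list(is_csmac = k <= max_clusters, n_clusters_to_90 = as.integer(k))
}

#' Classify cSMAC formation from segmented clusters
#'
#' A cell is deemed to have formed a central supramolecular activation
#' cluster (cSMAC) when more than 90% of its clustered Ag fluorescence is
#' contained in one or two clusters.
#'
#' @param cs a `cluster_set` (normally from the Ag channel) or a numeric
#'   vector of intensity fractions.
#' @return An object of class `csmac_call`: list with `is_csmac`,
#'   `n_clusters_to_90` and `evaluable`. An empty cluster set is reported as
#'   not evaluable (`is_csmac = NA`), which is distinct from `FALSE`.
#' @export
classify_csmac <- function(cs) {
    fr <- if (inherits(cs, "cluster_set")) cs$clusters$fraction else cs
    if (length(fr) == 0L || anyNA(fr)) {
        return(structure(list(is_csmac = NA, n_clusters_to_90 = NA_integer_,
                              evaluable = FALSE), class = "csmac_call"))
    }
    r <- csmac_rule(fr)
    structure(list(is_csmac = r$is_csmac,
                   n_clusters_to_90 = r$n_clusters_to_90,
                   evaluable = TRUE), class = "csmac_call")
}

#' @export
print.csmac_call <- function(x, ...) {
    if (!x$evaluable) cat("cSMAC call: not evaluable (no clusters)\n")
    else cat(sprintf("cSMAC call: %s (>90%% of Ag in %d cluster%s)\n",
                     if (x$is_csmac) "cSMAC" else "no cSMAC",
                     x$n_clusters_to_90,
                     if (x$n_clusters_to_90 == 1) "" else "s"))
    invisible(x)
}

#' Per-cell BCR signal-amplification ratio
#'
#' Total clustered pCD79 fluorescence divided by total clustered Ag
#' fluorescence for the same cell.
#'
#' @param pcd79_total total clustered pCD79 intensity (or a `cluster_set`).
#' @param ag_total total clustered Ag intensity (or a `cluster_set`).
#' @return The ratio, or `NA` with a warning when the Ag total is not
#'   positive (not evaluable).
#' @export
amplification_ratio <- function(pcd79_total, ag_total) {
    if (inherits(pcd79_total, "cluster_set"))
        pcd79_total <- pcd79_total$total_clustered_intensity
    if (inherits(ag_total, "cluster_set"))
        ag_total <- ag_total$total_clustered_intensity
    if (!is.finite(ag_total) || ag_total <= 0) {
        warning("Ag clustered intensity is not positive: ratio not evaluable")
        return(NA_real_)
    }
    pcd79_total / ag_total
}

#' Run the full cluster-quantification pipeline on a synapse frame
#'
#' For each requested channel: rolling-ball background subtraction, Otsu
#' binarization, connected-component segmentation with the physical area
#' filter, and intensity summation. The cSMAC call is made on the Ag channel
#' and the amplification ratio from the clustered pCD79 and Ag totals. Each
#' channel is thresholded on its own histogram.
#'
#' @param frame a [multichannel_frame] containing (at least) the channels
#'   named in `channels`.
#' @param channels channels to segment; the first is treated as Ag (cSMAC
#'   and ratio denominator), the second, when present, as the signaling
#'   readout (ratio numerator).
#' @param rolling_ball_px rolling-ball radius in pixels, default 10.
#' @param min_area_um2 cluster area filter in um^2, default 0.05.
#' @param connectivity component connectivity, default 8.
#' @return A list with `clusters` (named list of `cluster_set`), `csmac` (a
#'   `csmac_call`), and `amplification` (numeric or NA).
#' @export
quantify_synapse_frame <- function(frame, channels = c("Ag", "pCD79"),
                                   rolling_ball_px = 10, min_area_um2 = 0.05,
                                   connectivity = 8) {
    stopifnot(inherits(frame, "multichannel_frame"))
    if (!all(channels %in% names(frame$channels)))
        stop("frame is missing requested channels: ",
             paste(setdiff(channels, names(frame$channels)), collapse = ", "))
    sets <- lapply(channels, function(chn) {
        img <- subtract_background_rolling_ball(frame$channels[[chn]],
                                                rolling_ball_px)
        if (!is.null(frame$roi_mask)) {
            m <- as_intensity_matrix(img)
            m[!frame$roi_mask] <- 0
            img <- calibrated_image(m, pixel_size(frame), chn)
        }
        mask <- suppressWarnings(otsu_binarize(img))
        segment_clusters(mask, img, min_area_um2 = min_area_um2,
                         connectivity = connectivity)
    })
    names(sets) <- channels
    amp <- if (length(channels) >= 2 &&
               sets[[1]]$total_clustered_intensity > 0)
        amplification_ratio(sets[[2]], sets[[1]]) else NA_real_
    list(clusters = sets, csmac = classify_csmac(sets[[1]]),
         amplification = amp)
}
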