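bilinear_sample <- function(m, x, y) {
    # sample matrix m at fractional (x = col, y = row) positions
    nr <- nrow(m); nc <- ncol(m)
    x0 <- pmin(pmax(floor(x), 1), nc - 1); y0 <- pmin(pmax(floor(y), 1), nr - 1)
    fx <- pmin(pmax(x - x0, 0), 1); fy <- pmin(pmax(y - y0, 0), 1)
    m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
        m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
        m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
        m[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Extract a kymograph along a sampling line
#'
#' For each frame, intensities are sampled at 1-px spacing along the line
#' from `(x0, y0)` to `(x1, y1)` by bilinear interpolation and averaged
#' across `width_px` perpendicular offsets at 1-px spacing. One column per
#' frame.
#'
#' @param movie a [time_lapse].
#' @param line numeric length-4: (x0, y0, x1, y1) in pixel coordinates.
#' @param width_px odd sampling width perpendicular to the line, default 1.
#' @return An object of class `kymograph`: numeric matrix (position along
#'   line x time) with attributes `pixel_size_um`, `frame_interval_s`,
#'   `line`, `width_px`.
#' @export
extract_kymograph <- function(movie, line, width_px = 1) {
    stopifnot(inherits(movie, "time_lapse"))
    if (length(line) != 4) stop("'line' must be (x0, y0, x1, y1)")
    if (width_px < 1 || width_px %% 2 == 0) stop("'width_px' must be odd, >= 1")
    d <- dim(movie$frames[[1]])
    if (any(line[c(1, 3)] < 1) || any(line[c(1, 3)] > d[2]) ||
        any(line[c(2, 4)] < 1) || any(line[c(2, 4)] > d[1]))
        stop("line endpoints outside the image")
    len <- sqrt((line[3] - line[1])^2 + (line[4] - line[2])^2)
    n_samp <- max(2L, as.integer(round(len)) + 1L)
    tpar <- seq(0, 1, length.out = n_samp)
    ux <- (line[3] - line[1]) / len; uy <- (line[4] - line[2]) / len
    px <- line[1] + tpar * (line[3] - line[1])
    py <- line[2] + tpar * (line[4] - line[2])
    offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2)
    # perpendicular unit vector
    vx <- -uy; vy <- ux
    kymo <- vapply(movie$frames, function(f) {
        acc <- numeric(n_samp)
        for (o in offs)
            acc <- acc + bilinear_sample(f, px + o * vx, py + o * vy)
        acc / length(offs)
    }, numeric(n_samp))
    structure(kymo, pixel_size_um = pixel_size(movie),
              frame_interval_s = attr(movie, "frame_interval_s"),
              line = line, width_px = width_px,
              class = c("kymograph", "matrix", "array"))
}

#' Centripetal velocity of an annotated kymograph track
#'
#' velocity = |position change| x pixel size x 1000 / (frame change x frame
#' interval), in nm/s. Tracks are given as endpoint pairs on the kymograph,
#' mirroring manual kymograph reading.
#'
#' @param kymo a `kymograph` (used for its calibration), or `NULL` if both
#'   calibration arguments are supplied.
#' @param track numeric length-4: (position0, frame0, position1, frame1) in
#'   kymograph sample/frame units.
#' @param pixel_size_um,frame_interval_s calibration overrides.
#' @return Velocity in nm/s.
#' @export
track_velocity <- function(kymo, track, pixel_size_um = NULL,
                           frame_interval_s = NULL) {
    ps <- pixel_size_um %||% attr(kymo, "pixel_size_um")
    dt <- frame_interval_s %||% attr(kymo, "frame_interval_s")
    if (is.null(ps) || is.null(dt)) stop("calibration required")
    if (length(track) != 4) stop("'track' must be (p0, t0, p1, t1)")
    dframes <- track[4] - track[2]
    if (dframes <= 0) stop("track must advance in time (t1 > t0)")
    abs(track[3] - track[1]) * ps * 1000 / (dframes * dt)
}

#' Automated velocity estimate from a kymograph
#'
#' Estimates the dominant track slope by cross-correlating kymograph columns
#' separated by `frame_lag` frames over integer positional shifts, with
#' parabolic sub-pixel refinement of the correlation peak. This is an
#' extension for synthetic benchmarking; the primary measurement mode is
#' manual endpoint annotation via [track_velocity()].
#'
#' @param kymo a `kymograph`.
#' @param frame_lag column separation in frames, default 10.
#' @param max_shift_px largest positional shift searched; defaults to a
#'   third of the kymograph length.
#' @return Velocity in nm/s (speed; direction is not signed).
#' @export
estimate_kymograph_velocity <- function(kymo, frame_lag = 10,
                                        max_shift_px = NULL) {
    k <- unclass(kymo)
    attr(k, "pixel_size_um") <- NULL; attr(k, "frame_interval_s") <- NULL
    attr(k, "line") <- NULL; attr(k, "width_px") <- NULL
    n <- nrow(k); nt <- ncol(k)
    if (nt <= frame_lag) stop("not enough frames for the requested lag")
    max_shift <- max_shift_px %||% floor(n / 3)
    k <- sweep(k, 2, colMeans(k))        # remove static offset per column
    a <- k[, 1:(nt - frame_lag), drop = FALSE]
    b <- k[, (frame_lag + 1):nt, drop = FALSE]
    shifts <- -max_shift:max_shift
    score <- vapply(shifts, function(s) {
        ia <- max(1, 1 + s):min(n, n + s)      # rows of a
        ib <- ia - s                           # rows of b
        va <- a[ia, , drop = FALSE]; vb <- b[ib, , drop = FALSE]
        sum(va * vb) / length(va)
    }, numeric(1))
    i <- which.max(score)
    s_hat <- shifts[i]
    if (i > 1 && i < length(shifts)) {         # parabolic refinement
        y1 <- score[i - 1]; y2 <- score[i]; y3 <- score[i + 1]
        den <- y1 - 2 * y2 + y3
        if (den < 0) s_hat <- s_hat + 0.5 * (y1 - y3) / den
    }
    abs(s_hat) / frame_lag * attr(kymo, "pixel_size_um") * 1000 /
        attr(kymo, "frame_interval_s")
}

#' Summarize retrograde-flow velocities per condition
#'
#' @param tracks data.frame with columns `condition` and `velocity_nm_s`.
#' @param control label of the reference condition, default `"control"`.
#' @return A list with `medians` (data.frame: condition, n, median_nm_s) and
#'   `percent_reduction` (named numeric, one per non-control condition):
#'   100 x (1 - median_test / median_control). `NA` with a warning when the
#'   control median is zero.
#' @export
flow_summary <- function(tracks, control = "control") {
    stopifnot(is.data.frame(tracks),
              all(c("condition", "velocity_nm_s") %in% names(tracks)))
    if (!control %in% tracks$condition)
        stop("control condition '", control, "' absent from tracks")
    med <- aggregate(velocity_nm_s ~ condition, tracks, median)
    ns <- aggregate(velocity_nm_s ~ condition, tracks, length)
    medians <- data.frame(condition = med$condition, n = ns$velocity_nm_s,
                          median_nm_s = med$velocity_nm_s)
    m0 <- medians$median_nm_s[medians$condition == control]
    others <- setdiff(medians$condition, control)
    red <- setNames(rep(NA_real_, length(others)), others)
    if (m0 == 0) {
        warning("control median velocity is zero: reduction not evaluable")
    } else {
        for (cond in others)
            red[cond] <- 100 * (1 - medians$median_nm_s[
                medians$condition == cond] / m0)
    }
    list(medians = medians, percent_reduction = red)
}
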