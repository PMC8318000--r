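## Brute-force, pixel-loop oracles kept deliberately independent of the
## package implementation: plain loops, no shared helpers.

# grayscale opening with a spherical (non-flat) structuring element,
# ignoring out-of-image support
oracle_ball_opening <- function(m, radius) {
    r <- as.integer(radius)
    offs <- list()
    for (dy in -r:r) for (dx in -r:r)
        if (dx^2 + dy^2 <= radius^2)
            offs[[length(offs) + 1]] <- c(dy, dx, sqrt(radius^2 - dx^2 - dy^2))
    nr <- nrow(m); nc <- ncol(m)
    ero <- matrix(NA_real_, nr, nc)
    for (i in 1:nr) for (j in 1:nc) {
        v <- Inf
        for (o in offs) {
            ii <- i + o[1]; jj <- j + o[2]
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
                v <- min(v, m[ii, jj] - o[3])
        }
        ero[i, j] <- v
    }
    opn <- matrix(NA_real_, nr, nc)
    for (i in 1:nr) for (j in 1:nc) {
        v <- -Inf
        for (o in offs) {
            ii <- i - o[1]; jj <- j - o[2]
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
                v <- max(v, ero[ii, jj] + o[3])
        }
        opn[i, j] <- v
    }
    opn
}

# between-class variance of a threshold on a 256-bin histogram
oracle_otsu_sigma2b <- function(m, th) {
    lo <- m[m <= th]; hi <- m[m > th]
    if (length(lo) == 0 || length(hi) == 0) return(0)
    w0 <- length(lo) / length(m); w1 <- 1 - w0
    w0 * w1 * (mean(lo) - mean(hi))^2
}

# exhaustive search over the 256-bin histogram boundaries of the range
oracle_otsu_best <- function(m) {
    rng <- range(m)
    cand <- seq(rng[1], rng[2], length.out = 257)
    s <- vapply(cand, function(t) oracle_otsu_sigma2b(m, t), numeric(1))
    list(threshold = cand[which.max(s)], sigma2b = max(s))
}

# 8-connectivity labeling + per-label sums by explicit pixel loops
oracle_cluster_sums <- function(mask, img) {
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(0L, nr, nc); cur <- 0L
    for (j0 in 1:nc) for (i0 in 1:nr) {
        if (!mask[i0, j0] || lab[i0, j0] != 0L) next
        cur <- cur + 1L
        queue <- list(c(i0, j0))
        while (length(queue)) {
            p <- queue[[1]]; queue <- queue[-1]
            i <- p[1]; j <- p[2]
            if (lab[i, j] != 0L) next
            lab[i, j] <- cur
            for (di in -1:1) for (dj in -1:1) {
                ii <- i + di; jj <- j + dj
                if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                    mask[ii, jj] && lab[ii, jj] == 0L)
                    queue[[length(queue) + 1]] <- c(ii, jj)
            }
        }
    }
    if (cur == 0L) return(data.frame(n_px = integer(0), sum = numeric(0)))
    n_px <- integer(cur); sums <- numeric(cur)
    for (j in 1:nc) for (i in 1:nr) if (lab[i, j] > 0L) {
        n_px[lab[i, j]] <- n_px[lab[i, j]] + 1L
        sums[lab[i, j]] <- sums[lab[i, j]] + img[i, j]
    }
    data.frame(n_px = n_px, sum = sums)
}

# per-pixel distance binning for the radial profile
oracle_radial <- function(img, mask, center) {
    sums <- numeric(0); counts <- numeric(0); bins <- integer(0)
    nr <- nrow(img); nc <- ncol(img)
    rmax <- 0
    for (j in 1:nc) for (i in 1:nr) if (mask[i, j]) {
        r <- sqrt((j - center[1])^2 + (i - center[2])^2)
        rmax <- max(rmax, r)
        b <- floor(r) + 1L
        k <- match(b, bins)
        if (is.na(k)) {
            bins <- c(bins, b); sums <- c(sums, img[i, j]); counts <- c(counts, 1)
        } else {
            sums[k] <- sums[k] + img[i, j]; counts[k] <- counts[k] + 1
        }
    }
    o <- order(bins)
    mean_int <- (sums / counts)[o]
    data.frame(radius = (bins[o] - 0.5) / rmax,
               value = mean_int / max(mean_int))
}

# exact two-sided Mann-Whitney p by enumeration of all group labelings,
# matching the doubled-tail convention
oracle_mw_exact_p <- function(a, b) {
    pooled <- c(a, b); na <- length(a)
    rk <- rank(pooled)
    u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
    idx <- utils::combn(length(pooled), na)
    us <- apply(idx, 2, function(sel)
        sum(rank(pooled)[sel]) - na * (na + 1) / 2)
    if (u_obs > na * length(b) / 2) p <- 2 * mean(us >= u_obs)
    else p <- 2 * mean(us <= u_obs)
    min(1, p)
}

# direct evaluation of the cSMAC rule without sorting/cumsum: any single
# cluster, or any pair of clusters, holding > 90% of the intensity
oracle_csmac_direct <- function(fractions) {
    n <- length(fractions)
    if (any(fractions > 0.9)) return(TRUE)
    if (n >= 2) {
        for (i in 1:(n - 1)) for (j in (i + 1):n)
            if (fractions[i] + fractions[j] > 0.9) return(TRUE)
    }
    FALSE
}

default_camera <- function() camera_model()
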