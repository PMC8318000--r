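disk_mask <- function(n, cx, cy, R) {
    x <- matrix(seq_len(n), n, n, byrow = TRUE)
    y <- matrix(seq_len(n), n, n)
    (x - cx)^2 + (y - cy)^2 <= R^2
}

test_that("uniform disk profiles are identically 1 and normalized", {
    mk <- disk_mask(64, 32, 32, 25)
    img <- matrix(0, 64, 64); img[mk] <- 7
    p <- radial_intensity_profile(img, mk)
    expect_equal(p$value, rep(1, nrow(p)))
    expect_true(all(diff(p$radius) > 0))
    expect_equal(max(p$value), 1)
})

test_that("a bright ring at 0.8R peaks at normalized radius 0.8", {
    mk <- disk_mask(128, 64, 64, 50)
    r <- sqrt(outer((1:128 - 64)^2, (1:128 - 64)^2, "+"))
    img <- 10 + 200 * exp(-(r - 40)^2 / 8)
    img[!mk] <- 0
    p <- radial_intensity_profile(img, mk, center = c(64, 64))
    expect_lt(abs(profile_peak_radius(p) - 0.8), 1 / attr(p, "r_max_px") + 1e-9)
})

test_that("profiles match the per-pixel distance-binning oracle", {
    set.seed(5)
    img <- matrix(runif(64 * 64, 0, 50), 64, 64)
    mk <- disk_mask(64, 33, 30, 22)
    p <- radial_intensity_profile(img, mk, center = c(33, 30))
    want <- oracle_radial(img, mk, c(33, 30))
    expect_equal(p$radius, want$radius, tolerance = 1e-12)
    expect_equal(p$value, want$value, tolerance = 1e-12)
})

test_that("profiles are invariant to intensity scaling and 90-degree rotation", {
    truth <- spreading_cell_truth()
    sim <- simulate_spreading_cell(truth, noiseless_camera(), seed = 1)
    img <- unclass(sim$frame$channels$actin); mk <- sim$frame$roi_mask
    p1 <- radial_intensity_profile(img, mk)
    p2 <- radial_intensity_profile(img * 3.7, mk)
    expect_equal(p1$value, p2$value, tolerance = 1e-12)
    rot <- t(img)[ncol(img):1, ]          # 90-degree rotation
    mkr <- t(mk)[ncol(mk):1, ]
    p3 <- radial_intensity_profile(rot, mkr)
    common <- seq_len(min(nrow(p1), nrow(p3)))
    expect_lt(max(abs(p1$value[common] - p3$value[common])), 0.01)
})

test_that("population averaging: identical profiles give SE 0; empty input rejected", {
    mk <- disk_mask(64, 32, 32, 25)
    r <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, "+"))
    img <- 5 + 100 * exp(-(r - 20)^2 / 12); img[!mk] <- 0
    p <- radial_intensity_profile(img, mk, center = c(32, 32))
    pop <- average_profiles(rep(list(p), 8), grid_size = 30, span = 0.2)
    on_grid <- approx(p$radius, p$value, xout = pop$radius)$y
    expect_lt(max(abs(pop$mean - on_grid)), 0.05)
    expect_true(all(pop$se < 1e-6))
    expect_error(average_profiles(list()), "at least one")
})

test_that("the smoothed population mean tracks a known curve within 2 SE", {
    set.seed(8)
    curve <- function(r) exp(-(r - 0.6)^2 / 0.05)
    profs <- lapply(1:40, function(i) {
        r <- seq(0.02, 0.98, length.out = 45)
        v <- curve(r) + rnorm(45, 0, 0.08)
        structure(data.frame(radius = r, value = v),
                  class = c("radial_profile", "data.frame"))
    })
    pop <- average_profiles(profs, grid_size = 40, span = 0.25)
    inner <- pop$radius > 0.1 & pop$radius < 0.9   # away from edge effects
    cover <- mean(abs(pop$mean - curve(pop$radius))[inner] <=
                  2 * pop$se[inner] + 0.02)
    expect_gte(cover, 0.9)
})

test_that("peak radius: monotone profiles peak at the center; flat warns", {
    p <- structure(data.frame(radius = seq(0.05, 1, by = 0.05),
                              value = seq(1, 0.05, by = -0.05)),
                   class = c("radial_profile", "data.frame"))
    expect_equal(profile_peak_radius(p), 0.05)
    flat <- structure(data.frame(radius = c(0.1, 0.5, 1), value = c(1, 1, 1)),
                      class = c("radial_profile", "data.frame"))
    expect_warning(r <- profile_peak_radius(flat), "flat")
    expect_equal(r, 0.1)
})
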