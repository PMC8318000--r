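make_movie <- function(v_nm_s, seed = 1, camera = camera_model(),
                       n_frames = 40) {
    simulate_flow_movie(flow_movie_truth(v_true_nm_s = v_nm_s,
                                         n_frames = n_frames),
                        camera, seed = seed)$movie
}

test_that("kymograph shape and the static-movie case", {
    mv <- make_movie(0, camera = noiseless_camera(), n_frames = 10)
    ky <- extract_kymograph(mv, c(4, 24, 124, 24), width_px = 3)
    expect_identical(dim(ky), c(121L, 10L))
    expect_true(all(apply(ky, 1, function(r) diff(range(r)) == 0)))
    expect_error(extract_kymograph(mv, c(-5, 24, 124, 24)), "outside")
    expect_error(extract_kymograph(mv, c(4, 24, 124, 24), width_px = 2),
                 "odd")
})

test_that("track velocity unit arithmetic", {
    mv <- make_movie(0, n_frames = 10)
    ky <- extract_kymograph(mv, c(4, 24, 124, 24))
    # 10 px over 5 frames at 0.1 um/px and 2 s/frame -> 100 nm/s
    expect_equal(track_velocity(ky, c(20, 1, 30, 6)), 100)
    expect_equal(track_velocity(ky, c(20, 1, 20, 6)), 0)
    expect_error(track_velocity(ky, c(20, 6, 30, 1)), "advance in time")
})

test_that("velocity scales with pixel size and inversely with frame interval", {
    base <- track_velocity(NULL, c(10, 1, 30, 11), pixel_size_um = 0.1,
                           frame_interval_s = 2)
    expect_equal(track_velocity(NULL, c(10, 1, 30, 11), pixel_size_um = 0.2,
                                frame_interval_s = 2), 2 * base)
    expect_equal(track_velocity(NULL, c(10, 1, 30, 11), pixel_size_um = 0.1,
                                frame_interval_s = 4), base / 2)
})

test_that("automated slope estimation recovers the designed speed", {
    for (v in c(50, 100)) {
        ky <- extract_kymograph(make_movie(v, seed = v), c(4, 24, 124, 24),
                                width_px = 3)
        est <- estimate_kymograph_velocity(ky)
        expect_lt(abs(est - v) / v, 0.1)
    }
})

test_that("time reversal leaves the estimated speed unchanged", {
    mv <- make_movie(100, seed = 2)
    rev_mv <- time_lapse(rev(mv$frames), pixel_size(mv),
                         attr(mv, "frame_interval_s"))
    k1 <- extract_kymograph(mv, c(4, 24, 124, 24), width_px = 3)
    k2 <- extract_kymograph(rev_mv, c(4, 24, 124, 24), width_px = 3)
    v1 <- estimate_kymograph_velocity(k1)
    v2 <- estimate_kymograph_velocity(k2)
    expect_lt(abs(v1 - v2) / v1, 0.02)
})

test_that("flow summaries report medians and percent reduction vs control", {
    tracks <- data.frame(
        condition = rep(c("control", "knockdown"), each = 4),
        velocity_nm_s = c(90, 100, 110, 120, 50, 62, 70, 74))
    fs <- flow_summary(tracks)
    expect_equal(fs$medians$median_nm_s[fs$medians$condition == "control"], 105)
    expect_equal(unname(fs$percent_reduction["knockdown"]),
                 100 * (1 - 66 / 105))
    same <- data.frame(condition = rep(c("control", "knockdown"), each = 3),
                       velocity_nm_s = rep(c(80, 100, 120), 2))
    expect_equal(unname(flow_summary(same)$percent_reduction["knockdown"]), 0)
    # the stated arithmetic: control median 100, test median 62 -> 38%
    two <- data.frame(condition = c("control", "knockdown"),
                      velocity_nm_s = c(100, 62))
    expect_equal(unname(flow_summary(two)$percent_reduction["knockdown"]), 38)
})
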