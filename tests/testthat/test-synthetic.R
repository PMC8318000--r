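test_that("spreading-cell render puts the channel peaks at their designed radii", {
    truth <- spreading_cell_truth(cell_radius_px = 50,
                                  actin_ring_radius_px = 40,
                                  gmf_peak_radius_px = 30)
    sim <- simulate_spreading_cell(truth, noiseless_camera(), seed = 1)
    pa <- radial_intensity_profile(sim$frame$channels$actin,
                                   sim$frame$roi_mask)
    pg <- radial_intensity_profile(sim$frame$channels$GMFg,
                                   sim$frame$roi_mask)
    bin <- 1 / attr(pa, "r_max_px")
    expect_lt(abs(profile_peak_radius(pa) - 0.8), bin + 1e-9)
    expect_lt(abs(profile_peak_radius(pg) - 0.6), bin + 1e-9)
    # GMFg peak interior to the actin ring, as in spread B cells
    expect_lt(profile_peak_radius(pg), profile_peak_radius(pa))
})

test_that("spreading-cell geometry must fit in the image", {
    truth <- spreading_cell_truth(center = c(20, 20), cell_radius_px = 50,
                                  actin_ring_radius_px = 40,
                                  gmf_peak_radius_px = 30)
    expect_error(simulate_spreading_cell(truth, noiseless_camera(),
                                         image_size = c(64, 64), seed = 1),
                 "exceeds image bounds")
})

test_that("generators are bit-identical under a repeated seed", {
    truth <- spreading_cell_truth()
    a <- simulate_spreading_cell(truth, camera_model(), seed = 5)
    b <- simulate_spreading_cell(truth, camera_model(), seed = 5)
    expect_identical(a, b)

    st <- random_synapse_truth(seed = 11)
    expect_identical(st, random_synapse_truth(seed = 11))
    fa <- simulate_synapse_frame(st, camera_model(), seed = 3)
    fb <- simulate_synapse_frame(st, camera_model(), seed = 3)
    expect_identical(fa, fb)

    ft <- flow_movie_truth(n_frames = 5)
    ma <- simulate_flow_movie(ft, camera_model(), seed = 2)
    mb <- simulate_flow_movie(ft, camera_model(), seed = 2)
    expect_identical(ma, mb)
})

test_that("synapse truth: fractions sum to one and the stored cSMAC flag matches the rule", {
    for (i in 1:50) {
        tr <- random_synapse_truth(seed = i)
        expect_equal(sum(tr$designed_fractions), 1)
        expect_identical(tr$csmac_truth,
                         classify_csmac(tr$designed_fractions)$is_csmac)
    }
})

test_that("synapse renders drive the designed downstream calls", {
    cam <- noiseless_camera()
    one <- synapse_truth(rbind(c(48, 48)), 5e4)
    q1 <- quantify_synapse_frame(simulate_synapse_frame(one, cam, seed = 1)$frame)
    expect_true(q1$csmac$is_csmac)

    three <- synapse_truth(rbind(c(25, 25), c(70, 25), c(48, 70)),
                           c(0.4, 0.3, 0.3) * 1e5)
    q3 <- quantify_synapse_frame(simulate_synapse_frame(three, cam, seed = 1)$frame)
    expect_false(q3$csmac$is_csmac)
    expect_identical(q3$csmac$n_clusters_to_90, 3L)

    blank <- synapse_truth(matrix(numeric(0), 0, 2), numeric(0))
    sim <- simulate_synapse_frame(blank, cam, seed = 1)
    expect_equal(max(as_vec <- unclass(sim$frame$channels$Ag)), 0)
})

test_that("flow movie translates at the designed speed", {
    cam <- noiseless_camera()
    static <- simulate_flow_movie(flow_movie_truth(v_true_nm_s = 0,
                                                   n_frames = 4),
                                  cam, seed = 1)$movie
    expect_identical(static$frames[[1]], static$frames[[4]])

    # displacement exactly 2 px/frame: kymograph columns are shifted copies
    tr2 <- flow_movie_truth(v_true_nm_s = 100, frame_interval_s = 2,
                            pixel_size_um = 0.1, n_frames = 6)
    expect_equal(tr2$displacement_px_per_frame, 2)
    mv <- simulate_flow_movie(tr2, cam, seed = 4)$movie
    ky <- extract_kymograph(mv, c(4, 24, 124, 24))
    shifted <- ky[1:(nrow(ky) - 2), 2]
    expect_equal(ky[3:nrow(ky), 1], shifted, tolerance = 1e-8)

    expect_error(flow_movie_truth(frame_interval_s = 0), "frame_interval_s")
    # sub-threshold nonzero motion is rejected
    slow <- flow_movie_truth(v_true_nm_s = 1)
    expect_error(simulate_flow_movie(slow, cam, seed = 1), "0.05 px")
})
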