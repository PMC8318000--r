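test_that("Otsu separates a bimodal image and matches exhaustive search", {
    img <- matrix(c(rep(0, 50), rep(100, 50)), 10)
    mask <- otsu_binarize(img)
    th <- attr(mask, "threshold")
    expect_true(th > 0 && th < 100)
    expect_identical(sum(mask), 50L)
    expect_true(all(img[mask] == 100))

    set.seed(12)
    for (i in 1:5) {
        m <- matrix(c(rnorm(150, 20, 4), rnorm(106, 80, 8)), 16, 16)
        m <- m - min(m)
        got <- attr(otsu_binarize(m), "threshold")
        best <- oracle_otsu_best(m)
        # the returned threshold attains the exhaustive-search maximum of
        # the between-class variance (same 256-bin histogram convention)
        expect_equal(oracle_otsu_sigma2b(m, got), best$sigma2b,
                     tolerance = 1e-9)
    }
})

test_that("constant images yield an empty mask and no downstream clusters", {
    img <- calibrated_image(matrix(5, 12, 12), 0.1)
    expect_warning(mask <- otsu_binarize(img), "constant")
    expect_false(any(mask))
    cs <- segment_clusters(mask, img)
    expect_identical(nrow(cs$clusters), 0L)
    expect_identical(cs$total_clustered_intensity, 0)
    expect_false(classify_csmac(cs)$evaluable)
})

test_that("area filter is strict: 5 px at 0.1 um discarded, 6 px retained", {
    px <- 0.1                      # pixel area 0.01 um^2
    m <- matrix(0, 20, 20)
    m[2, 2:6] <- 10                # 5 px = 0.0500 um^2, not > 0.05
    m[10, 3:8] <- 10               # 6 px = 0.06 um^2
    img <- calibrated_image(m, px)
    cs <- segment_clusters(m > 0, img)
    expect_identical(nrow(cs$clusters), 1L)
    expect_equal(cs$clusters$area_um2, 0.06)
    expect_equal(cs$clusters$n_px, 6L)
})

test_that("per-cluster sums and areas match the pixel-loop oracle", {
    set.seed(21)
    img <- matrix(runif(48 * 48, 0, 100), 48, 48)
    mask <- matrix(FALSE, 48, 48)
    for (k in 1:6) {
        c0 <- sample(6:42, 2); r <- sample(1:3, 1)
        mask[pmax(1, c0[1] - r):pmin(48, c0[1] + r),
             pmax(1, c0[2] - r):pmin(48, c0[2] + r)] <- TRUE
    }
    ci <- calibrated_image(img, 0.1)
    cs <- segment_clusters(mask, ci, min_area_um2 = 0)
    want <- oracle_cluster_sums(mask, img)
    expect_identical(nrow(cs$clusters), nrow(want))
    expect_equal(sort(cs$clusters$intensity), sort(want$sum))
    expect_equal(sort(cs$clusters$n_px), sort(want$n_px))
    expect_equal(sum(cs$clusters$fraction), 1)
    expect_lte(cs$total_clustered_intensity, sum(img))
})

test_that("4-connectivity splits diagonal touches that 8-connectivity joins", {
    m <- matrix(0, 8, 8)
    m[2:3, 2:3] <- 1; m[4:5, 4:5] <- 1      # touching corner-to-corner
    img <- calibrated_image(m, 1)
    expect_identical(nrow(segment_clusters(m > 0, img, 0)$clusters), 1L)
    expect_identical(
        nrow(segment_clusters(m > 0, img, 0, connectivity = 4)$clusters), 2L)
})

test_that("cSMAC calls follow the >90%-in-<=2-clusters rule", {
    c1 <- classify_csmac(c(0.95, 0.05))
    expect_true(c1$is_csmac); expect_identical(c1$n_clusters_to_90, 1L)
    c2 <- classify_csmac(c(0.50, 0.41, 0.09))
    expect_true(c2$is_csmac); expect_identical(c2$n_clusters_to_90, 2L)
    c3 <- classify_csmac(c(0.4, 0.3, 0.3))
    expect_false(c3$is_csmac); expect_identical(c3$n_clusters_to_90, 3L)
    ne <- classify_csmac(numeric(0))
    expect_false(ne$evaluable); expect_true(is.na(ne$is_csmac))
})

test_that("merging two clusters can only flip the call toward cSMAC", {
    set.seed(30)
    for (i in 1:100) {
        n <- sample(3:8, 1)
        fr <- runif(n); fr <- fr / sum(fr)
        top2 <- function(f) sum(sort(f, decreasing = TRUE)[1:min(2, length(f))])
        pair <- sample(n, 2)
        merged <- c(fr[-pair], sum(fr[pair]))
        expect_gte(top2(merged) + 1e-12, top2(fr))
        if (classify_csmac(fr)$is_csmac)
            expect_true(classify_csmac(merged)$is_csmac)
    }
})

test_that("amplification ratio arithmetic and degenerate cases", {
    expect_equal(amplification_ratio(50, 50), 1)
    expect_equal(amplification_ratio(0, 10), 0)
    expect_warning(r <- amplification_ratio(5, 0), "not evaluable")
    expect_true(is.na(r))
})

test_that("the whole cluster pipeline is invariant to a constant offset", {
    tr <- synapse_truth(rbind(c(30, 30), c(64, 60)), c(6e4, 3e4),
                        pcd79_per_ag = 0.5)
    sim <- simulate_synapse_frame(tr, camera_model(), seed = 9)
    shift <- sim$frame
    shift$channels <- lapply(shift$channels, function(ch)
        calibrated_image(unclass(ch) + 500, attr(ch, "pixel_size_um"),
                         attr(ch, "channel")))
    q0 <- quantify_synapse_frame(sim$frame)
    q1 <- quantify_synapse_frame(shift)
    expect_equal(q0$clusters$Ag$clusters, q1$clusters$Ag$clusters,
                 tolerance = 1e-8)
    expect_identical(q0$csmac$is_csmac, q1$csmac$is_csmac)
    expect_equal(q0$amplification, q1$amplification, tolerance = 1e-8)
})
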