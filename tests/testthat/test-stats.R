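test_that("ROUT: degenerate and small samples are never flagged", {
    expect_warning(r <- rout_outliers(rep(4.2, 10)), "degenerate")
    expect_identical(r$n_flagged, 0L)
    r2 <- rout_outliers(c(1, 2, 100))          # below min_n
    expect_identical(r2$n_flagged, 0L)
})

test_that("ROUT detects a gross outlier and spares clean data", {
    det <- vapply(1:200, function(s) {
        set.seed(s)
        x <- c(rnorm(30), 10)
        rout_outliers(x)$outlier[31]
    }, logical(1))
    expect_gte(mean(det), 0.99)
    set.seed(77)
    fp <- vapply(1:400, function(i) mean(rout_outliers(rnorm(50))$outlier),
                 numeric(1))
    expect_lte(mean(fp), 0.015)
})

test_that("ROUT flags are invariant under affine transforms", {
    set.seed(9)
    x <- c(rnorm(40), 8, -7)
    f1 <- rout_outliers(x)$outlier
    f2 <- rout_outliers(3.5 * x - 120)$outlier
    expect_identical(f1, f2)
})

test_that("Mann-Whitney: exact enumeration agreement and invariances", {
    mw <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
    expect_identical(mw$U, 0)
    expect_equal(mw$p, 0.1)
    expect_true(mw$exact)

    set.seed(4)
    for (i in 1:6) {
        a <- rnorm(4); b <- rnorm(4, 1)
        expect_equal(mann_whitney_u(a, b)$p, oracle_mw_exact_p(a, b),
                     tolerance = 1e-12)
    }
    # invariance under a strictly monotone transform of the pooled data
    a <- rexp(8); b <- rexp(10) + 0.3
    expect_equal(mann_whitney_u(a, b)$p,
                 mann_whitney_u(exp(a), exp(b))$p, tolerance = 1e-12)
    # identical samples carry no separation
    expect_gte(mann_whitney_u(1:20, 1:20)$p, 0.99)
    expect_equal(mann_whitney_u(rep(1, 5), rep(1, 7))$p, 1)
})

test_that("paired t: closed form, invariance, degenerate handling", {
    r <- paired_t_test(c(2, 4, 6), c(1, 2, 3))   # d = 1, 2, 3
    expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
    expect_equal(r$p, 2 * pt(r$t, df = 2, lower.tail = FALSE),
                 tolerance = 1e-12)

    a <- rnorm(6); b <- rnorm(6)
    expect_equal(paired_t_test(a + 5, b + 5)$t, paired_t_test(a, b)$t,
                 tolerance = 1e-10)

    same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t, 0); expect_equal(same$p, 1)
    sym <- paired_t_test(c(2, 0), c(1, 1))       # d = 1, -1
    expect_equal(sym$t, 0); expect_equal(sym$p, 1)
    expect_warning(ne <- paired_t_test(c(2, 3, 4), c(1, 2, 3)),
                   "not evaluable")
    expect_true(is.na(ne$p))
})

test_that("percent-of-control normalization per experiment and time point", {
    tab <- data.frame(
        experiment = rep("e1", 8),
        condition = rep(c("control", "knockdown"), each = 4),
        time_point = 15,
        value = c(80, 90, 100, 110, 40, 45, 50, 55))
    out <- normalize_to_control(tab)
    expect_equal(out$percent_of_control, 50)
    tab$value[5:8] <- tab$value[1:4]
    expect_equal(normalize_to_control(tab)$percent_of_control, 100)
    # scale-free within a stratum
    tab2 <- tab; tab2$value <- tab2$value * 7
    expect_equal(normalize_to_control(tab2)$percent_of_control,
                 normalize_to_control(tab)$percent_of_control)
})

test_that("normalization recovers a designed knockdown ratio from noisy cohorts", {
    set.seed(14)
    tab <- do.call(rbind, lapply(1:3, function(e) {
        data.frame(experiment = paste0("e", e),
                   condition = rep(c("control", "knockdown"), each = 30),
                   time_point = 30,
                   value = c(rlnorm(30, log(1000), 0.3),
                             rlnorm(30, log(600), 0.3)))
    }))
    out <- normalize_to_control(tab)
    expect_lt(max(abs(out$percent_of_control - 60)), 10)
    expect_lt(abs(mean(out$percent_of_control) - 60), 5)
})

test_that("densitometry ratios normalize to the reference sample", {
    expect_equal(densitometry_ratio(120, 80, 120 / 80), 1)
    expect_equal(densitometry_ratio(200, 100, 0.5), 4)
    expect_equal(densitometry_ratio(0, 100, 0.5), 0)
    expect_error(densitometry_ratio(10, 0, 1), "positive")
    expect_error(densitometry_ratio(10, 5, 0), "positive")
})

test_that("experiment summaries: order statistics, proportions, SEM", {
    tab <- data.frame(condition = "control", time_point = 30,
                      value = 1:9)
    s <- summarize_experiments(tab)
    expect_equal(s$strata$median, 5)
    expect_equal(s$strata$q25, 3); expect_equal(s$strata$q75, 7)

    tab2 <- data.frame(condition = "control", time_point = 30,
                       value = 1, is_csmac = c(rep(TRUE, 6), rep(FALSE, 4)))
    expect_equal(summarize_experiments(tab2)$csmac_percent$percent_csmac, 60)

    tab3 <- data.frame(condition = "control", time_point = 30,
                       experiment = rep(c("e1", "e2", "e3"), each = 3),
                       value = rep(c(10, 20, 30), each = 3))
    em <- summarize_experiments(tab3)$experiment_medians
    expect_equal(em$mean_of_medians, 20)
    expect_equal(em$sem, 5.7735, tolerance = 1e-4)
})
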