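#' Robust outlier removal (ROUT) for a measurement column
#'
#' Location-only specialization of robust regression and outlier removal:
#' a robust center is fitted by iteratively reweighted least squares with
#' Lorentzian (Cauchy-type) weights, the robust standard deviation of the
#' residuals (RSDR) is taken as the 68.27th percentile of the absolute
#' residuals with the small-sample correction n/(n - 1), and residual
#' t-ratios are tested largest-first with a step-down false-discovery
#' procedure at rate `Q`: the i-th most extreme point is flagged when its
#' two-sided t-tail probability (df = n - 1) falls below
#' `Q * (n - i + 1) / n`, stopping at the first failure. Flagged values are
#' marked, never silently deleted.
#'
#' Below `min_n` observations no flagging is attempted. A degenerate sample
#' (RSDR of zero, e.g. constant data) yields no flags with a warning.
#'
#' @param values numeric vector; non-finite entries are never flagged.
#' @param Q target false-discovery rate, default 0.01 (1%).
#' @param min_n minimum sample size for flagging, default 5.
#' @param max_iter,tol IRLS iteration cap and relative convergence
#'   tolerance.
#' @return An object of class `rout_result`: list with `outlier` (logical
#'   vector), `center` (robust center), `rsdr`, `Q`, `n_flagged`.
#' @export
rout_outliers <- function(values, Q = 0.01, min_n = 5, max_iter = 60,
                          tol = 1e-9) {
    stopifnot(is.numeric(values))
    if (Q <= 0 || Q >= 1) stop("'Q' must be in (0, 1)")
    ok <- is.finite(values)
    x <- values[ok]
    n <- length(x)
    flags <- rep(FALSE, length(values))
    if (n < min_n) {
        return(structure(list(outlier = flags, center = median(x),
                              rsdr = NA_real_, Q = Q, n_flagged = 0L),
                         class = "rout_result"))
    }
    rsdr_of <- function(r) unname(quantile(abs(r), 0.6827, type = 7)) *
        n / (n - 1)
    m <- median(x)
    s <- rsdr_of(x - m)
    if (s <= 0) {
        warning("degenerate RSDR (no residual spread): no outliers flagged")
        return(structure(list(outlier = flags, center = m, rsdr = 0,
                              Q = Q, n_flagged = 0L), class = "rout_result"))
    }
    for (it in seq_len(max_iter)) {
        w <- 1 / (1 + ((x - m) / s)^2)
        m_new <- sum(w * x) / sum(w)
        s_new <- rsdr_of(x - m_new)
        conv <- abs(m_new - m) <= tol * max(s, abs(m), 1e-300)
        m <- m_new
        if (s_new > 0) s <- s_new
        if (conv) break
    }
    t_ratio <- abs(x - m) / s
    p <- 2 * pt(t_ratio, df = n - 1, lower.tail = FALSE)
    ord <- order(p)                       # most extreme first
    fl <- rep(FALSE, n)
    for (i in seq_len(n)) {
        alpha_i <- Q * (n - i + 1) / n
        if (p[ord[i]] < alpha_i) fl[ord[i]] <- TRUE else break
    }
    flags[ok] <- fl
    structure(list(outlier = flags, center = m, rsdr = s, Q = Q,
                   n_flagged = sum(fl)), class = "rout_result")
}

#' @export
print.rout_result <- function(x, ...) {
    cat(sprintf("ROUT (Q = %g%%): %d of %d values flagged; center %.4g, RSDR %.4g\n",
                100 * x$Q, x$n_flagged, length(x$outlier), x$center, x$rsdr))
    invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-based comparison of two independent samples. The p-value is exact
#' (from the null permutation distribution of the rank sum) when there are
#' no ties and `n_a * n_b <= exact_limit`; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param sample_a,sample_b numeric vectors (nonempty).
#' @param exact_limit product-of-sizes bound for the exact computation,
#'   default 400.
#' @return A list with `U` (the U statistic for `sample_a`), `p` (two-sided),
#'   and `exact` (logical). Completely tied data yield p = 1.
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact_limit = 400) {
    a <- sample_a[is.finite(sample_a)]; b <- sample_b[is.finite(sample_b)]
    if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
    na <- length(a); nb <- length(b)
    ties <- anyDuplicated(c(a, b)) > 0
    U <- sum(rank(c(a, b))[seq_len(na)]) - na * (na + 1) / 2
    if (diff(range(c(a, b))) == 0)
        return(list(U = U, p = 1, exact = FALSE))
    use_exact <- !ties && na * nb <= exact_limit
    wt <- suppressWarnings(wilcox.test(a, b, exact = use_exact,
                                       correct = TRUE))
    p <- min(1, wt$p.value)
    list(U = U, p = p, exact = use_exact)
}

#' Two-tailed paired t test
#'
#' @param paired_a,paired_b numeric vectors of equal length (n >= 2),
#'   matched by position.
#' @return A list with `t`, `p` (two-sided), `df`, `mean_diff`. When every
#'   difference is identical and nonzero the statistic is unbounded and the
#'   test is reported as not evaluable (`t = NA`, `p = NA`, with a warning);
#'   identical pairs (all differences zero) give t = 0, p = 1.
#' @export
paired_t_test <- function(paired_a, paired_b) {
    if (length(paired_a) != length(paired_b)) stop("samples must be paired")
    keep <- is.finite(paired_a) & is.finite(paired_b)
    d <- paired_a[keep] - paired_b[keep]
    n <- length(d)
    if (n < 2) stop("need at least 2 pairs")
    if (sd(d) == 0) {
        if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1, mean_diff = 0))
        warning("zero difference variance with nonzero mean: not evaluable")
        return(list(t = NA_real_, p = NA_real_, df = n - 1,
                    mean_diff = mean(d)))
    }
    tt <- t.test(paired_a[keep], paired_b[keep], paired = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), mean_diff = mean(d))
}

#' Per-experiment percent-of-control normalization
#'
#' For each (experiment, time point) stratum, the knockdown median is
#' expressed as a percent of the control median for the same time point in
#' the same experiment: 100 x median(knockdown) / median(control).
#'
#' @param table data.frame with columns `experiment`, `condition`,
#'   `time_point`, `value` (a cell-measurement table).
#' @param control,test condition labels, defaults `"control"` and
#'   `"knockdown"`.
#' @return data.frame with columns `experiment`, `time_point`,
#'   `median_control`, `median_test`, `percent_of_control`. Strata with a
#'   zero control median are reported as `NA` with a warning; strata missing
#'   either condition are dropped with a warning.
#' @export
normalize_to_control <- function(table, control = "control",
                                 test = "knockdown") {
    stopifnot(is.data.frame(table),
              all(c("experiment", "condition", "time_point", "value")
                  %in% names(table)))
    strata <- unique(table[, c("experiment", "time_point")])
    out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
        sub <- table[table$experiment == strata$experiment[i] &
                     table$time_point == strata$time_point[i], ]
        vc <- sub$value[sub$condition == control]
        vt <- sub$value[sub$condition == test]
        if (length(vc) == 0L || length(vt) == 0L) {
            warning("stratum missing a condition: dropped")
            return(NULL)
        }
        mc <- median(vc); mt <- median(vt)
        pct <- if (mc == 0) {
            warning("zero control median: stratum not evaluable")
            NA_real_
        } else 100 * mt / mc
        data.frame(experiment = strata$experiment[i],
                   time_point = strata$time_point[i],
                   median_control = mc, median_test = mt,
                   percent_of_control = pct)
    }))
    out
}

#' Densitometry ratio normalized to a reference sample
#'
#' Band intensity divided by its loading control, then divided by the
#' reference band/loading ratio (the reference sample's own normalized value
#' is 1.0 by construction).
#'
#' @param band band intensity (vectorized).
#' @param loading loading-control intensity (> 0).
#' @param reference_ratio band/loading ratio of the reference sample (> 0).
#' @return (band / loading) / reference_ratio.
#' @export
densitometry_ratio <- function(band, loading, reference_ratio) {
    if (any(!is.finite(loading)) || any(loading <= 0))
        stop("loading-control intensity must be positive")
    if (!is.finite(reference_ratio) || reference_ratio <= 0)
        stop("reference ratio must be positive")
    (band / loading) / reference_ratio
}

sem <- function(x) sd(x) / sqrt(length(x))

#' Summary tables for per-cell measurements
#'
#' Produces the descriptive layer behind the dot plots and line graphs:
#' per-stratum median, interquartile range and n; the percent of
#' cSMAC-positive cells per condition and time point (when an `is_csmac`
#' column is present); and the mean +/- SEM of per-experiment medians across
#' experiments.
#'
#' @param table data.frame with columns `condition`, `time_point`, `value`
#'   and optionally `experiment`, `is_csmac`.
#' @return A list with `strata` (condition x time point: median, q25, q75,
#'   n), `csmac_percent` (when available) and `experiment_medians` (when an
#'   `experiment` column is present: per condition/time mean and SEM of the
#'   per-experiment medians).
#' @export
summarize_experiments <- function(table) {
    stopifnot(is.data.frame(table), nrow(table) > 0,
              all(c("condition", "time_point", "value") %in% names(table)))
    key <- interaction(table$condition, table$time_point, drop = TRUE)
    strata <- do.call(rbind, lapply(split(table, key), function(sub) {
        q <- quantile(sub$value, c(0.25, 0.5, 0.75), na.rm = TRUE)
        data.frame(condition = sub$condition[1],
                   time_point = sub$time_point[1],
                   median = unname(q[2]), q25 = unname(q[1]),
                   q75 = unname(q[3]), n = nrow(sub))
    }))
    rownames(strata) <- NULL
    out <- list(strata = strata)
    if ("is_csmac" %in% names(table)) {
        out$csmac_percent <- do.call(rbind, lapply(split(table, key),
            function(sub) {
                ev <- sub$is_csmac[!is.na(sub$is_csmac)]
                data.frame(condition = sub$condition[1],
                           time_point = sub$time_point[1],
                           percent_csmac = if (length(ev))
                               100 * mean(ev) else NA_real_,
                           n = length(ev))
            }))
        rownames(out$csmac_percent) <- NULL
    }
    if ("experiment" %in% names(table)) {
        med <- aggregate(value ~ condition + time_point + experiment,
                         table, median)
        out$experiment_medians <- do.call(rbind, lapply(
            split(med, interaction(med$condition, med$time_point,
                                   drop = TRUE)),
            function(sub) data.frame(condition = sub$condition[1],
                                     time_point = sub$time_point[1],
                                     mean_of_medians = mean(sub$value),
                                     sem = if (nrow(sub) > 1) sem(sub$value)
                                           else NA_real_,
                                     n_experiments = nrow(sub))))
        rownames(out$experiment_medians) <- NULL
    }
    out
}
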