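#' Pipeline run configuration
#'
#' Bundles the acquisition calibration, stage parameters and master seed for
#' an end-to-end run. In `synthetic` mode the generator parameters define two
#' cohorts (control and knockdown) of synapse frames, flow movies and
#' spreading cells; in `real` mode, TIFF paths written by
#' [write_frame_tiff()] are quantified instead.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param pixel_size_um pixel size in micrometres (required).
#' @param frame_interval_s frame interval for time-lapse stages, default 2.
#' @param seed master seed; fanned out to per-stage child seeds via
#'   [derive_seed()] so stages can be re-run in isolation.
#' @param out_dir output directory for tables, summary JSON and log.
#' @param n_cells synapse frames per cohort (synthetic mode), default 40.
#' @param n_movies flow movies per cohort, default 12.
#' @param rolling_ball_px,min_area_um2,rout_q stage parameters.
#' @param control_v_nm_s,knockdown_v_nm_s median true flow speeds of the two
#'   cohorts, defaults 100 and 62 nm/s.
#' @param control_pcd79_per_ag,knockdown_pcd79_per_ag designed amplification
#'   ratios of the two cohorts, defaults 1 and 0.5.
#' @param input_frames character vector of TIFF paths (real mode).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       pixel_size_um = NULL, frame_interval_s = 2,
                       seed = 1, out_dir = tempfile("synapseQuant-run-"),
                       n_cells = 40, n_movies = 12,
                       rolling_ball_px = 10, min_area_um2 = 0.05,
                       rout_q = 0.01,
                       control_v_nm_s = 100, knockdown_v_nm_s = 62,
                       control_pcd79_per_ag = 1,
                       knockdown_pcd79_per_ag = 0.5,
                       input_frames = character(0)) {
    mode <- match.arg(mode)
    if (is.null(pixel_size_um))
        stop("missing calibration: 'pixel_size_um' is required")
    stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
    stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
    if (rolling_ball_px < 1) stop("'rolling_ball_px' must be >= 1")
    if (min_area_um2 < 0) stop("'min_area_um2' must be >= 0")
    if (rout_q <= 0 || rout_q >= 1) stop("'rout_q' must be in (0, 1)")
    structure(list(mode = mode, pixel_size_um = pixel_size_um,
                   frame_interval_s = frame_interval_s, seed = seed,
                   out_dir = out_dir, n_cells = n_cells,
                   n_movies = n_movies, rolling_ball_px = rolling_ball_px,
                   min_area_um2 = min_area_um2, rout_q = rout_q,
                   control_v_nm_s = control_v_nm_s,
                   knockdown_v_nm_s = knockdown_v_nm_s,
                   control_pcd79_per_ag = control_pcd79_per_ag,
                   knockdown_pcd79_per_ag = knockdown_pcd79_per_ag,
                   input_frames = input_frames),
              class = "run_config")
}

config_hash <- function(config) {
    # stable content hash of the scientific configuration (order-normalized;
    # the output location does not change what is computed)
    fields <- config[sort(setdiff(names(config), "out_dir"))]
    txt <- paste(vapply(fields, function(x)
        paste(format(x, digits = 15), collapse = ","), character(1)),
        collapse = ";")
    # polynomial rolling hash, kept in 31-bit double-safe range
    h <- 17
    for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}

write_table_csv <- function(df, path) {
    # fixed formatting so identical runs produce byte-identical files
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 10,
                                                   format = "g"))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
}

quantify_synthetic_cohort <- function(condition, config, camera) {
    seed0 <- derive_seed(config$seed, if (condition == "control") 100 else 200)
    ratio <- if (condition == "control") config$control_pcd79_per_ag
             else config$knockdown_pcd79_per_ag
    # knockdown cells coalesce less: more, smaller clusters
    n_range <- if (condition == "control") 1:3 else 2:6
    cells <- lapply(seq_len(config$n_cells), function(i) {
        sd_i <- derive_seed(seed0, i)
        n_cl <- with_seed(derive_seed(sd_i, 1),
                          sample(n_range, 1))
        truth <- random_synapse_truth(derive_seed(sd_i, 2),
                                      n_clusters = n_cl,
                                      pcd79_per_ag = ratio,
                                      pixel_size_um = config$pixel_size_um)
        sim <- simulate_synapse_frame(truth, camera, seed = derive_seed(sd_i, 3))
        q <- quantify_synapse_frame(sim$frame,
                                    rolling_ball_px = config$rolling_ball_px,
                                    min_area_um2 = config$min_area_um2)
        data.frame(cell_id = paste0(condition, "_", i),
                   condition = condition,
                   n_clusters_designed = nrow(truth$centers),
                   n_clusters_measured = nrow(q$clusters$Ag$clusters),
                   ag_clustered = q$clusters$Ag$total_clustered_intensity,
                   pcd79_clustered = q$clusters$pCD79$total_clustered_intensity,
                   is_csmac = q$csmac$is_csmac,
                   csmac_truth = truth$csmac_truth,
                   amplification = q$amplification)
    })
    do.call(rbind, cells)
}

flow_synthetic_cohort <- function(condition, config, camera) {
    seed0 <- derive_seed(config$seed, if (condition == "control") 300 else 400)
    v_med <- if (condition == "control") config$control_v_nm_s
             else config$knockdown_v_nm_s
    rows <- lapply(seq_len(config$n_movies), function(i) {
        sd_i <- derive_seed(seed0, i)
        # per-cell biological spread around the cohort median
        v_i <- with_seed(derive_seed(sd_i, 1),
                         v_med * exp(rnorm(1, 0, 0.15)))
        truth <- flow_movie_truth(v_true_nm_s = v_i,
                                  frame_interval_s = config$frame_interval_s,
                                  pixel_size_um = config$pixel_size_um)
        sim <- simulate_flow_movie(truth, camera, seed = derive_seed(sd_i, 2))
        kym <- extract_kymograph(sim$movie, c(4, 24, 124, 24), width_px = 3)
        data.frame(track_id = paste0(condition, "_", i),
                   condition = condition, v_true_nm_s = v_i,
                   velocity_nm_s = estimate_kymograph_velocity(kym))
    })
    do.call(rbind, rows)
}

#' Run the quantification pipeline end-to-end
#'
#' Executes the configured stages and writes an output bundle to
#' `config$out_dir`: per-cell cluster tables (`cells.csv`), flow-track
#' velocities (`tracks.csv`), a machine-readable summary (`summary.json`)
#' carrying provenance (config hash, seed, package version), and a plain-text
#' log (`run.log`). Re-running the same configuration reproduces
#' byte-identical tables.
#'
#' @param config a [run_config].
#' @return The summary list, invisibly; side effect is the written bundle.
#' @export
run_quantification <- function(config) {
    stopifnot(inherits(config, "run_config"))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    log_lines <- c(sprintf("synapseQuant %s | mode=%s | seed=%d | config=%s",
                           as.character(utils::packageVersion("synapseQuant")),
                           config$mode, config$seed, config_hash(config)))
    camera <- camera_model()
    if (config$mode == "synthetic") {
        cells <- rbind(quantify_synthetic_cohort("control", config, camera),
                       quantify_synthetic_cohort("knockdown", config, camera))
        tracks <- rbind(flow_synthetic_cohort("control", config, camera),
                        flow_synthetic_cohort("knockdown", config, camera))
        log_lines <- c(log_lines,
                       sprintf("clusters: %d cells quantified", nrow(cells)),
                       sprintf("flow: %d tracks measured", nrow(tracks)))
    } else {
        if (length(config$input_frames) == 0L)
            stop("real mode requires 'input_frames'")
        cells <- do.call(rbind, lapply(seq_along(config$input_frames),
            function(i) {
                fr <- read_frame_tiff(config$input_frames[i])
                q <- quantify_synapse_frame(
                    fr, channels = names(fr$channels)[1:min(2, length(fr$channels))],
                    rolling_ball_px = config$rolling_ball_px,
                    min_area_um2 = config$min_area_um2)
                data.frame(cell_id = basename(config$input_frames[i]),
                           condition = NA_character_,
                           n_clusters_designed = NA_integer_,
                           n_clusters_measured = nrow(q$clusters[[1]]$clusters),
                           ag_clustered = q$clusters[[1]]$total_clustered_intensity,
                           pcd79_clustered = if (length(q$clusters) > 1)
                               q$clusters[[2]]$total_clustered_intensity
                               else NA_real_,
                           is_csmac = q$csmac$is_csmac,
                           csmac_truth = NA,
                           amplification = q$amplification)
            }))
        tracks <- NULL
        log_lines <- c(log_lines,
                       sprintf("clusters: %d frames quantified", nrow(cells)))
    }
    write_table_csv(cells, file.path(config$out_dir, "cells.csv"))
    summary <- list(
        provenance = list(
            package = "synapseQuant",
            version = as.character(utils::packageVersion("synapseQuant")),
            seed = config$seed, config_hash = config_hash(config)),
        csmac_percent = lapply(split(cells, cells$condition), function(sub) {
            ev <- sub$is_csmac[!is.na(sub$is_csmac)]
            if (length(ev)) 100 * mean(ev) else NA_real_
        }),
        median_amplification = lapply(split(cells, cells$condition),
            function(sub) median(sub$amplification, na.rm = TRUE)))
    if (!is.null(tracks)) {
        write_table_csv(tracks, file.path(config$out_dir, "tracks.csv"))
        fs <- flow_summary(tracks)
        summary$flow <- list(
            medians = setNames(as.list(fs$medians$median_nm_s),
                               fs$medians$condition),
            percent_reduction = as.list(fs$percent_reduction))
        # per-condition clustered-pCD79 medians as percent of control
        amp_tab <- data.frame(experiment = "synthetic",
                              condition = cells$condition,
                              time_point = 30,
                              value = cells$pcd79_clustered)
        norm <- normalize_to_control(amp_tab)
        summary$pcd79_percent_of_control <- norm$percent_of_control[1]
    }
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
    invisible(summary)
}
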