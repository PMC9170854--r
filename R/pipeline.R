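#' Default run configuration
#'
#' Nested list of all tunables, reproducing the reference setup: 150 s
#' acquisition split into 14 subsets (RL 4-30 s), six spheres at a nominal
#' 10:1 sphere:background ratio, 4 mm voxels on a 144 x 144 x 48 grid,
#' F-18 decay, alpha = 0.05, target reconstruction length 150 s.
#'
#' @return named list with sections `phantom`, `grid`, `noise`, `schedule`,
#'   `analysis`, `io` and a `seed`.
#' @export
default_run_config <- function() {
  list(
    phantom = list(
      sphere_diameters_mm = c(10, 13, 17, 22, 28, 37),
      background_activity_kbq_ml = 2100,
      sphere_activity_kbq_ml = 20040,
      torso_semiaxes_mm = c(150, 110),
      lung_insert_radius_mm = 25,
      ring_radius_mm = 57.2
    ),
    grid = list(
      matrix_size = c(144L, 144L, 48L),
      voxel_size_mm = 4
    ),
    noise = list(
      sensitivity_counts_per_kbq_s = 2e-4,
      psf_fwhm_mm = 8,
      psf_apply = "post",
      half_life_s = 109.7 * 60
    ),
    schedule = list(
      total_s = 150,
      rl_s = c(4, 6, 8, 10, 12, 15, 17, 19, 20, 22, 24, 26, 28, 30)
    ),
    analysis = list(
      rl2_s = 150,
      alpha = 0.05,
      n_reference_frames = 0,
      supersample = 3L,
      detection = "geometry"
    ),
    io = list(
      write_frames = FALSE,
      frames_dir = NULL
    ),
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_run_config()] and validates
#' the result.
#'
#' @param path YAML config file; `NULL` returns the validated defaults.
#' @return a validated config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a config list to validate.
#' @export
validate_run_config <- function(config) {
  need <- c("phantom", "grid", "noise", "schedule", "analysis", "io", "seed")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop(sprintf("config lacks section(s): %s", paste(missing, collapse = ", ")))
  if (config$noise$sensitivity_counts_per_kbq_s <= 0)
    stop("noise$sensitivity_counts_per_kbq_s must be > 0")
  if (config$schedule$total_s <= 0)
    stop("schedule$total_s must be > 0")
  if (any(config$schedule$rl_s <= 0) ||
      any(config$schedule$rl_s > config$schedule$total_s))
    stop("schedule$rl_s values must lie in (0, total_s]")
  if (config$analysis$rl2_s <= 0) stop("analysis$rl2_s must be > 0")
  if (config$analysis$alpha <= 0 || config$analysis$alpha >= 1)
    stop("analysis$alpha must lie in (0, 1)")
  if (!config$analysis$detection %in% c("geometry", "auto"))
    stop("analysis$detection must be 'geometry' or 'auto'")
  config$seed <- as.integer(config$seed)
  config
}

# Simulate every frame of every schedule, compute metrics on the fly and
# discard the volume (full frame stacks are never held in memory).
stream_subset_metrics <- function(truth, schedules, noise, rois, seed,
                                  frames_dir = NULL) {
  grid <- truth$grid
  prep <- lapply(rois, function(roi)
    list(roi = roi, m3 = sphere_mask_3d(roi, grid),
         m2 = disk_mask_2d(roi, grid)))
  rows <- list()
  for (r in seq_along(schedules)) {
    sch <- schedules[[r]]
    for (k in seq_len(nrow(sch$intervals))) {
      img <- simulate_frame(truth, sch$intervals[k, 1], sch$rl_s, noise,
                            seed = frame_seed(seed, r, k))
      if (!is.null(frames_dir)) {
        dir.create(frames_dir, recursive = TRUE, showWarnings = FALSE)
        write_one_frame(img, file.path(
          frames_dir, sprintf("rl%s_frame%03d", as.character(sch$rl_s), k)),
          seed = seed)
      }
      for (p in prep) {
        v2 <- mask_values(img, p$m2)
        v3 <- mask_values(img, p$m3)
        argmax <- p$m3$indices[which.max(v3), ]
        pk <- mean(mask_values(img, peak_mask(argmax, grid)))
        rows[[length(rows) + 1]] <- data.frame(
          sphere_id = p$roi$sphere_id, metric = suv_metric_names,
          frame_index = k, rl_s = sch$rl_s,
          value_kbq_ml = c(max(v2), max(v3), mean(v2), mean(v3), pk),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full estimation pipeline
#'
#' Simulates (or loads) the frames, detects the spheres once on a reference
#' image, extracts the five SUV metrics from every frame, computes
#' per-subset coefficients of variation, extrapolates them to the target
#' reconstruction length, cross-estimates across subsets, and runs the
#' normality checks and pairwise Welch comparisons. All tables are written
#' as CSV, the test report and run manifest as JSON. Deterministic for a
#' fixed config and seed.
#'
#' @param config a config list (see [default_run_config()]).
#' @param out_dir output directory for artifacts.
#' @param frames optional pre-loaded frames (named list RL -> volumes, e.g.
#'   from [read_frames()]); when supplied the simulator is bypassed and
#'   frame metadata drives the analysis.
#' @return invisibly, a list with the computed tables and artifact paths.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, frames = NULL) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  seed <- config$seed

  geom <- build_phantom_geometry(config$phantom)
  grid <- grid_spec(config$grid$matrix_size, config$grid$voxel_size_mm)
  noise <- do.call(noise_model, config$noise)
  schedules <- default_schedules(config$schedule$total_s, config$schedule$rl_s)
  truth <- rasterize_activity(geom, grid, config$analysis$supersample)

  rois <- if (config$analysis$detection == "geometry")
    detect_spheres(truth, geom_hint = geom)
  else
    detect_spheres(truth, expected_diameters_mm = geom$sphere_diameters_mm)

  if (is.null(frames)) {
    frames_dir <- if (isTRUE(config$io$write_frames))
      config$io$frames_dir %||% file.path(out_dir, "frames")
    records <- stream_subset_metrics(truth, schedules, noise, rois, seed,
                                     frames_dir)
  } else {
    records <- compute_all_metrics(frames, rois)
  }

  cov_tab <- cov_by_subset(records)
  agg <- estimate_at_full_length(records, schedules, config$analysis$rl2_s)
  cross <- cross_estimate_matrix(records, schedules)
  comparisons <- compare_table(agg, config$analysis$alpha)
  recovery <- recovery_curve(records, geom)

  # KS normality of every subset population, raw and log
  ks_rows <- list()
  key <- interaction(records$metric, records$sphere_id, records$rl_s,
                     drop = TRUE)
  for (p in split(records, key)) {
    if (nrow(p) < 5L) next
    for (tr in c("raw", "log")) {
      ks <- ks_normality(p$value_kbq_ml, transform = tr,
                         alpha = config$analysis$alpha)
      ks_rows[[length(ks_rows) + 1]] <- data.frame(
        metric = p$metric[1], sphere_id = p$sphere_id[1], rl_s = p$rl_s[1],
        transform = tr, statistic = ks$statistic, p_value = ks$p_value,
        reject = ks$reject, stringsAsFactors = FALSE)
    }
  }
  ks_tab <- do.call(rbind, ks_rows)

  paths <- list(
    roi = file.path(out_dir, "roi.csv"),
    metrics = file.path(out_dir, "metrics.csv"),
    cov = file.path(out_dir, "cov_by_subset.csv"),
    estimates = file.path(out_dir, "estimates_full_length.csv"),
    summary = file.path(out_dir, "estimates_summary.csv"),
    cross = file.path(out_dir, "cross_estimates.csv"),
    table1 = file.path(out_dir, "summary_table.csv"),
    recovery = file.path(out_dir, "recovery_curve.csv"),
    comparisons = file.path(out_dir, "comparisons.csv"),
    report = file.path(out_dir, "test_report.json"),
    manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(roi_table(rois), paths$roi, row.names = FALSE)
  utils::write.csv(records, paths$metrics, row.names = FALSE)
  utils::write.csv(cov_tab, paths$cov, row.names = FALSE)
  utils::write.csv(agg$estimates, paths$estimates, row.names = FALSE)
  utils::write.csv(agg$summary, paths$summary, row.names = FALSE)
  utils::write.csv(cross$summary, paths$cross, row.names = FALSE)
  utils::write.csv(summary_table(agg$summary), paths$table1, row.names = FALSE)
  utils::write.csv(recovery, paths$recovery, row.names = FALSE)
  utils::write.csv(comparisons, paths$comparisons, row.names = FALSE)
  jsonlite::write_json(
    list(ks_normality = ks_tab, comparisons = comparisons),
    paths$report, dataframe = "rows", digits = NA)
  jsonlite::write_json(
    list(config = config, seed = seed,
         package_version = as.character(utils::packageVersion("suvvar")),
         n_frames = nrow(unique(records[, c("rl_s", "frame_index")])),
         n_records = nrow(records),
         sphere_to_background_ratio = sphere_to_background_ratio(geom),
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    paths$manifest, auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(geom = geom, grid = grid, rois = rois, records = records,
                 cov = cov_tab, aggregate = agg, cross = cross,
                 comparisons = comparisons, ks = ks_tab,
                 recovery = recovery, paths = paths))
}

#' Metrics-by-spheres summary table
#'
#' Reshapes the per-(metric, sphere) aggregate into the classic wide layout:
#' one row per metric, one column per sphere, cells "mean +/- SD %".
#'
#' @param summary the `summary` data.frame from [estimate_at_full_length()].
#' @return wide data.frame of formatted estimates.
#' @export
summary_table <- function(summary) {
  spheres <- unique(summary$sphere_id)
  spheres <- spheres[order(as.numeric(sub("mm$", "", spheres)))]
  metrics <- sort(unique(summary$metric))
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (s in spheres) {
    cell <- vapply(metrics, function(m) {
      row <- summary[summary$metric == m & summary$sphere_id == s, ]
      sprintf("%.1f +/- %.1f%%", row$mean_estimate, row$sd_of_estimates)
    }, "")
    out[[paste0("d_", s)]] <- cell
  }
  out
}

#' Recovery curve
#'
#' Mean and SD of each metric across the frames of each subset, per sphere,
#' plus the recovery coefficient (measured mean / true sphere
#' concentration). With a single frame in a subset the SD is reported as 0
#' with a warning.
#'
#' @param records data.frame from [compute_all_metrics()].
#' @param geom the phantom geometry supplying the true concentration.
#' @return data.frame per (metric, rl_s, sphere): n, mean, sd, recovery.
#' @export
recovery_curve <- function(records, geom) {
  key <- interaction(records$metric, records$sphere_id, records$rl_s,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(p) {
    s <- if (nrow(p) > 1L) stats::sd(p$value_kbq_ml) else {
      warning(sprintf("single frame for %s/%s at RL=%g s: SD reported as 0",
                      p$metric[1], p$sphere_id[1], p$rl_s[1]))
      0
    }
    data.frame(metric = p$metric[1], sphere_id = p$sphere_id[1],
               rl_s = p$rl_s[1], n_frames = nrow(p),
               mean_value = mean(p$value_kbq_ml), sd_value = s,
               recovery = mean(p$value_kbq_ml) / geom$sphere_activity_kbq_ml,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$metric, out$rl_s,
                   as.numeric(sub("mm$", "", out$sphere_id))), ]
  rownames(out) <- NULL
  out
}
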