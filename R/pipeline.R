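#' Angiographic metrics for every cohort visit
#'
#' For each (animal, eye, week): vessel index of the SVP and DCP angiograms
#' against the eye's ROI set (median prefilter by default) and the sharpness
#' index of the choroidal angiogram.
#'
#' @param cohort Cohort tibble (see [read_cohort()]); must carry `roi_path`
#'   or `rois_dir` must point at `<animal>_<eye>.json` files.
#' @param rois_dir Optional directory of ROI JSON files.
#' @param prefilter Apply the 3x3 median prefilter before the vessel index.
#' @param per_pixel_sharpness Report the per-interior-pixel sharpness
#'   (default) rather than the raw sum.
#' @param pitch_config Pixel pitches for image reading.
#' @return Tidy tibble: `animal_id`, `eye`, `group`, `week`, `plexus`,
#'   `metric`, `value`.
#' @export
cohort_metrics <- function(cohort, rois_dir = NULL, prefilter = TRUE,
                           per_pixel_sharpness = TRUE,
                           pitch_config = pitch_defaults()) {
  cohort <- validate_cohort(cohort)
  roi_cache <- list()
  purrr::map_dfr(seq_len(nrow(cohort)), function(r) {
    row <- cohort[r, ]
    roi_path <- if (!is.null(rois_dir)) {
      file.path(rois_dir, paste0(row$animal_id, "_", row$eye, ".json"))
    } else row$roi_path
    if (is.null(roi_path) || is.na(roi_path) || !file.exists(roi_path)) {
      abort(sprintf("ROI file not found for %s/%s: '%s'.", row$animal_id, row$eye, roi_path))
    }
    if (is.null(roi_cache[[roi_path]])) roi_cache[[roi_path]] <<- read_roi_set(roi_path)
    roi <- roi_cache[[roi_path]]
    svp <- read_image(row$svp_path, pitch_config, plexus = "SVP")
    dcp <- read_image(row$dcp_path, pitch_config, plexus = "DCP")
    cho <- read_image(row$choroid_path, pitch_config, plexus = "choroid")
    sh <- choroid_sharpness(cho)
    tibble::tibble(
      animal_id = row$animal_id, eye = row$eye, group = row$group, week = row$week,
      plexus = c("SVP", "DCP", "choroid"),
      metric = c("vessel_index", "vessel_index", "sharpness"),
      value = c(vessel_index(svp, roi, prefilter)$value,
                vessel_index(dcp, roi, prefilter)$value,
                if (per_pixel_sharpness) sh$per_pixel_value else sh$value)
    )
  })
}

#' Layer thicknesses for every cohort visit
#'
#' For each visit: locate the ONH on the structural enface, map it into
#' B-scan stack coordinates, select measurement sites at the requested
#' slow-axis distances (two columns per B-scan), detect boundaries at each
#' site, and average valid sites into one thickness record. Visits where no
#' site yields a valid profile are dropped with a warning.
#'
#' @param cohort Cohort tibble with `structural_path` and `bscan_stack_path`.
#' @param distances_mm Slow-axis distances of the measurement B-scans.
#' @param window_px Column band half-width for boundary detection.
#' @param field_mm Physical enface extent `c(width_mm, height_mm)`.
#' @param pitch_z_um Axial pitch of the B-scans.
#' @return Tibble: `animal_id`, `eye`, `group`, `week`, `gcc_um`,
#'   `inl_onl_um`, `pr_debris_um`, `trt_um`, `n_sites`.
#' @export
cohort_thickness <- function(cohort, distances_mm = c(1, 2), window_px = 7L,
                             field_mm = c(3.9, 2.4), pitch_z_um = 1.95) {
  cohort <- validate_cohort(cohort)
  purrr::map_dfr(seq_len(nrow(cohort)), function(r) {
    row <- cohort[r, ]
    pc <- pitch_defaults(); pc$pitch_z_um <- pitch_z_um
    structural <- read_image(row$structural_path, pc, kind = "enface_structural")
    onh <- locate_onh(structural)
    stack <- read_bscan_stack(row$bscan_stack_path, pc)
    n_pages <- length(stack)
    wpx <- stack[[1]]$width_px
    pitch_lat <- field_mm[1] * 1000 / wpx
    pitch_slow <- field_mm[2] * 1000 / n_pages
    onh_b <- onh["y_px"] * (field_mm[2] * 1000 / structural$height_px) /
      pitch_slow + 0.5
    onh_c <- onh["x_px"] / structural$width_px * wpx
    sites <- select_measurement_sites(c(onh_c, onh_b), c(pitch_lat, pitch_slow),
                                      n_bscans = n_pages, width_px = wpx,
                                      distances_mm = distances_mm)
    profiles <- purrr::map(seq_len(nrow(sites)), function(s) {
      detect_boundaries(stack[[sites$bscan_index[s]]], sites$column[s], window_px)
    })
    rec <- tryCatch(layer_thicknesses(profiles, pitch_z_um), error = function(e) NULL)
    if (is.null(rec)) {
      warn(sprintf("No valid boundary profiles for %s/%s week %s; visit dropped.",
                   row$animal_id, row$eye, row$week))
      return(tibble::tibble())
    }
    dplyr::bind_cols(
      tibble::tibble(animal_id = row$animal_id, eye = row$eye,
                     group = row$group, week = row$week),
      rec
    )
  })
}

#' Longitudinal statistics for every metric
#'
#' For the RCS follow-up arm of each metric: the two-way repeated-measures
#' ANOVA (Greenhouse-Geisser corrected), Bonferroni-adjusted consecutive-week
#' contrasts, and the linear trend contrast. For the cross-sectional control
#' arm: one-way ANOVA across age groups (eyes averaged per animal) with
#' Bonferroni-corrected pairwise comparisons.
#'
#' @param long Tidy tibble with columns `metric`, `group`, `animal_id`,
#'   `eye`, `week`, `value`.
#' @return Tibble: `metric`, `arm`, `effect`, `estimate`, `statistic`, `df1`,
#'   `df2`, `epsilon_gg`, `p_raw`, `p_adjusted`, `family_size`.
#' @export
longitudinal_stats <- function(long) {
  long <- tibble::as_tibble(long)
  purrr::map_dfr(unique(long$metric), function(met) {
    d <- dplyr::filter(long, .data$metric == met)
    out <- list()
    rcs <- dplyr::filter(d, .data$group == "RCS")
    if (length(unique(rcs$week)) >= 2 && length(unique(rcs$animal_id)) >= 3) {
      an <- rm_anova_week(rcs)
      out$anova <- tibble::tibble(
        metric = met, arm = "RCS", effect = an$effect, estimate = NA_real_,
        statistic = an$statistic, df1 = an$df1, df2 = an$df2,
        epsilon_gg = an$epsilon_gg, p_raw = an$p_uncorrected,
        p_adjusted = an$p_gg, family_size = NA_integer_
      )
      cc <- consecutive_contrasts(rcs)
      out$cc <- tibble::tibble(
        metric = met, arm = "RCS", effect = cc$label, estimate = cc$estimate,
        statistic = cc$statistic, df1 = cc$df, df2 = NA_real_,
        epsilon_gg = NA_real_, p_raw = cc$p_raw, p_adjusted = cc$p_bonferroni,
        family_size = cc$family_size
      )
      tr <- linear_trend_contrast(rcs)
      out$tr <- tibble::tibble(
        metric = met, arm = "RCS", effect = "linear trend", estimate = tr$estimate,
        statistic = tr$statistic, df1 = tr$df, df2 = NA_real_,
        epsilon_gg = NA_real_, p_raw = tr$p_raw, p_adjusted = tr$p_raw,
        family_size = 1L
      )
    }
    ctl <- dplyr::filter(d, .data$group == "control")
    if (nrow(ctl) > 0 && length(unique(ctl$week)) >= 2) {
      ea <- eye_averaged(ctl)
      ow <- oneway_anova(tibble::tibble(group = as.character(ea$week), value = ea$value))
      out$ctl <- dplyr::bind_rows(
        tibble::tibble(metric = met, arm = "control", effect = "age group",
                       estimate = NA_real_, statistic = ow$anova$statistic,
                       df1 = ow$anova$df1, df2 = ow$anova$df2, epsilon_gg = NA_real_,
                       p_raw = ow$anova$p_value, p_adjusted = ow$anova$p_value,
                       family_size = NA_integer_),
        tibble::tibble(metric = met, arm = "control", effect = ow$contrasts$label,
                       estimate = ow$contrasts$estimate,
                       statistic = ow$contrasts$statistic,
                       df1 = ow$contrasts$df, df2 = NA_real_, epsilon_gg = NA_real_,
                       p_raw = ow$contrasts$p_raw,
                       p_adjusted = ow$contrasts$p_bonferroni,
                       family_size = ow$contrasts$family_size)
      )
    }
    dplyr::bind_rows(out)
  })
}

thickness_to_long <- function(th) {
  th |>
    tidyr::pivot_longer(c("gcc_um", "inl_onl_um", "pr_debris_um", "trt_um"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("metric", "group", "animal_id", "eye", "week", "value")
}

metrics_to_long <- function(mt) {
  mt |>
    dplyr::mutate(metric = paste(.data$plexus, .data$metric, sep = "_")) |>
    dplyr::select("metric", "group", "animal_id", "eye", "week", "value")
}

summarise_run <- function(stats_tbl, alpha = 0.05) {
  lines <- c("# Pipeline summary", "")
  for (met in unique(stats_tbl$metric)) {
    d <- dplyr::filter(stats_tbl, .data$metric == met, .data$arm == "RCS")
    if (nrow(d) == 0) next
    wk <- dplyr::filter(d, .data$effect == "week")
    tr <- dplyr::filter(d, .data$effect == "linear trend")
    cc <- dplyr::filter(d, grepl("^wk", .data$effect))
    sig_cc <- cc$effect[cc$p_adjusted < alpha]
    lines <- c(lines, sprintf("## %s", met),
      sprintf("- week effect (GG-corrected): F = %.3f, p = %.4g %s",
              wk$statistic, wk$p_adjusted,
              ifelse(wk$p_adjusted < alpha, "(significant)", "(not significant)")),
      sprintf("- linear trend: %s, p = %.4g %s",
              ifelse(tr$estimate < 0, "decreasing", "increasing"), tr$p_adjusted,
              ifelse(tr$p_adjusted < alpha, "(significant)", "(not significant)")),
      sprintf("- consecutive intervals significant at Bonferroni-adjusted %.2f (family %d): %s",
              alpha, cc$family_size[1],
              if (length(sig_cc)) paste(sig_cc, collapse = ", ") else "none"),
      "")
  }
  lines
}

#' Run the full pipeline: simulate, metrics, thickness, statistics
#'
#' Orchestrates the stages into one reproducible run directory containing
#' `metrics.csv`, `thickness.csv`, `stats_report.csv`, `summary.md`, a config
#' snapshot (`config.yaml`) and a run log. Any stage failure aborts with the
#' stage name. Outputs are pure functions of (config, seed): a rerun with the
#' same config and seed reproduces the CSVs byte for byte.
#'
#' @param config A named list (or path to a YAML file) with optional entries:
#'   `seed`, `out_dir`, `run_name`, `cohort_csv` (skip simulation and use an
#'   existing cohort), `simulate` (overrides passed to
#'   [degeneration_params()]), `write_bscans`, `stages` (subset of
#'   `c("thickness", "stats")` to run after metrics), `prefilter`,
#'   `per_pixel_sharpness`, `distances_mm`, `window_px`, `alpha`, `force`.
#' @return Invisibly, a list with the run directory and the stage tibbles.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(list(
    seed = 20200624, out_dir = tempfile("octadegen_run_"), run_name = NULL,
    cohort_csv = NULL, simulate = list(), write_bscans = TRUE,
    stages = c("thickness", "stats"), prefilter = TRUE,
    per_pixel_sharpness = TRUE, distances_mm = c(1, 2), window_px = 7L,
    alpha = 0.05, force = FALSE
  ), config)
  run_dir <- if (is.null(cfg$run_name)) cfg$out_dir else file.path(cfg$out_dir, cfg$run_name)
  if (dir.exists(run_dir) && length(dir(run_dir)) > 0 && !cfg$force) {
    abort(sprintf("Run directory '%s' is not empty (set force = TRUE).", run_dir))
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "run.log")
  log_lines <- character()
  stage <- function(name, code) {
    withCallingHandlers(
      tryCatch(code, error = function(e) {
        abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
      }),
      warning = function(w) {
        log_lines <<- c(log_lines, sprintf("[%s] warning: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        log_lines <<- c(log_lines, sprintf("[%s] %s", name, trimws(conditionMessage(m))))
        invokeRestart("muffleMessage")
      }
    )
  }

  params <- do.call(degeneration_params, modifyList(cfg$simulate, list(seed = cfg$seed)))
  cohort <- stage("simulate", {
    if (!is.null(cfg$cohort_csv)) {
      read_cohort(cfg$cohort_csv)
    } else {
      simulate_cohort(params, file.path(run_dir, "data"), force = cfg$force,
                      write_bscans = cfg$write_bscans)$cohort
    }
  })

  metrics <- stage("metrics", {
    cohort_metrics(cohort, prefilter = cfg$prefilter,
                   per_pixel_sharpness = cfg$per_pixel_sharpness)
  })
  write_table(metrics, file.path(run_dir, "metrics.csv"))

  thickness <- NULL
  if ("thickness" %in% cfg$stages) {
    thickness <- stage("thickness", {
      cohort_thickness(cohort, distances_mm = cfg$distances_mm,
                       window_px = cfg$window_px,
                       field_mm = params$field_mm,
                       pitch_z_um = params$bscan$pitch_z_um)
    })
    write_table(thickness, file.path(run_dir, "thickness.csv"))
  }

  stats_tbl <- NULL
  if ("stats" %in% cfg$stages) {
    stats_tbl <- stage("stats", {
      long <- metrics_to_long(metrics)
      if (!is.null(thickness) && nrow(thickness) > 0) {
        long <- dplyr::bind_rows(long, thickness_to_long(thickness))
      }
      longitudinal_stats(long)
    })
    write_table(stats_tbl, file.path(run_dir, "stats_report.csv"))
    writeLines(summarise_run(stats_tbl, cfg$alpha), file.path(run_dir, "summary.md"))
  }

  yaml::write_yaml(cfg[setdiff(names(cfg), "force")], file.path(run_dir, "config.yaml"))
  writeLines(log_lines, log_path)
  invisible(list(dir = run_dir, cohort = cohort, metrics = metrics,
                 thickness = thickness, stats = stats_tbl, params = params))
}
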