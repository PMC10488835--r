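# End-to-end orchestration: simulate -> analyze -> stats. Thin wrappers
# over the module functions, with a config object holding the study
# defaults (5 mm circles, >6 m/s outlier rule, 90 bpm reference,
# <1.5 m/s correlation cap) and machine-readable run logs.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with the study defaults:
#' 5 mm circle radius and spacing, strict >6 m/s velocity-outlier
#' threshold, 90 bpm reference heart rate for EMMs, 1.5 m/s cap for the
#' slow-conduction correlation, strict wall rule and area-weighted
#' voltage aggregation.
#'
#' @param radius_mm circle radius (mm).
#' @param spacing_mm center spacing (mm).
#' @param cv_outlier_threshold outlier threshold (m/s, strict >).
#' @param reference_heart_rate EMM reference heart rate (bpm).
#' @param cv_correlation_cap cap for the slow-velocity correlation (m/s).
#' @param wall_rule `"strict"` or `"majority"`.
#' @param voltage_aggregation `"area_weighted"` or `"vertex_mean"`.
#' @param seed integer seed for center placement.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(radius_mm = 5, spacing_mm = 5,
                            cv_outlier_threshold = 6,
                            reference_heart_rate = 90,
                            cv_correlation_cap = 1.5,
                            wall_rule = c("strict", "majority"),
                            voltage_aggregation = c("area_weighted",
                                                    "vertex_mean"),
                            seed = 1L) {
  wall_rule <- match.arg(wall_rule)
  voltage_aggregation <- match.arg(voltage_aggregation)
  stopifnot(radius_mm > 0, spacing_mm > 0, cv_outlier_threshold > 0,
            reference_heart_rate > 0, cv_correlation_cap > 0)
  structure(list(radius_mm = radius_mm, spacing_mm = spacing_mm,
                 cv_outlier_threshold = cv_outlier_threshold,
                 reference_heart_rate = reference_heart_rate,
                 cv_correlation_cap = cv_correlation_cap,
                 wall_rule = wall_rule,
                 voltage_aggregation = voltage_aggregation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Simulate a study to disk
#'
#' Generates a multi-animal synthetic study ([generate_study()]) and
#' writes one map file per design row plus `truth_table.csv` and a JSON
#' run log. Rerunning with the same seed reproduces identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param design study design tibble; defaults to the 21-map reference
#'   layout ([reference_map_design()]).
#' @param format on-disk map format, `"vtk"` or `"bundle"`.
#' @param seed integer seed.
#' @param ... passed to [generate_study()].
#' @return invisibly, the truth table with a `file` column.
#' @export
pipeline_simulate <- function(out_dir, design = reference_map_design(),
                              format = c("vtk", "bundle"), seed = 1L, ...) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(design = design, seed = seed, ...)
  files <- character(length(study$maps))
  for (i in seq_along(study$maps)) {
    id <- names(study$maps)[i]
    files[i] <- file.path(out_dir, if (format == "vtk")
      paste0(id, ".vtk") else id)
    write_map(study$maps[[i]], files[i], format = format)
  }
  truth <- mutate(study$truth, file = files)
  readr::write_csv(truth, file.path(out_dir, "truth_table.csv"))
  write_run_log(file.path(out_dir, "simulate_log.json"),
                list(command = "simulate", seed = seed,
                     n_maps = length(files), format = format))
  invisible(truth)
}

#' Analyze one map
#'
#' Covers the map with circles, assigns walls, measures CV/VA per circle
#' and applies the outlier filter.
#'
#' @param map a [surface_map()].
#' @param config a [pipeline_config()].
#' @return list with `measurements` (tibble), `patches` (tibble) and
#'   `summary` (one-row tibble: point/circle counts, mean circle area,
#'   mean points per circle, resolution in points/mm^2, volume in mL).
#' @export
analyze_map <- function(map, config = pipeline_config()) {
  patches <- cover_map(map, radius = config$radius_mm,
                       spacing = config$spacing_mm, seed = config$seed,
                       voltage_aggregation = config$voltage_aggregation)
  if (any(map$wall_label != "unlabeled"))
    patches <- assign_walls(patches, map, rule = config$wall_rule)
  meas <- measure_circles(patches, map$meta)
  meas <- apply_outlier_filter(meas, threshold = config$cv_outlier_threshold)
  vol <- suppressWarnings(enclosed_volume(map))
  mean_area <- mean(patches$area_mm2)
  mean_pts <- mean(patches$n_points)
  summary <- tibble(
    map_id = as.character(map$meta$map_id %||% NA_character_),
    chamber = as.character(map$meta$chamber %||% NA_character_),
    n_points = nrow(map$vertices),
    n_circles = nrow(patches),
    mean_circle_area_mm2 = mean_area,
    mean_points_per_circle = mean_pts,
    resolution_points_per_mm2 = mean_pts / mean_area,
    volume_ml = as.numeric(vol)
  )
  list(measurements = meas, patches = patches, summary = summary)
}

#' Analyze a set of maps
#'
#' Runs [analyze_map()] per map and binds the results.
#'
#' @param maps named list of [surface_map()] objects, or a character
#'   vector of file paths readable by [read_map()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: writes `measurements.csv`,
#'   `map_summaries.csv`, `exclusions.csv` and a JSON run log.
#' @return list with `measurements` (all maps), `summaries` (one row per
#'   map) and `exclusions` (outlier/zero-dt log).
#' @export
pipeline_analyze <- function(maps, config = pipeline_config(),
                             out_dir = NULL) {
  if (is.character(maps)) {
    paths <- maps
    maps <- lapply(paths, function(p)
      tryCatch(read_map(p),
               error = function(e) abort(sprintf("%s: %s", p, conditionMessage(e)))))
  }
  if (length(maps) == 0) abort("no maps to analyze")
  res <- lapply(maps, analyze_map, config = config)
  measurements <- bind_rows(lapply(res, `[[`, "measurements"))
  summaries <- bind_rows(lapply(res, `[[`, "summary"))
  exclusions <- measurements %>%
    group_by(.data$map_id) %>%
    summarise(n_circles = dplyr::n(),
              n_cv_outlier = sum(.data$exclusion_reason == "cv_outlier"),
              n_zero_dt = sum(.data$exclusion_reason == "zero_dt"),
              .groups = "drop")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(measurements, file.path(out_dir, "measurements.csv"))
    readr::write_csv(summaries, file.path(out_dir, "map_summaries.csv"))
    readr::write_csv(exclusions, file.path(out_dir, "exclusions.csv"))
    write_run_log(file.path(out_dir, "analyze_log.json"),
                  list(command = "analyze", config = unclass(config),
                       n_maps = nrow(summaries),
                       n_circles = nrow(measurements),
                       n_excluded = sum(!measurements$valid)))
  }
  list(measurements = measurements, summaries = summaries,
       exclusions = exclusions)
}

#' Run the statistical comparison
#'
#' Fits the chamber mixed models for log CV and VA, computes EMMs at the
#' reference heart rate, Tukey-adjusted all-pairs contrasts, and the
#' correlation analyses (overall, per chamber, per chamber below the
#' slow-velocity cap).
#'
#' @param measurements measurement tibble (outlier filter already applied
#'   by [pipeline_analyze()]; reapplied defensively here).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for JSON + text reports.
#' @return list with per-response elements (`log_cv`, `va`): fitted
#'   `model`, `emm`, `contrasts`; plus `correlations`.
#' @export
pipeline_stats <- function(measurements, config = pipeline_config(),
                           out_dir = NULL) {
  measurements <- apply_outlier_filter(measurements,
                                       threshold = config$cv_outlier_threshold)
  out <- list()
  for (resp in c("log_cv", "va")) {
    m <- fit_mixed_model(measurements, response = resp)
    out[[resp]] <- list(
      model = m,
      emm = emm_at(m, heart_rate = config$reference_heart_rate),
      contrasts = pairwise_contrasts(
        m, which = "all_pairs", adjust = "tukey",
        heart_rate = config$reference_heart_rate)
    )
  }
  corr <- bind_rows(
    pearson_correlation(measurements, "overall"),
    pearson_correlation(measurements, "per_chamber"),
    mutate(pearson_correlation(measurements, "per_chamber",
                               cv_cap = config$cv_correlation_cap),
           scope = sprintf("per_chamber_cv<%g", config$cv_correlation_cap))
  )
  out$correlations <- corr
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(
      config = unclass(config),
      log_cv = list(coefficients = tidy(out$log_cv$model),
                    variance = glance(out$log_cv$model),
                    emm = out$log_cv$emm,
                    contrasts = out$log_cv$contrasts),
      va = list(coefficients = tidy(out$va$model),
                variance = glance(out$va$model),
                emm = out$va$emm,
                contrasts = out$va$contrasts),
      correlations = corr
    )
    jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(render_stats_text(out), file.path(out_dir, "stats_report.txt"))
  }
  out
}

# "estimate +/- SE" text report, the field's reporting convention.
render_stats_text <- function(stats) {
  fmt <- function(e, s) sprintf("%.3g ± %.2g", e, s)
  lines <- c("Chamber comparison (EMMs at reference heart rate)", "")
  for (resp in c("log_cv", "va")) {
    unit <- if (resp == "log_cv") "m/s" else "mV"
    lines <- c(lines, sprintf("-- %s --",
                              if (resp == "log_cv") "conduction velocity"
                              else "voltage amplitude"))
    e <- stats[[resp]]$emm
    lines <- c(lines, sprintf("  %s: %s %s", e$chamber,
                              fmt(e$estimate, e$se), unit))
    ct <- stats[[resp]]$contrasts
    est <- ct[[2]]
    lines <- c(lines, "  pairwise (Tukey):",
               sprintf("    %s: %s%s, p = %.3g", ct$contrast,
                       if (resp == "log_cv") "×" else "Δ ",
                       fmt(est, ct$se), ct$p_value), "")
  }
  corr <- stats$correlations
  lines <- c(lines, "-- cv/va correlations --",
             sprintf("  %s%s: r(%d) = %.2f, p = %.3g [%s]", corr$scope,
                     ifelse(is.na(corr$chamber), "",
                            paste0(" ", corr$chamber)),
                     corr$df, corr$r, corr$p_value, corr$interpretation))
  lines
}

write_run_log <- function(path, entries) {
  entries$timestamp <- format(Sys.time(), tz = "UTC")
  entries$package_version <- as.character(utils::packageVersion("eamap"))
  entries$r_version <- R.version.string
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Aggregate a map inventory
#'
#' Study-level aggregates of a map inventory table (one row per map):
#' map count, mean measurement points per map, mean circles per whole
#' map, and their standard errors — the headline summary of a mapping
#' study ("21 maps of 5632 +/- 295 points with 131 +/- 8 circles").
#'
#' @param inventory tibble as from [reference_map_inventory()], with
#'   columns `n_points` and `circles_whole_map`.
#' @return one-row tibble: `n_maps`, `mean_points`, `sem_points`,
#'   `mean_circles`, `sem_circles`.
#' @export
summarize_map_inventory <- function(inventory) {
  n <- nrow(inventory)
  if (n == 0) abort("empty inventory")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  tibble(n_maps = n,
         mean_points = mean(inventory$n_points),
         sem_points = sem(inventory$n_points),
         mean_circles = mean(inventory$circles_whole_map),
         sem_circles = sem(inventory$circles_whole_map))
}
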