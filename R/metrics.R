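# Per-circle conduction velocity and voltage amplitude.
#
# The local conduction velocity of a circular patch is the effective circle
# diameter -- recovered from the measured (clipped) patch area A as
# 2*sqrt(A/pi) -- divided by the activation spread dt = t_last - t_first
# across the patch. In the fixed mm/ms unit system this is numerically
# m/s. For a planar wavefront crossing a full circular patch the first and
# last activations sit at opposite ends of the diameter along the
# propagation direction, so the estimator is exact in the continuum limit.

#' Circle-based local conduction velocity
#'
#' `cv = 2 * sqrt(area / pi) / dt`, in mm/ms (numerically equal to m/s).
#' The area is the actual clipped patch area, not the nominal `pi r^2`, so
#' circles truncated by cutouts or map borders use their effective
#' diameter. `dt = 0` yields `NA` (the circle is excluded downstream with
#' reason `zero_dt`), never an infinite velocity.
#'
#' @param area patch area in mm^2 (> 0); vectorised.
#' @param dt activation spread `t_last - t_first` in ms (>= 0); vectorised.
#' @return conduction velocity in m/s; `NA` where `dt == 0`.
#' @examples
#' conduction_velocity(25 * pi, 10)  # diameter 10 mm over 10 ms -> 1 m/s
#' @export
conduction_velocity <- function(area, dt) {
  if (any(area <= 0, na.rm = TRUE)) abort("area must be > 0 (mm^2)")
  if (any(dt < 0, na.rm = TRUE)) abort("dt must be >= 0 (ms)")
  out <- 2 * sqrt(area / pi) / dt
  out[dt == 0] <- NA_real_
  out
}

#' Assemble per-circle measurements from patches
#'
#' Turns a patch table from [cover_map()] into the analysis table: one row
#' per non-empty circle with conduction velocity, mean voltage amplitude
#' and the map metadata copied through. Circles with zero activation
#' spread are marked invalid with reason `zero_dt`; the >6 m/s outlier
#' rule is applied separately by [apply_outlier_filter()].
#'
#' @param patches tibble from [cover_map()] (optionally after
#'   [assign_walls()]).
#' @param meta named list of map metadata (`map_id`, `animal_id`,
#'   `chamber`, `heart_rate`, `sex`), typically `map$meta`.
#' @return a tibble with columns `map_id`, `animal_id`, `chamber`,
#'   `wall_assignment`, `heart_rate`, `sex`, `circle_id`, `area_mm2`,
#'   `n_points`, `cv`, `va`, `valid`, `exclusion_reason`.
#' @export
measure_circles <- function(patches, meta = list()) {
  dt <- patches$t_last_ms - patches$t_first_ms
  cv <- rep(NA_real_, nrow(patches))
  ok <- patches$area_mm2 > 0 & dt > 0
  cv[ok] <- conduction_velocity(patches$area_mm2[ok], dt[ok])
  tibble(
    map_id = as.character(meta$map_id %||% NA_character_),
    animal_id = as.character(meta$animal_id %||% NA_character_),
    chamber = as.character(meta$chamber %||% NA_character_),
    wall_assignment = patches$wall_assignment,
    heart_rate = as.numeric(meta$heart_rate %||% NA_real_),
    sex = as.character(meta$sex %||% NA_character_),
    circle_id = patches$circle_id,
    area_mm2 = patches$area_mm2,
    n_points = patches$n_points,
    cv = cv,
    va = patches$mean_voltage_mV,
    valid = ok,
    exclusion_reason = ifelse(ok, "none",
                              ifelse(patches$area_mm2 <= 0, "empty", "zero_dt"))
  )
}

#' Flag conduction-velocity outliers
#'
#' Velocities strictly above the threshold (default 6 m/s) are flagged
#' invalid with reason `cv_outlier` and ignored in all downstream models;
#' a velocity of exactly 6 m/s is kept. Such values arise when a circle
#' sees near-simultaneous activation (e.g. colliding wavefronts or a
#' breakthrough site), which inflates the diameter-over-spread estimate.
#'
#' @param measurements tibble from [measure_circles()] (rows from several
#'   maps may be bound together).
#' @param threshold outlier threshold in m/s; strictly-greater comparison.
#' @return the measurements with `valid` / `exclusion_reason` updated, and
#'   an exclusion log (count of outliers per map) attached as attribute
#'   `exclusion_log`.
#' @export
apply_outlier_filter <- function(measurements, threshold = 6) {
  if (threshold <= 0) abort("threshold must be > 0 (m/s)")
  out <- measurements %>%
    mutate(
      .outlier = .data$valid & !is.na(.data$cv) & .data$cv > threshold,
      valid = .data$valid & !.data$.outlier,
      exclusion_reason = ifelse(.data$.outlier, "cv_outlier",
                                .data$exclusion_reason)
    ) %>%
    select(-".outlier")
  log <- out %>%
    group_by(.data$map_id) %>%
    summarise(n_circles = dplyr::n(),
              n_cv_outlier = sum(.data$exclusion_reason == "cv_outlier"),
              n_zero_dt = sum(.data$exclusion_reason == "zero_dt"),
              .groups = "drop")
  attr(out, "exclusion_log") <- log
  out
}
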