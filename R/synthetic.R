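# Synthetic electroanatomical maps with known ground truth.
#
# Activation fields are closed-form (planar, focal, colliding wavefronts)
# rather than eikonal-solver output, so the true wave speed is exact and
# every downstream estimate can be checked against it. Geometries are a
# flat triangulated sheet and subdivided-icosahedron ellipsoid chambers;
# anatomical realism is explicitly not a goal.

#' Flat triangulated sheet
#'
#' Regular grid in the z = 0 plane, each cell split into two triangles.
#' The workhorse geometry for analytic checks: patch areas, planar-wave
#' recovery and convergence studies.
#'
#' @param width,height sheet extent in mm.
#' @param edge_length grid spacing in mm (triangle legs).
#' @param wall_partition `"none"` or `"quadrants"` (anterior / lateral /
#'   posterior / septal by xy quadrant, useful for wall-assignment tests).
#' @return a [surface_map()] with zero activation and voltage fields.
#' @export
flat_sheet <- function(width = 60, height = 60, edge_length = 0.5,
                       wall_partition = c("none", "quadrants")) {
  wall_partition <- match.arg(wall_partition)
  xs <- seq(0, width, by = edge_length)
  ys <- seq(0, height, by = edge_length)
  nx <- length(xs); ny <- length(ys)
  vertices <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  tri <- rbind(
    cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
    cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  )
  wall <- rep("unlabeled", nrow(vertices))
  if (wall_partition == "quadrants") {
    cx <- width / 2; cy <- height / 2
    wall <- ifelse(vertices[, 1] < cx,
                   ifelse(vertices[, 2] < cy, "anterior", "lateral"),
                   ifelse(vertices[, 2] < cy, "posterior", "septal"))
  }
  surface_map(vertices, tri, activation = numeric(nrow(vertices)),
              voltage = numeric(nrow(vertices)), wall_label = wall)
}

# Unit icosphere: subdivided icosahedron projected onto the unit sphere.
icosphere <- function(subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mid_env <- new.env(hash = TRUE)
    mid_of <- function(a, b) {
      k <- edge_key(a, b)
      got <- mget(k, envir = mid_env, ifnotfound = NA)
      need <- is.na(unlist(got))
      if (any(need)) {
        p <- (v[a[need], , drop = FALSE] + v[b[need], , drop = FALSE]) / 2
        p <- p / sqrt(rowSums(p^2))
        ids <- nrow(v) + seq_len(sum(need))
        v <<- rbind(v, p)
        for (ii in seq_along(ids))
          assign(k[need][ii], ids[ii], envir = mid_env)
      }
      unlist(mget(k, envir = mid_env))
    }
    a <- f[, 1]; b <- f[, 2]; c_ <- f[, 3]
    ab <- mid_of(a, b); bc <- mid_of(b, c_); ca <- mid_of(c_, a)
    f <- rbind(cbind(a, ab, ca), cbind(b, bc, ab),
               cbind(c_, ca, bc), cbind(ab, bc, ca))
  }
  list(vertices = v, triangles = unname(f))
}

#' Ellipsoid chamber surface
#'
#' Closed ellipsoid built from a subdivided icosahedron, standing in for a
#' cardiac chamber. Vertices are partitioned into the chamber's allowed
#' wall segments: an optional superior polar cap (atria) plus azimuthal
#' sectors around the z axis for the remaining walls.
#'
#' @param semi_axes length-3 numeric, ellipsoid semi-axes in mm.
#' @param subdivisions icosphere subdivision level (level s gives
#'   `10 * 4^s + 2` vertices).
#' @param chamber chamber whose wall scheme to plant (`"RA"`, `"LA"`,
#'   `"RV"`, `"LV"`), or `NULL` for an unlabeled surface.
#' @param superior_cap_frac for atria, fraction of the z-extent (from the
#'   top) labeled `superior`.
#' @return a [surface_map()] with zero activation and voltage fields.
#' @export
ellipsoid_chamber <- function(semi_axes = c(25, 22, 30), subdivisions = 3,
                              chamber = NULL, superior_cap_frac = 0.3) {
  ico <- icosphere(subdivisions)
  vertices <- ico$vertices %*% diag(semi_axes)
  wall <- rep("unlabeled", nrow(vertices))
  meta <- list()
  if (!is.null(chamber)) {
    walls <- wall_scheme(chamber)
    sector_walls <- setdiff(walls, "superior")
    az <- atan2(vertices[, 2], vertices[, 1])          # (-pi, pi]
    sector <- findInterval(az, seq(-pi, pi, length.out = length(sector_walls) + 1),
                           rightmost.closed = TRUE)
    sector <- pmin(pmax(sector, 1L), length(sector_walls))
    wall <- sector_walls[sector]
    if ("superior" %in% walls) {
      zcut <- max(vertices[, 3]) - superior_cap_frac * diff(range(vertices[, 3]))
      wall[vertices[, 3] > zcut] <- "superior"
    }
    meta$chamber <- chamber
  }
  surface_map(vertices, ico$triangles,
              activation = numeric(nrow(vertices)),
              voltage = numeric(nrow(vertices)),
              wall_label = wall, meta = meta)
}

#' Wavefront field specifications
#'
#' Closed-form activation-time fields evaluated at the mesh vertices:
#' * `wave_planar()`: `t(x) = (x . n) / v` for unit direction `n` and
#'   speed `v` (m/s == mm/ms) — a plane wave.
#' * `wave_focal()`: `t(x) = |x - origin| / v`, straight-line distance
#'   over speed; an approximation of a focal (point-source) activation
#'   that is exact on flat geometry and approximate on curved surfaces.
#' * `wave_colliding()`: pointwise minimum of two component fields — two
#'   wavefronts meeting inside the map, the stress case in which
#'   diameter-over-spread velocity estimates are inflated near the
#'   collision line.
#'
#' @param direction length-3 propagation direction (normalised internally).
#' @param speed wave speed in m/s (> 0).
#' @param origin length-3 source location in mm.
#' @param wave1,wave2 component wave specifications.
#' @return a wave specification for [generate_map()].
#' @name waves
NULL

#' @rdname waves
#' @export
wave_planar <- function(direction = c(1, 0, 0), speed = 0.6) {
  if (speed <= 0) abort("wave speed must be > 0 (m/s)")
  n <- direction / sqrt(sum(direction^2))
  structure(list(type = "planar", direction = n, speed = speed),
            class = "eamap_wave")
}

#' @rdname waves
#' @export
wave_focal <- function(origin = c(0, 0, 0), speed = 0.6) {
  if (speed <= 0) abort("wave speed must be > 0 (m/s)")
  structure(list(type = "focal", origin = origin, speed = speed),
            class = "eamap_wave")
}

#' @rdname waves
#' @export
wave_colliding <- function(wave1, wave2) {
  structure(list(type = "colliding", waves = list(wave1, wave2)),
            class = "eamap_wave")
}

# Evaluate a wave specification at vertex coordinates (ms).
activation_field <- function(wave, vertices) {
  switch(wave$type,
    planar = as.vector(vertices %*% wave$direction) / wave$speed,
    focal = sqrt(rowSums(sweep(vertices, 2, wave$origin)^2)) / wave$speed,
    colliding = do.call(pmin, lapply(wave$waves, activation_field,
                                     vertices = vertices)),
    abort(sprintf("unknown wave type '%s'", wave$type))
  )
}

#' Build a synthetic-map scenario
#'
#' Bundles everything [generate_map()] needs: a geometry, a wavefront, a
#' voltage field (per-wall means plus Gaussian noise), cutout disks and a
#' seed. The same scenario and seed always reproduce the identical map.
#'
#' @param geometry a [surface_map()] providing vertices/triangles and wall
#'   labels (e.g. [flat_sheet()] or [ellipsoid_chamber()]).
#' @param wave a wave specification from [wave_planar()], [wave_focal()]
#'   or [wave_colliding()].
#' @param voltage_mean baseline voltage in mV, used for walls without an
#'   entry in `voltage_by_wall` and for unlabeled vertices.
#' @param voltage_by_wall named numeric, per-wall mean voltage in mV.
#' @param voltage_sd vertex-level Gaussian noise sd in mV (values are
#'   clamped at 0 to respect the nonnegative-amplitude invariant).
#' @param activation_jitter_sd vertex-level activation noise sd in ms.
#' @param cutouts list of `list(center = c(x, y, z), radius = r)` disks;
#'   vertices within `r` of a center are marked cutout, emulating vessel /
#'   valve transition zones.
#' @param flat_spots list of the same disk shape; activation inside is
#'   replaced by its local mean, creating near-simultaneous activation and
#'   hence planted >6 m/s velocity outliers.
#' @param meta map metadata list, as in [surface_map()].
#' @param seed integer seed.
#' @return a `map_scenario` list.
#' @export
map_scenario <- function(geometry, wave, voltage_mean = 5,
                         voltage_by_wall = NULL, voltage_sd = 0,
                         activation_jitter_sd = 0, cutouts = list(),
                         flat_spots = list(), meta = list(), seed = 1L) {
  structure(list(geometry = geometry, wave = wave,
                 voltage_mean = voltage_mean,
                 voltage_by_wall = voltage_by_wall,
                 voltage_sd = voltage_sd,
                 activation_jitter_sd = activation_jitter_sd,
                 cutouts = cutouts, flat_spots = flat_spots,
                 meta = meta, seed = as.integer(seed)),
            class = "map_scenario")
}

#' Generate one synthetic map
#'
#' Evaluates the scenario's wavefront analytically at each vertex, plants
#' wall-dependent voltage with Gaussian noise, applies cutout disks and
#' optional activation flat spots, and returns the map together with a
#' ground-truth record (true speed, per-wall voltage means, flat-spot
#' vertex sets). Identical seeds give bitwise-identical maps.
#'
#' @param scenario a [map_scenario()].
#' @return list with elements `map` (a [surface_map()]) and `truth`.
#' @export
generate_map <- function(scenario) {
  geom <- scenario$geometry
  v <- geom$vertices
  n <- nrow(v)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(scenario$seed)

  act <- activation_field(scenario$wave, v)
  act <- act - min(act)
  if (scenario$activation_jitter_sd > 0)
    act <- act + stats::rnorm(n, 0, scenario$activation_jitter_sd)

  flat_ids <- integer(0)
  for (fs in scenario$flat_spots) {
    inside <- which(sqrt(rowSums(sweep(v, 2, fs$center)^2)) <= fs$radius)
    if (length(inside)) {
      act[inside] <- mean(act[inside])
      flat_ids <- union(flat_ids, inside)
    }
  }

  cut <- rep(FALSE, n)
  for (co in scenario$cutouts)
    cut <- cut | sqrt(rowSums(sweep(v, 2, co$center)^2)) <= co$radius
  if (all(cut)) abort("scenario cutouts cover every vertex")

  means <- rep(scenario$voltage_mean, n)
  if (!is.null(scenario$voltage_by_wall)) {
    hit <- geom$wall_label %in% names(scenario$voltage_by_wall)
    means[hit] <- scenario$voltage_by_wall[geom$wall_label[hit]]
  }
  volt <- pmax(0, means + stats::rnorm(n, 0, scenario$voltage_sd))

  map <- surface_map(v, geom$triangles, activation = act, voltage = volt,
                     cutout = cut, wall_label = geom$wall_label,
                     meta = scenario$meta)
  truth <- list(
    wave = scenario$wave,
    speed = if (scenario$wave$type == "colliding")
      vapply(scenario$wave$waves, `[[`, 0, "speed") else scenario$wave$speed,
    voltage_mean = scenario$voltage_mean,
    voltage_by_wall = scenario$voltage_by_wall,
    voltage_sd = scenario$voltage_sd,
    flat_spot_vertices = flat_ids,
    seed = scenario$seed
  )
  list(map = map, truth = truth)
}

#' Reference study layout
#'
#' The map-level inventory of the porcine mapping study this package
#' models: 21 sinus-rhythm maps from 4 juvenile animals (two female), with
#' mapping location, mean heart rate, recorded point and circle counts,
#' and map volume. Used both as the default design of the study
#' simulator and to recompute the study-level aggregates.
#'
#' @return a tibble with one row per map: `pig`, `map_nr`, `location`,
#'   `heart_rate`, `n_points`, `volume_ml`, `circles_whole_map` and
#'   per-wall circle counts.
#' @export
reference_map_inventory <- function() {
  path <- system.file("extdata", "porcine_map_inventory.csv",
                      package = "eamap", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' @describeIn reference_map_inventory design columns only (`animal_id`,
#'   `map_id`, `chamber`, `heart_rate`, `sex`), with sexes assigned
#'   two-female / two-male as in the study.
#' @export
reference_map_design <- function() {
  inv <- reference_map_inventory()
  tibble(
    animal_id = paste0("pig", inv$pig),
    map_id = paste0("map", inv$map_nr),
    chamber = inv$location,
    heart_rate = inv$heart_rate,
    sex = ifelse(inv$pig %in% c(3, 5), "f", "m")
  )
}

#' Simulate a per-circle measurement table from the hierarchical model
#'
#' Draws circle-level conduction velocity and voltage amplitude directly
#' from the mixed model the statistics layer fits: on the log scale,
#' `log cv = chamber mean + animal intercept + slope * (HR - 90) + sex
#' effect + residual`, and analogously (untransformed) for voltage. This
#' bypasses the geometry pipeline, giving exact knowledge of every
#' generative parameter — the tool for parameter-recovery and CI-coverage
#' studies of [fit_mixed_model()].
#'
#' Default chamber means follow the ordering observed in healthy porcine
#' chambers (CV: LA > LV > RV > RA; VA: LV > RV > LA > RA).
#'
#' @param design tibble with one row per map (`animal_id`, `map_id`,
#'   `chamber`, `heart_rate`, `sex`); defaults to [reference_map_design()].
#' @param circles_per_map circles simulated per map.
#' @param chamber_log_cv named numeric, true chamber means of log CV
#'   (log m/s) at 90 bpm.
#' @param chamber_va named numeric, true chamber means of VA (mV) at
#'   90 bpm.
#' @param hr_slope_log_cv,hr_slope_va fixed heart-rate slopes (per bpm).
#' @param animal_sd_log_cv,animal_sd_va random-intercept sds.
#' @param resid_sd_log_cv,resid_sd_va circle-level residual sds.
#' @param sex_effect_log_cv,sex_effect_va additive effect of female sex.
#' @param outlier_fraction fraction of circles replaced by planted
#'   velocity outliers (cv drawn uniformly in 8–30 m/s).
#' @param seed integer seed.
#' @return a measurement tibble as from [measure_circles()], plus a
#'   logical `planted_outlier` column; the full generative parameter set
#'   is attached as attribute `truth`.
#' @export
simulate_measurements <- function(
    design = reference_map_design(), circles_per_map = 131,
    chamber_log_cv = log(c(RA = 0.50, LA = 0.79, RV = 0.54, LV = 0.59)),
    chamber_va = c(RA = 3.35, LA = 4.81, RV = 7.83, LV = 10.98),
    hr_slope_log_cv = -0.002, hr_slope_va = -0.01,
    animal_sd_log_cv = 0.10, animal_sd_va = 0.5,
    resid_sd_log_cv = 0.30, resid_sd_va = 1.5,
    sex_effect_log_cv = 0, sex_effect_va = 0,
    outlier_fraction = 0, seed = 1L) {
  animals <- unique(design$animal_id)
  if (length(animals) < 2)
    abort("need >= 2 animals for an identifiable hierarchy")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  b_cv <- stats::rnorm(length(animals), 0, animal_sd_log_cv)
  b_va <- stats::rnorm(length(animals), 0, animal_sd_va)
  names(b_cv) <- names(b_va) <- animals

  rows <- design[rep(seq_len(nrow(design)), each = circles_per_map), ]
  nn <- nrow(rows)
  fem <- as.numeric(rows$sex == "f")
  log_cv <- chamber_log_cv[rows$chamber] + b_cv[rows$animal_id] +
    hr_slope_log_cv * (rows$heart_rate - 90) + sex_effect_log_cv * fem +
    stats::rnorm(nn, 0, resid_sd_log_cv)
  va <- pmax(0, chamber_va[rows$chamber] + b_va[rows$animal_id] +
               hr_slope_va * (rows$heart_rate - 90) + sex_effect_va * fem +
               stats::rnorm(nn, 0, resid_sd_va))
  cv <- exp(unname(log_cv))

  planted <- rep(FALSE, nn)
  if (outlier_fraction > 0) {
    k <- round(outlier_fraction * nn)
    planted[sample.int(nn, k)] <- TRUE
    cv[planted] <- stats::runif(sum(planted), 8, 30)
  }

  out <- tibble(
    map_id = rows$map_id, animal_id = rows$animal_id,
    chamber = rows$chamber, wall_assignment = NA_character_,
    heart_rate = rows$heart_rate, sex = rows$sex,
    circle_id = unlist(lapply(seq_len(nrow(design)),
                              function(i) seq_len(circles_per_map))),
    area_mm2 = NA_real_, n_points = NA_integer_,
    cv = cv, va = unname(va),
    valid = TRUE, exclusion_reason = "none",
    planted_outlier = planted
  )
  attr(out, "truth") <- list(
    chamber_log_cv = chamber_log_cv, chamber_va = chamber_va,
    hr_slope_log_cv = hr_slope_log_cv, hr_slope_va = hr_slope_va,
    animal_sd_log_cv = animal_sd_log_cv, animal_sd_va = animal_sd_va,
    resid_sd_log_cv = resid_sd_log_cv, resid_sd_va = resid_sd_va,
    sex_effect_log_cv = sex_effect_log_cv, sex_effect_va = sex_effect_va,
    animal_intercepts_log_cv = b_cv, animal_intercepts_va = b_va,
    outlier_fraction = outlier_fraction, seed = seed
  )
  out
}

#' Generate a full multi-animal synthetic study of surface maps
#'
#' One synthetic map per design row: a planar wavefront crosses an
#' ellipsoid chamber at a per-map speed built from the chamber mean, a
#' multiplicative (log-scale) animal random intercept and the heart-rate
#' slope; voltage is the chamber mean plus an additive animal intercept
#' and vertex noise. The returned truth table lists every per-map
#' generative value.
#'
#' @inheritParams simulate_measurements
#' @param subdivisions icosphere subdivision per chamber geometry (level 3
#'   = 642 vertices keeps a 21-map study fast; raise for denser maps).
#' @param voltage_sd vertex-level voltage noise sd (mV).
#' @param activation_jitter_sd vertex-level activation noise sd (ms).
#' @return list with `maps` (named list of [surface_map()]) and `truth`
#'   (tibble of per-map generative parameters).
#' @export
generate_study <- function(
    design = reference_map_design(), subdivisions = 3,
    chamber_log_cv = log(c(RA = 0.50, LA = 0.79, RV = 0.54, LV = 0.59)),
    chamber_va = c(RA = 3.35, LA = 4.81, RV = 7.83, LV = 10.98),
    hr_slope_log_cv = -0.002, hr_slope_va = -0.01,
    animal_sd_log_cv = 0.10, animal_sd_va = 0.5,
    voltage_sd = 1.5, activation_jitter_sd = 0, seed = 1L) {
  animals <- unique(design$animal_id)
  if (length(animals) < 2)
    abort("need >= 2 animals for an identifiable study")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  b_cv <- stats::rnorm(length(animals), 0, animal_sd_log_cv)
  b_va <- stats::rnorm(length(animals), 0, animal_sd_va)
  names(b_cv) <- names(b_va) <- animals

  # chamber sizes loosely matching juvenile porcine volumes
  axes <- list(RA = c(26, 24, 28), LA = c(21, 20, 24),
               RV = c(24, 22, 30), LV = c(22, 21, 29))
  maps <- list()
  truth <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    speed <- exp(chamber_log_cv[[row$chamber]] + b_cv[[row$animal_id]] +
                 hr_slope_log_cv * (row$heart_rate - 90))
    vmean <- chamber_va[[row$chamber]] + b_va[[row$animal_id]] +
      hr_slope_va * (row$heart_rate - 90)
    dir_angle <- stats::runif(1, 0, 2 * pi)
    sc <- map_scenario(
      geometry = ellipsoid_chamber(axes[[row$chamber]],
                                   subdivisions = subdivisions,
                                   chamber = row$chamber),
      wave = wave_planar(c(cos(dir_angle), sin(dir_angle), 0.2), speed),
      voltage_mean = vmean, voltage_sd = voltage_sd,
      activation_jitter_sd = activation_jitter_sd,
      meta = list(map_id = row$map_id, animal_id = row$animal_id,
                  chamber = row$chamber, heart_rate = row$heart_rate,
                  sex = row$sex),
      seed = sample.int(.Machine$integer.max, 1)
    )
    gen <- generate_map(sc)
    maps[[row$map_id]] <- gen$map
    truth[[i]] <- tibble(map_id = row$map_id, animal_id = row$animal_id,
                         chamber = row$chamber, heart_rate = row$heart_rate,
                         sex = row$sex, true_speed = unname(speed),
                         true_voltage_mean = unname(vmean),
                         animal_intercept_log_cv = unname(b_cv[[row$animal_id]]),
                         animal_intercept_va = unname(b_va[[row$animal_id]]),
                         map_seed = sc$seed)
  }
  list(maps = maps, truth = bind_rows(truth))
}
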