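# Circular-patch extraction: intersect the non-cutout surface with a
# Euclidean ball, the mesh analogue of a spherical implicit-function clip.
# The distance-to-center field is evaluated at the vertices and iso-clipped
# at level = radius with linear interpolation along edges (consistent with
# linear elements): triangles fully inside are kept whole, boundary
# triangles are split exactly at the interpolated crossing points, and all
# scalar fields are linearly interpolated at the split points.

# Precomputed per-map clip context: non-cutout triangles and their areas.
clip_cache <- function(map) {
  keep <- !cutout_triangles(map)
  tr <- map$triangles[keep, , drop = FALSE]
  list(tr = tr, areas = triangle_areas(map)[keep])
}

empty_patch <- function(center, radius) {
  structure(list(center = center, radius = radius, area = 0,
                 covered_vertex_ids = integer(0), t_first = NA_real_,
                 t_last = NA_real_, mean_voltage = NA_real_, n_points = 0L,
                 wall_assignment = NA_character_, empty = TRUE),
            class = "circle_patch")
}

#' Clip a spherical region out of a surface map
#'
#' Computes the circular patch cut from the non-cutout surface by the
#' Euclidean ball of the given radius: the patch area, the activation
#' extrema over covered vertices and interpolated clip-boundary points, the
#' mean voltage over the clipped surface (area-weighted by default), and
#' the measurement points strictly inside the ball.
#'
#' An empty intersection returns an empty-patch marker (`$empty = TRUE`),
#' not an error; placing the center exactly on a cutout vertex is rejected.
#'
#' @param map a [surface_map()].
#' @param center length-3 numeric, ball center in mm.
#' @param radius ball radius in mm (> 0); the study default is 5 mm.
#' @param voltage_aggregation `"area_weighted"` integrates the linearly
#'   interpolated voltage over the clipped patch; `"vertex_mean"` averages
#'   over covered vertices.
#' @return a `circle_patch`: list with `center`, `radius`, `area` (mm^2),
#'   `covered_vertex_ids`, `t_first`/`t_last` (ms), `mean_voltage` (mV),
#'   `n_points`, `wall_assignment`, `empty`.
#' @export
clip_ball <- function(map, center, radius,
                      voltage_aggregation = c("area_weighted", "vertex_mean")) {
  voltage_aggregation <- match.arg(voltage_aggregation)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    abort("radius must be a single positive number (mm)")
  clip_ball_impl(map, center, radius, clip_cache(map), voltage_aggregation)
}

clip_ball_impl <- function(map, center, radius, cache, voltage_aggregation) {
  v <- map$vertices
  d <- sqrt((v[, 1] - center[1])^2 + (v[, 2] - center[2])^2 +
            (v[, 3] - center[3])^2)
  if (any(map$cutout & d < 1e-9))
    abort("circle center lies on a cutout vertex")

  tr <- cache$tr
  if (nrow(tr) == 0) return(empty_patch(center, radius))
  d1 <- d[tr[, 1]]; d2 <- d[tr[, 2]]; d3 <- d[tr[, 3]]
  cand <- pmin(d1, d2, d3) <= radius
  if (!any(cand)) return(empty_patch(center, radius))

  tri <- tr[cand, , drop = FALSE]
  full_area <- cache$areas[cand]
  ins <- cbind(d1[cand] <= radius, d2[cand] <= radius, d3[cand] <= radius)
  k <- rowSums(ins)

  act <- map$activation
  volt <- map$voltage
  area_total <- 0
  volt_int <- 0
  boundary_t <- numeric(0)

  # fully covered triangles
  w3 <- k == 3
  if (any(w3)) {
    a3 <- full_area[w3]
    area_total <- area_total + sum(a3)
    volt_int <- volt_int +
      sum(a3 * (volt[tri[w3, 1]] + volt[tri[w3, 2]] + volt[tri[w3, 3]]) / 3)
  }

  # boundary triangles: rotate indices so the pattern is canonical, split
  # the crossing edges at s = (radius - d_in) / (d_out - d_in)
  tri_area3 <- function(p, q, r) {
    e1 <- q - p; e2 <- r - p
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  rot_idx <- function(rows, pos) {
    # returns vertex ids (a, b, c) with the cycle rotated so 'pos' comes first
    i <- cbind(rows, pos)
    a <- tri[cbind(rows, pos)]
    b <- tri[cbind(rows, pos %% 3L + 1L)]
    c_ <- tri[cbind(rows, (pos + 1L) %% 3L + 1L)]
    list(a = a, b = b, c = c_)
  }
  lerp_pt <- function(i, j, s) v[i, , drop = FALSE] +
    (v[j, , drop = FALSE] - v[i, , drop = FALSE]) * s

  w1 <- which(k == 1)
  if (length(w1)) {
    pos <- max.col(ins[w1, , drop = FALSE], ties.method = "first")
    ix <- rot_idx(w1, pos)                      # a inside; b, c outside
    s_ab <- (radius - d[ix$a]) / (d[ix$b] - d[ix$a])
    s_ac <- (radius - d[ix$a]) / (d[ix$c] - d[ix$a])
    p_ab <- lerp_pt(ix$a, ix$b, s_ab)
    p_ac <- lerp_pt(ix$a, ix$c, s_ac)
    ar <- tri_area3(v[ix$a, , drop = FALSE], p_ab, p_ac)
    v_ab <- volt[ix$a] + s_ab * (volt[ix$b] - volt[ix$a])
    v_ac <- volt[ix$a] + s_ac * (volt[ix$c] - volt[ix$a])
    t_ab <- act[ix$a] + s_ab * (act[ix$b] - act[ix$a])
    t_ac <- act[ix$a] + s_ac * (act[ix$c] - act[ix$a])
    area_total <- area_total + sum(ar)
    volt_int <- volt_int + sum(ar * (volt[ix$a] + v_ab + v_ac) / 3)
    boundary_t <- c(boundary_t, t_ab, t_ac)
  }

  w2 <- which(k == 2)
  if (length(w2)) {
    posout <- max.col(!ins[w2, , drop = FALSE], ties.method = "first")
    # rotate so the outside vertex is last: (a, b inside, c outside)
    ix <- rot_idx(w2, posout %% 3L + 1L)
    s_bc <- (radius - d[ix$b]) / (d[ix$c] - d[ix$b])
    s_ca <- (radius - d[ix$a]) / (d[ix$c] - d[ix$a])
    p_bc <- lerp_pt(ix$b, ix$c, s_bc)
    p_ca <- lerp_pt(ix$a, ix$c, s_ca)
    va_ <- v[ix$a, , drop = FALSE]; vb_ <- v[ix$b, , drop = FALSE]
    ar1 <- tri_area3(va_, vb_, p_bc)
    ar2 <- tri_area3(va_, p_bc, p_ca)
    v_bc <- volt[ix$b] + s_bc * (volt[ix$c] - volt[ix$b])
    v_ca <- volt[ix$a] + s_ca * (volt[ix$c] - volt[ix$a])
    t_bc <- act[ix$b] + s_bc * (act[ix$c] - act[ix$b])
    t_ca <- act[ix$a] + s_ca * (act[ix$c] - act[ix$a])
    area_total <- area_total + sum(ar1) + sum(ar2)
    volt_int <- volt_int +
      sum(ar1 * (volt[ix$a] + volt[ix$b] + v_bc) / 3) +
      sum(ar2 * (volt[ix$a] + v_bc + v_ca) / 3)
    boundary_t <- c(boundary_t, t_bc, t_ca)
  }

  covered <- sort(unique(as.vector(tri)[as.vector(ins)]))
  if (area_total <= 0 || length(covered) == 0)
    return(empty_patch(center, radius))

  mean_voltage <- if (voltage_aggregation == "area_weighted")
    volt_int / area_total else mean(volt[covered])
  t_all <- c(act[covered], boundary_t)

  structure(list(
    center = center, radius = radius, area = area_total,
    covered_vertex_ids = covered,
    t_first = min(t_all), t_last = max(t_all),
    mean_voltage = mean_voltage,
    n_points = sum(d[covered] < radius),
    wall_assignment = NA_character_, empty = FALSE
  ), class = "circle_patch")
}

#' @export
print.circle_patch <- function(x, ...) {
  if (x$empty) {
    cat("<circle_patch> empty (r =", x$radius, "mm)\n")
  } else {
    cat(sprintf(
      "<circle_patch> r = %g mm, area %.2f mm2, %d points, dt %.2f ms, %.2f mV\n",
      x$radius, x$area, x$n_points, x$t_last - x$t_first, x$mean_voltage))
  }
  invisible(x)
}

#' Place circle centers by greedy farthest-point sampling
#'
#' Selects centers among the non-cutout mesh vertices: starting from a
#' seeded initial vertex, repeatedly picks the vertex farthest (Euclidean)
#' from all chosen centers until that farthest distance falls below
#' `spacing`. The result is a roughly uniform covering with inter-center
#' distance >= `spacing`, deterministic for a given seed (the seed picks
#' the initial vertex and breaks exact distance ties).
#'
#' @param map a [surface_map()].
#' @param spacing minimum inter-center distance in mm (the study default
#'   pairs 5 mm spacing with 5 mm circle radius, giving overlapping
#'   circles).
#' @param seed integer RNG seed.
#' @return numeric matrix of centers (rows, columns x/y/z), with the chosen
#'   vertex indices as attribute `vertex_ids`; zero rows when every vertex
#'   is a cutout.
#' @export
sample_centers <- function(map, spacing = 5, seed = 1L) {
  if (spacing <= 0) abort("spacing must be > 0 (mm)")
  cand <- which(!map$cutout)
  if (length(cand) == 0) {
    out <- matrix(numeric(0), 0, 3)
    attr(out, "vertex_ids") <- integer(0)
    return(out)
  }
  V <- map$vertices[cand, , drop = FALSE]
  n <- nrow(V)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chosen <- sample.int(n, 1)
  mind <- sqrt((V[, 1] - V[chosen, 1])^2 + (V[, 2] - V[chosen, 2])^2 +
               (V[, 3] - V[chosen, 3])^2)
  repeat {
    mx <- max(mind)
    if (mx < spacing) break
    ties <- which(mind > mx - 1e-12)
    nxt <- if (length(ties) > 1) ties[sample.int(length(ties), 1)] else ties
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, sqrt((V[, 1] - V[nxt, 1])^2 + (V[, 2] - V[nxt, 2])^2 +
                            (V[, 3] - V[nxt, 3])^2))
  }
  out <- V[chosen, , drop = FALSE]
  attr(out, "vertex_ids") <- cand[chosen]
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Cover a map with overlapping circular patches
#'
#' Runs [sample_centers()] and [clip_ball()] per center, drops empty
#' patches, and returns one row per circle. This is the map-level analogue
#' of tiling the curved chamber surface with ~5 mm spherical filters.
#'
#' @inheritParams clip_ball
#' @param radius circle radius in mm (default 5).
#' @param spacing center spacing in mm (default 5).
#' @param seed integer seed for center placement.
#' @return a tibble with columns `circle_id`, `center_x/y/z`, `radius_mm`,
#'   `area_mm2`, `n_points`, `t_first_ms`, `t_last_ms`, `mean_voltage_mV`,
#'   `wall_assignment` (filled by [assign_walls()]), and a list-column
#'   `covered` of covered vertex indices. Per-map summary statistics
#'   (`n_circles`, `mean_area_mm2`, `mean_n_points`) are attached as the
#'   attribute `summary`.
#' @export
cover_map <- function(map, radius = 5, spacing = 5, seed = 1L,
                      voltage_aggregation = c("area_weighted", "vertex_mean")) {
  voltage_aggregation <- match.arg(voltage_aggregation)
  validate_surface_map(map)
  centers <- sample_centers(map, spacing = spacing, seed = seed)
  cache <- clip_cache(map)
  patches <- lapply(seq_len(nrow(centers)), function(i)
    clip_ball_impl(map, centers[i, ], radius, cache, voltage_aggregation))
  patches <- patches[!vapply(patches, `[[`, logical(1), "empty")]
  out <- tibble(
    circle_id = seq_along(patches),
    center_x = vapply(patches, function(p) p$center[1], 0),
    center_y = vapply(patches, function(p) p$center[2], 0),
    center_z = vapply(patches, function(p) p$center[3], 0),
    radius_mm = radius,
    area_mm2 = vapply(patches, `[[`, 0, "area"),
    n_points = vapply(patches, `[[`, 0L, "n_points"),
    t_first_ms = vapply(patches, `[[`, 0, "t_first"),
    t_last_ms = vapply(patches, `[[`, 0, "t_last"),
    mean_voltage_mV = vapply(patches, `[[`, 0, "mean_voltage"),
    wall_assignment = NA_character_,
    covered = lapply(patches, `[[`, "covered_vertex_ids")
  )
  attr(out, "summary") <- list(
    n_circles = nrow(out),
    mean_area_mm2 = mean(out$area_mm2),
    mean_n_points = mean(out$n_points)
  )
  out
}
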