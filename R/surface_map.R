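#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||% :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Enumerations used throughout the package. Chambers follow clinical naming;
# wall segments are the anatomical partitions a chamber can carry. RA walls
# never include "anterior" and ventricular walls never include "superior";
# that restriction lives in wall_scheme(), not here.
CHAMBERS <- c("RA", "LA", "RV", "LV")
WALL_LEVELS <- c("anterior", "posterior", "lateral", "septal", "superior",
                 "unlabeled")

#' Construct an electroanatomical surface map
#'
#' A `surface_map` is a triangulated surface with per-vertex scalar fields:
#' local activation time (ms), unipolar voltage amplitude (mV), a logical
#' cutout mask marking excluded transition zones (vessel ostia, valves,
#' chamber transitions), and an optional anatomical wall label. Coordinates
#' are millimetres; the mm/ms/mV unit system is fixed so that conduction
#' velocities in mm/ms coincide with m/s.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param triangles integer matrix, one row per triangle, three 1-based
#'   vertex indices per row. Counter-clockwise orientation (seen from
#'   outside) gives positive enclosed volume.
#' @param activation numeric vector of local activation times (ms), one per
#'   vertex.
#' @param voltage numeric vector of nonnegative unipolar amplitudes (mV),
#'   one per vertex.
#' @param cutout logical vector, one per vertex; `TRUE` marks vertices in
#'   excluded transition zones. Defaults to all `FALSE`.
#' @param wall_label character vector of wall segments, one per vertex, each
#'   one of `"anterior"`, `"posterior"`, `"lateral"`, `"septal"`,
#'   `"superior"`, `"unlabeled"`. Defaults to all `"unlabeled"`.
#' @param meta named list of map metadata: `map_id`, `animal_id`, `chamber`
#'   (one of RA/LA/RV/LV), `heart_rate` (bpm), `sex`.
#'
#' @return An object of class `surface_map`.
#' @examples
#' sheet <- flat_sheet(width = 10, height = 10, edge_length = 1)
#' sheet
#' surface_area(sheet)
#' @export
surface_map <- function(vertices, triangles, activation, voltage,
                        cutout = NULL, wall_label = NULL, meta = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  n <- nrow(vertices)

  if (is.null(cutout)) cutout <- rep(FALSE, n)
  if (is.null(wall_label)) wall_label <- rep("unlabeled", n)

  map <- structure(
    list(
      vertices = vertices,
      triangles = triangles,
      activation = as.double(activation),
      voltage = as.double(voltage),
      cutout = as.logical(cutout),
      wall_label = as.character(wall_label),
      meta = meta
    ),
    class = "surface_map"
  )
  validate_surface_map(map)
}

#' Validate a surface map
#'
#' Checks the structural invariants of a [surface_map()]: three distinct,
#' in-range vertex indices per triangle, strictly positive triangle areas,
#' finite coordinates, one scalar value per vertex, nonnegative voltage, and
#' chamber / wall labels restricted to their enumerations.
#'
#' @param map a `surface_map`.
#' @return `map`, invisibly unchanged, or an error describing the violation.
#' @export
validate_surface_map <- function(map) {
  v <- map$vertices
  tr <- map$triangles
  n <- nrow(v)
  if (ncol(v) != 3L) abort("vertices must have 3 columns (x, y, z in mm)")
  if (!all(is.finite(v))) abort("vertex coordinates must be finite")
  if (ncol(tr) != 3L) abort("triangles must have 3 vertex indices per row")
  if (nrow(tr) > 0) {
    if (min(tr) < 1L || max(tr) > n)
      abort("triangle vertex indices out of range")
    if (any(tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]))
      abort("degenerate triangle: repeated vertex index")
    if (any(triangle_areas(map) <= 0))
      abort("all triangle areas must be > 0 (zero-area triangle found)")
  }
  for (fld in c("activation", "voltage", "cutout", "wall_label")) {
    if (length(map[[fld]]) != n)
      abort(sprintf("field '%s' must have one value per vertex (%d != %d)",
                    fld, length(map[[fld]]), n))
  }
  if (any(!is.finite(map$activation)))
    abort("activation times must be finite")
  if (any(!is.finite(map$voltage)) || any(map$voltage < 0))
    abort("voltage must be finite and >= 0 (unipolar amplitude)")
  if (!all(map$wall_label %in% WALL_LEVELS))
    abort(sprintf("wall_label values must be one of: %s",
                  paste(WALL_LEVELS, collapse = ", ")))
  ch <- map$meta$chamber
  if (!is.null(ch) && !ch %in% CHAMBERS)
    abort(sprintf("chamber must be one of %s", paste(CHAMBERS, collapse = ", ")))
  invisible(map)
}

#' @export
print.surface_map <- function(x, ...) {
  m <- x$meta
  cat("<surface_map>",
      if (!is.null(m$map_id)) paste0(" map ", m$map_id),
      if (!is.null(m$chamber)) paste0(" [", m$chamber, "]"), "\n", sep = "")
  cat(sprintf("  %d vertices, %d triangles, %.1f mm2 surface\n",
              nrow(x$vertices), nrow(x$triangles), surface_area(x)))
  cat(sprintf("  activation %.2f..%.2f ms, voltage %.2f..%.2f mV, %d cutout vertices\n",
              min(x$activation), max(x$activation),
              min(x$voltage), max(x$voltage), sum(x$cutout)))
  if (!is.null(m$animal_id))
    cat(sprintf("  animal %s, heart rate %s bpm, sex %s\n",
                m$animal_id, m$heart_rate %||% "?", m$sex %||% "?"))
  invisible(x)
}

# Per-triangle areas (mm^2) via cross products; vectorised over triangles.
triangle_areas <- function(map) {
  v <- map$vertices
  tr <- map$triangles
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Logical: triangles with at least one cutout vertex. A triangle is excluded
# as soon as any of its vertices lies in a cutout zone (conservative rule).
cutout_triangles <- function(map) {
  tr <- map$triangles
  map$cutout[tr[, 1]] | map$cutout[tr[, 2]] | map$cutout[tr[, 3]]
}

#' Total surface area of a map
#'
#' Sum of triangle areas in mm^2. With `restrict_to_non_cutout = TRUE` only
#' triangles whose three vertices are all outside cutout zones contribute,
#' matching the exclusion rule used when placing circles.
#'
#' @param map a [surface_map()].
#' @param restrict_to_non_cutout drop triangles touching a cutout vertex?
#' @return surface area in mm^2 (a single number).
#' @export
surface_area <- function(map, restrict_to_non_cutout = FALSE) {
  validate_surface_map(map)
  areas <- triangle_areas(map)
  if (restrict_to_non_cutout) areas <- areas[!cutout_triangles(map)]
  sum(areas)
}

#' Enclosed volume of a closed surface map
#'
#' Signed divergence-theorem volume (sum of signed tetrahedron volumes
#' against the origin), reported as an absolute value and converted from
#' mm^3 to mL. Chamber maps exported from mapping systems are not guaranteed
#' to be watertight, so an open mesh produces a warning and a best-effort
#' value rather than an error; openness is detected from boundary edges
#' (edges used by exactly one triangle).
#'
#' @param map a [surface_map()].
#' @return volume in mL, with attribute `open_mesh` (logical).
#' @export
enclosed_volume <- function(map) {
  validate_surface_map(map)
  v <- map$vertices
  tr <- map$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  # a . (b x c) / 6 per triangle
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  vol_mm3 <- abs(sum(det) / 6)
  open <- is_open_mesh(map)
  if (open)
    warn("mesh has boundary edges; enclosed_volume is a best-effort value")
  structure(vol_mm3 / 1000, open_mesh = open)
}

# TRUE if any edge belongs to exactly one triangle.
is_open_mesh <- function(map) {
  tr <- map$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  any(table(key) == 1L)
}

#' Apply a rigid transform to a map
#'
#' Rotates (3x3 orthonormal matrix) and translates the vertex coordinates,
#' leaving every scalar field untouched. Useful for invariance checks:
#' areas, volumes and patch structure are unchanged under rigid motion.
#'
#' @param map a [surface_map()].
#' @param rotation 3x3 rotation matrix (defaults to identity).
#' @param translation length-3 numeric offset in mm.
#' @return the transformed `surface_map`.
#' @export
transform_map <- function(map, rotation = diag(3), translation = c(0, 0, 0)) {
  map$vertices <- map$vertices %*% t(rotation) +
    matrix(translation, nrow(map$vertices), 3, byrow = TRUE)
  map
}
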