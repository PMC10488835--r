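# On-disk formats for surface maps.
#
# Primary format: legacy ASCII VTK polydata with named POINT_DATA scalar
# arrays "activation_ms", "voltage_mV", "cutout" (0/1) and "wall_label"
# (integer codes into the wall-level enumeration). Map metadata is carried
# as a JSON object on the VTK title line. Vertex indices are 0-based on
# disk (VTK convention) and 1-based in R.
#
# Secondary format: a "tabular bundle" directory with vertices.csv,
# triangles.csv (0-based indices), scalars.csv and meta.json -- a diffable
# dialect used for small fixtures.

#' Write a surface map to disk
#'
#' @param map a [surface_map()].
#' @param path output file (`format = "vtk"`) or directory
#'   (`format = "bundle"`).
#' @param format `"vtk"` for legacy ASCII VTK polydata, `"bundle"` for a
#'   directory of delimited text files plus JSON metadata.
#' @return `path`, invisibly.
#' @seealso [read_map()]
#' @export
write_map <- function(map, path, format = c("vtk", "bundle")) {
  format <- match.arg(format)
  validate_surface_map(map)
  if (format == "vtk") write_map_vtk(map, path) else write_map_bundle(map, path)
  invisible(path)
}

#' Read a surface map from disk
#'
#' Reads either format written by [write_map()]. The two encodings of the
#' same mesh yield identical `surface_map` objects. A file missing a
#' required scalar field (activation, voltage) raises a schema error naming
#' the field; `cutout` and `wall_label` default to all-`FALSE` /
#' `"unlabeled"` when absent. Non-triangular polygon cells raise a format
#' error.
#'
#' @param path file (vtk) or directory (bundle) produced by [write_map()].
#' @param format `"auto"` (directory implies bundle), `"vtk"` or `"bundle"`.
#' @return a validated [surface_map()].
#' @export
read_map <- function(path, format = c("auto", "vtk", "bundle")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file or directory: %s", path))
  if (format == "auto") format <- if (dir.exists(path)) "bundle" else "vtk"
  if (format == "vtk") read_map_vtk(path) else read_map_bundle(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_map_vtk <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(map$vertices)
  m <- nrow(map$triangles)
  meta_json <- as.character(jsonlite::toJSON(map$meta, auto_unbox = TRUE, digits = NA))
  writeLines(c("# vtk DataFile Version 3.0", meta_json, "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(apply(map$vertices, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(paste(3L, map$triangles[, 1] - 1L, map$triangles[, 2] - 1L,
                   map$triangles[, 3] - 1L), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  write_scalar <- function(name, type, values) {
    writeLines(c(sprintf("SCALARS %s %s 1", name, type),
                 "LOOKUP_TABLE default"), con)
    writeLines(if (type == "int") format(values) else fmt_num(values), con)
  }
  write_scalar("activation_ms", "double", map$activation)
  write_scalar("voltage_mV", "double", map$voltage)
  write_scalar("cutout", "int", as.integer(map$cutout))
  write_scalar("wall_label", "int",
               match(map$wall_label, WALL_LEVELS) - 1L)
  invisible(path)
}

read_map_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- tryCatch(jsonlite::fromJSON(lines[2]), error = function(e) list())
  if (!isTRUE(grepl("POLYDATA", lines[4])))
    abort(sprintf("%s: expected DATASET POLYDATA", path))

  i_pts <- grep("^POINTS ", lines)[1]
  if (is.na(i_pts)) abort(sprintf("%s: no POINTS section", path))
  n <- as.integer(strsplit(lines[i_pts], "\\s+")[[1]][2])
  pts <- scan(text = lines[(i_pts + 1):(i_pts + n)], quiet = TRUE)
  vertices <- matrix(pts, ncol = 3, byrow = TRUE)

  i_poly <- grep("^POLYGONS ", lines)[1]
  if (is.na(i_poly)) abort(sprintf("%s: no POLYGONS section", path))
  m <- as.integer(strsplit(lines[i_poly], "\\s+")[[1]][2])
  triangles <- NULL
  if (m > 0) {
    cells <- matrix(scan(text = lines[(i_poly + 1):(i_poly + m)], quiet = TRUE),
                    nrow = m, byrow = TRUE)
    if (ncol(cells) != 4 || any(cells[, 1] != 3))
      abort(sprintf("%s: non-triangular polygon cells are not supported", path))
    triangles <- cells[, 2:4, drop = FALSE] + 1L
  }

  scalars <- list()
  for (i in grep("^SCALARS ", lines)) {
    name <- strsplit(lines[i], "\\s+")[[1]][2]
    off <- if (grepl("^LOOKUP_TABLE", lines[i + 1])) 2L else 1L
    scalars[[name]] <- scan(text = lines[(i + off):(i + off + n - 1)], quiet = TRUE)
  }
  for (req in c("activation_ms", "voltage_mV"))
    if (is.null(scalars[[req]]))
      abort(sprintf("%s: required scalar field '%s' is missing", path, req))

  wall <- if (is.null(scalars$wall_label)) rep("unlabeled", n) else
    WALL_LEVELS[as.integer(scalars$wall_label) + 1L]
  surface_map(
    vertices = vertices, triangles = triangles,
    activation = scalars$activation_ms, voltage = scalars$voltage_mV,
    cutout = if (is.null(scalars$cutout)) NULL else scalars$cutout > 0,
    wall_label = wall, meta = as.list(meta)
  )
}

write_map_bundle <- function(map, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble(x = map$vertices[, 1], y = map$vertices[, 2],
                          z = map$vertices[, 3]),
                   file.path(path, "vertices.csv"))
  readr::write_csv(tibble(v1 = map$triangles[, 1] - 1L,
                          v2 = map$triangles[, 2] - 1L,
                          v3 = map$triangles[, 3] - 1L),
                   file.path(path, "triangles.csv"))
  readr::write_csv(tibble(activation_ms = map$activation,
                          voltage_mV = map$voltage,
                          cutout = as.integer(map$cutout),
                          wall_label = map$wall_label),
                   file.path(path, "scalars.csv"))
  jsonlite::write_json(map$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_map_bundle <- function(path) {
  need <- file.path(path, c("vertices.csv", "triangles.csv", "scalars.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    abort(sprintf("bundle %s is missing: %s", path,
                  paste(basename(missing), collapse = ", ")))
  v <- readr::read_csv(need[1], show_col_types = FALSE)
  tr <- readr::read_csv(need[2], show_col_types = FALSE)
  sc <- readr::read_csv(need[3], show_col_types = FALSE)
  for (req in c("activation_ms", "voltage_mV"))
    if (is.null(sc[[req]]))
      abort(sprintf("%s: required scalar field '%s' is missing",
                    need[3], req))
  meta_file <- file.path(path, "meta.json")
  meta <- if (file.exists(meta_file)) as.list(jsonlite::fromJSON(meta_file)) else list()
  surface_map(
    vertices = as.matrix(v[, c("x", "y", "z")]),
    triangles = as.matrix(tr[, c("v1", "v2", "v3")]) + 1L,
    activation = sc$activation_ms, voltage = sc$voltage_mV,
    cutout = if (is.null(sc$cutout)) NULL else sc$cutout > 0,
    wall_label = sc$wall_label %||% NULL, meta = meta
  )
}
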