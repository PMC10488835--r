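test_that("surface_map validation rejects malformed meshes", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_s3_class(surface_map(v, rbind(c(1, 2, 3)), 1:3, 1:3), "surface_map")
  expect_error(surface_map(v, rbind(c(1, 2, 4)), 1:3, 1:3), "out of range")
  expect_error(surface_map(v, rbind(c(1, 2, 2)), 1:3, 1:3), "degenerate")
  expect_error(surface_map(v, rbind(c(1, 2, 3)), 1:3, c(-1, 1, 1)),
               "voltage")
  expect_error(surface_map(v, rbind(c(1, 2, 3)), 1:2, 1:3), "activation")
  expect_error(surface_map(v, rbind(c(1, 2, 3)), 1:3, 1:3,
                           wall_label = c("anterior", "roof", "septal")),
               "wall_label")
  # collinear vertices give a zero-area triangle
  vz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(surface_map(vz, rbind(c(1, 2, 3)), 1:3, 1:3), "area")
})

test_that("write/read round trip preserves all fields in both formats", {
  map <- tiny_fixture_map()
  for (fmt in c("vtk", "bundle")) {
    path <- file.path(tempdir(), paste0("rt_", fmt))
    write_map(map, path, format = fmt)
    got <- read_map(path)
    expect_identical(got$vertices, map$vertices)
    expect_identical(got$triangles, map$triangles)
    expect_identical(got$activation, map$activation)
    expect_identical(got$voltage, map$voltage)
    expect_identical(got$cutout, map$cutout)
    expect_identical(got$wall_label, map$wall_label)
    expect_equal(got$meta[order(names(got$meta))],
                 map$meta[order(names(map$meta))])
    unlink(path, recursive = TRUE)
  }
})

test_that("legacy-VTK and tabular-bundle encodings agree on the same mesh", {
  map <- tiny_fixture_map()
  p1 <- file.path(tempdir(), "cross.vtk")
  p2 <- file.path(tempdir(), "cross_bundle")
  write_map(map, p1, "vtk")
  write_map(map, p2, "bundle")
  a <- read_map(p1)
  b <- read_map(p2)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$triangles, b$triangles)
  expect_identical(a$activation, b$activation)
  expect_identical(a$voltage, b$voltage)
  expect_identical(a$cutout, b$cutout)
  expect_identical(a$wall_label, b$wall_label)
  unlink(c(p1, p2), recursive = TRUE)
})

test_that("missing scalar fields raise schema errors naming the field", {
  map <- tiny_fixture_map()
  p <- file.path(tempdir(), "broken.vtk")
  write_map(map, p, "vtk")
  lines <- readLines(p)
  i <- grep("SCALARS activation_ms", lines)
  # drop the activation array (header + lookup + values)
  drop <- i:(i + 1 + nrow(map$vertices))
  writeLines(lines[-drop], p)
  expect_error(read_map(p), "activation_ms")
  unlink(p)

  pb <- file.path(tempdir(), "broken_bundle")
  write_map(map, pb, "bundle")
  sc <- readr::read_csv(file.path(pb, "scalars.csv"), show_col_types = FALSE)
  readr::write_csv(sc[setdiff(names(sc), "voltage_mV")],
                   file.path(pb, "scalars.csv"))
  expect_error(read_map(pb), "voltage_mV")
  unlink(pb, recursive = TRUE)
})

test_that("non-triangular polygon cells are a format error", {
  map <- unit_square_map()
  p <- file.path(tempdir(), "quad.vtk")
  write_map(map, p, "vtk")
  lines <- readLines(p)
  i <- grep("^POLYGONS", lines)
  lines[i] <- "POLYGONS 1 5"
  lines <- c(lines[1:i], "4 0 1 2 3", lines[(i + 3):length(lines)])
  writeLines(lines, p)
  expect_error(read_map(p), "non-triangular")
  unlink(p)
})

test_that("surface area is analytic on squares and spheres", {
  expect_equal(surface_area(unit_square_map()), 1.0)
  sph <- ellipsoid_chamber(c(10, 10, 10), subdivisions = 4)
  expect_lt(abs(surface_area(sph) - 4 * pi * 100) / (4 * pi * 100), 0.01)
})

test_that("surface area respects the cutout restriction", {
  map <- unit_square_map()
  map$cutout <- c(TRUE, FALSE, FALSE, FALSE)  # both triangles touch vertex 1
  expect_equal(surface_area(map, restrict_to_non_cutout = TRUE), 0)
  map$cutout <- c(FALSE, FALSE, FALSE, TRUE)  # only the second triangle
  expect_equal(surface_area(map, restrict_to_non_cutout = TRUE), 0.5)
})

test_that("surface area is rigid-invariant and additive", {
  map <- tiny_fixture_map()
  a0 <- surface_area(map)
  th <- c(0.3, 1.1, 2.5)
  for (i in seq_along(th)) {
    rz <- matrix(c(cos(th[i]), -sin(th[i]), 0,
                   sin(th[i]), cos(th[i]), 0, 0, 0, 1), 3, byrow = TRUE)
    moved <- transform_map(map, rz, c(3 * i, -2, 0.5))
    expect_equal(surface_area(moved), a0, tolerance = 1e-12)
  }
  # additivity over a split of the triangle set
  half <- map
  half$triangles <- map$triangles[1:4, ]
  other <- map
  other$triangles <- map$triangles[5:8, ]
  expect_equal(surface_area(half) + surface_area(other), a0)
})

test_that("enclosed volume is analytic, orientation-invariant, unit-correct", {
  cube <- cube_map()
  expect_equal(as.numeric(enclosed_volume(cube)), 0.001)  # 1 mm^3 in mL
  flipped <- cube
  flipped$triangles <- cube$triangles[, c(1, 3, 2)]
  expect_equal(as.numeric(enclosed_volume(flipped)), 0.001)
  sph <- ellipsoid_chamber(rep(26.2, 3), subdivisions = 4)
  truth <- 4 / 3 * pi * 26.2^3 / 1000
  expect_lt(abs(as.numeric(enclosed_volume(sph)) - truth) / truth, 0.01)
  expect_false(attr(enclosed_volume(sph), "open_mesh"))
})

test_that("open meshes give a warned best-effort volume", {
  sheet <- unit_square_map()
  expect_warning(v <- enclosed_volume(sheet), "boundary")
  expect_true(attr(v, "open_mesh"))
})
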