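# Small meshes built in code; no binary fixtures.

# unit square in the z = 0 plane, two triangles
unit_square_map <- function(activation = c(0, 1, 2, 3),
                            voltage = c(1, 1, 1, 1)) {
  surface_map(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    triangles = rbind(c(1, 2, 3), c(1, 3, 4)),
    activation = activation, voltage = voltage
  )
}

# closed unit cube (12 triangles, outward orientation)
cube_map <- function(edge = 1) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)) * edge
  tr <- rbind(c(1, 3, 2), c(1, 4, 3),      # bottom (-z)
              c(5, 6, 7), c(5, 7, 8),      # top (+z)
              c(1, 2, 6), c(1, 6, 5),      # front (-y)
              c(2, 3, 7), c(2, 7, 6),      # right (+x)
              c(3, 4, 8), c(3, 8, 7),      # back (+y)
              c(4, 1, 5), c(4, 5, 8))      # left (-x)
  surface_map(v, tr, activation = seq_len(8), voltage = rep(2, 8))
}

# 10-vertex strip with varied scalar fields, for format round trips
tiny_fixture_map <- function() {
  xs <- seq(0, 4, by = 1)
  v <- rbind(cbind(xs, 0, 0), cbind(xs, 1, 0.5))
  tr <- do.call(rbind, lapply(1:4, function(i)
    rbind(c(i, i + 1, i + 6), c(i, i + 6, i + 5))))
  surface_map(
    v, tr,
    activation = c(0, 1.5, 3, 4.25, 6, 0.5, 2, 3.5, 5, 6.5),
    voltage = c(7, 6.5, 3, 0, 2.25, 8, 5, 4, 1, 0.75),
    cutout = c(rep(FALSE, 9), TRUE),
    wall_label = c(rep("anterior", 5), rep("posterior", 4), "unlabeled"),
    meta = list(map_id = "fix1", animal_id = "pigA", chamber = "LV",
                heart_rate = 101.5, sex = "f")
  )
}

# measurement table built by hand (bypasses the geometry layer)
manual_measurements <- function(cv, va = rep(5, length(cv)),
                                chamber = "RA", animal = "pig1",
                                heart_rate = 90, sex = "m") {
  tibble::tibble(
    map_id = "m1", animal_id = animal, chamber = chamber,
    wall_assignment = NA_character_, heart_rate = heart_rate, sex = sex,
    circle_id = seq_along(cv), area_mm2 = NA_real_, n_points = NA_integer_,
    cv = cv, va = va, valid = TRUE, exclusion_reason = "none"
  )
}

# true fixed-effect vector of the log-cv model implied by a
# simulate_measurements() truth record (LA is the reference level)
true_log_cv_effects <- function(truth) {
  mu <- truth$chamber_log_cv
  c(`(Intercept)` = unname(mu[["LA"]] - 90 * truth$hr_slope_log_cv),
    .locLV = unname(mu[["LV"]] - mu[["LA"]]),
    .locRA = unname(mu[["RA"]] - mu[["LA"]]),
    .locRV = unname(mu[["RV"]] - mu[["LA"]]),
    heart_rate = truth$hr_slope_log_cv)
}
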