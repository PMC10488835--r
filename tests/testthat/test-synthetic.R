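test_that("planar wavefront fields are exact and scale with speed", {
  sh <- flat_sheet(20, 20, 1)
  g1 <- generate_map(map_scenario(sh, wave_planar(c(1, 0, 0), 1), seed = 1))
  # propagation along +x from the x = 0 edge: t = x / v
  expect_equal(g1$map$activation, sh$vertices[, 1], tolerance = 1e-12)
  g2 <- generate_map(map_scenario(sh, wave_planar(c(1, 0, 0), 2), seed = 1))
  expect_equal(g2$map$activation, g1$map$activation / 2, tolerance = 1e-12)
  # focal source: straight-line distance over speed
  gf <- generate_map(map_scenario(sh, wave_focal(c(10, 10, 0), 0.5),
                                  seed = 1))
  d <- sqrt(rowSums(sweep(sh$vertices, 2, c(10, 10, 0))^2))
  expect_equal(gf$map$activation, d / 0.5, tolerance = 1e-12)
})

test_that("generated maps are bitwise reproducible under a fixed seed", {
  sc <- map_scenario(flat_sheet(15, 15, 0.5), wave_planar(c(1, 1, 0), 0.7),
                     voltage_mean = 6, voltage_sd = 2,
                     activation_jitter_sd = 0.2, seed = 99)
  a <- generate_map(sc)
  b <- generate_map(sc)
  expect_identical(a$map$activation, b$map$activation)
  expect_identical(a$map$voltage, b$map$voltage)
  expect_identical(a$truth, b$truth)
})

test_that("scenario cutouts, walls and voltage means are planted as asked", {
  sh <- flat_sheet(30, 30, 1, wall_partition = "quadrants")
  sc <- map_scenario(
    sh, wave_planar(c(1, 0, 0), 0.6),
    voltage_mean = 4, voltage_by_wall = c(anterior = 10, septal = 2),
    cutouts = list(list(center = c(15, 15, 0), radius = 3)),
    seed = 21)
  g <- generate_map(sc)
  d <- sqrt((sh$vertices[, 1] - 15)^2 + (sh$vertices[, 2] - 15)^2)
  expect_identical(g$map$cutout, unname(d <= 3))
  expect_true(all(g$map$voltage[g$map$wall_label == "anterior"] == 10))
  expect_true(all(g$map$voltage[g$map$wall_label == "septal"] == 2))
  expect_true(all(g$map$voltage[g$map$wall_label == "lateral"] == 4))
  # all-covering cutouts are rejected
  bad <- map_scenario(sh, wave_planar(c(1, 0, 0), 0.6),
                      cutouts = list(list(center = c(15, 15, 0),
                                          radius = 1000)), seed = 1)
  expect_error(generate_map(bad), "cutouts cover every vertex")
})

test_that("flat spots plant near-simultaneous activation", {
  sh <- flat_sheet(40, 40, 0.5)
  sc <- map_scenario(sh, wave_planar(c(1, 0, 0), 0.5),
                     flat_spots = list(list(center = c(30, 10, 0),
                                            radius = 12)),
                     seed = 2)
  g <- generate_map(sc)
  ids <- g$truth$flat_spot_vertices
  expect_gt(length(ids), 0)
  expect_lt(diff(range(g$map$activation[ids])), 1e-9)
  # a circle inside the flat spot has (near) zero spread -> excluded
  m <- measure_circles(cover_map(g$map, radius = 5, spacing = 5, seed = 3),
                       g$map$meta)
  m <- apply_outlier_filter(m)
  expect_gt(sum(!m$valid), 0)
})

test_that("full pipeline on a planar-wave sheet recovers 0.6 m/s", {
  sh <- flat_sheet(40, 40, 0.5)
  g <- generate_map(map_scenario(sh, wave_planar(c(1, 2, 0), 0.6),
                                 voltage_mean = 7, seed = 4))
  m <- measure_circles(cover_map(g$map, radius = 5, spacing = 5, seed = 5),
                       g$map$meta)
  expect_lt(abs(stats::median(m$cv, na.rm = TRUE) - 0.6) / 0.6, 0.02)
  expect_equal(mean(m$va), 7, tolerance = 1e-9)
})

test_that("the reference study layout matches the printed inventory", {
  inv <- reference_map_inventory()
  expect_equal(nrow(inv), 21)
  des <- reference_map_design()
  expect_equal(nrow(des), 21)
  expect_equal(length(unique(des$animal_id)), 4)
  expect_setequal(unique(des$chamber), c("RA", "LA", "RV", "LV"))
  expect_equal(sort(unique(des$sex)), c("f", "m"))
  # RA rows carry no anterior circles; ventricles no superior circles
  expect_true(all(is.na(inv$circles_anterior[inv$location == "RA"])))
  expect_true(all(is.na(inv$circles_superior[inv$location %in% c("RV", "LV")])))
})

test_that("measurement simulation is deterministic with a recoverable truth", {
  a <- simulate_measurements(circles_per_map = 10, seed = 55)
  b <- simulate_measurements(circles_per_map = 10, seed = 55)
  expect_identical(a, b)
  tr <- attr(a, "truth")
  expect_named(tr$chamber_log_cv, c("RA", "LA", "RV", "LV"))
  expect_equal(tr$seed, 55)
  expect_equal(length(tr$animal_intercepts_log_cv), 4)
  expect_error(simulate_measurements(
    design = dplyr::filter(reference_map_design(), animal_id == "pig1")),
    "2 animals")
})

test_that("study generation applies hierarchy on the planted scales", {
  des <- tibble::tibble(animal_id = rep(c("a1", "a2"), each = 2),
                        map_id = paste0("m", 1:4),
                        chamber = "LV", heart_rate = 90, sex = "m")
  st <- generate_study(design = des, subdivisions = 1,
                       animal_sd_log_cv = 0, animal_sd_va = 0,
                       voltage_sd = 0, seed = 3)
  # zero random-intercept sd at the reference heart rate: every map gets
  # the chamber's true speed and voltage mean
  expect_equal(st$truth$true_speed, rep(0.59, 4), tolerance = 1e-12)
  expect_equal(st$truth$true_voltage_mean, rep(10.98, 4), tolerance = 1e-12)
  expect_error(generate_study(design = des[des$animal_id == "a1", ]),
               "2 animals")
  # determinism of the whole dataset
  st2 <- generate_study(design = des, subdivisions = 1,
                        animal_sd_log_cv = 0, animal_sd_va = 0,
                        voltage_sd = 0, seed = 3)
  expect_identical(st$truth, st2$truth)
  expect_identical(st$maps[["m1"]]$activation, st2$maps[["m1"]]$activation)
})

test_that("study-scale simulation recovers the planted chamber ordering", {
  nrep <- 40
  ok <- vapply(seq_len(nrep), function(i) {
    m <- simulate_measurements(circles_per_map = 131, seed = 7000 + i)
    fit <- suppressMessages(fit_mixed_model(m, "log_cv"))
    td <- tidy(fit)
    mu <- c(LA = 0,
            LV = td$estimate[td$term == ".locLV"],
            RA = td$estimate[td$term == ".locRA"],
            RV = td$estimate[td$term == ".locRV"])
    identical(names(sort(mu, decreasing = TRUE)),
              c("LA", "LV", "RV", "RA"))
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})
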