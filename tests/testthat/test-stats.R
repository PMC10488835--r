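test_that("noiseless hierarchical data identifies the fixed effects", {
  m <- simulate_measurements(circles_per_map = 12, animal_sd_log_cv = 0,
                             resid_sd_log_cv = 1e-8, seed = 3)
  fit <- suppressWarnings(suppressMessages(fit_mixed_model(m, "log_cv")))
  expect_true(fit$singular)  # zero random-intercept variance, flagged not fatal
  td <- tidy(fit)
  truth <- true_log_cv_effects(attr(m, "truth"))
  expect_equal(td$estimate[match(names(truth), td$term)], unname(truth),
               tolerance = 1e-5)
})

test_that("degenerate designs are rejected with clear errors", {
  m <- simulate_measurements(circles_per_map = 10, seed = 1)
  one_animal <- dplyr::filter(m, animal_id == "pig1")
  expect_error(fit_mixed_model(one_animal, "log_cv"), "2 animals")
  neg <- manual_measurements(cv = c(-1, 0.5, 0.7, 0.8))
  neg$animal_id <- c("a", "a", "b", "b")
  expect_error(fit_mixed_model(neg, "log_cv"), "cv > 0")
  expect_error(sex_effect_test(dplyr::filter(m, sex == "m"), "log_cv"),
               "both sexes")
})

test_that("EMMs at the reference heart rate recover planted chamber means", {
  m <- simulate_measurements(seed = 7)
  truth <- attr(m, "truth")
  fit <- fit_mixed_model(m, "log_cv")
  e <- emm_at(fit, heart_rate = 90)
  want <- exp(truth$chamber_log_cv[e$chamber])
  expect_true(all(abs(e$estimate - want) <= 2 * e$se))
  # back-transformed estimates are positive with positive SEs
  expect_true(all(e$estimate > 0 & e$se > 0))
  # voltage response on the identity scale
  fitv <- fit_mixed_model(m, "va")
  ev <- emm_at(fitv, heart_rate = 90)
  expect_true(all(abs(ev$estimate - truth$chamber_va[ev$chamber]) <=
                    2.5 * ev$se))
})

test_that("EMM back-transform is exp of the log-scale EMM", {
  m <- simulate_measurements(circles_per_map = 25, seed = 11)
  fit <- fit_mixed_model(m, "log_cv")
  link <- as.data.frame(summary(emmeans::emmeans(
    fit$fit, ".loc", at = list(heart_rate = 90),
    lmer.df = "satterthwaite")))
  e <- emm_at(fit, heart_rate = 90)
  expect_equal(e$estimate, exp(link$emmean), tolerance = 1e-10)
  # delta-method SE on the response scale
  expect_equal(e$se, exp(link$emmean) * link$SE, tolerance = 1e-10)
})

test_that("a zero planted heart-rate slope leaves EMMs rate-invariant", {
  m <- simulate_measurements(circles_per_map = 12, hr_slope_log_cv = 0,
                             animal_sd_log_cv = 0, resid_sd_log_cv = 1e-8,
                             seed = 5)
  # the near-noiseless fit sits on the variance boundary; convergence
  # chatter is expected there
  fit <- suppressWarnings(suppressMessages(fit_mixed_model(m, "log_cv")))
  e90 <- emm_at(fit, heart_rate = 90)
  e60 <- suppressWarnings(emm_at(fit, heart_rate = 60))
  expect_equal(e90$estimate, e60$estimate, tolerance = 1e-5)
  # and extrapolation outside the observed range warns
  expect_warning(emm_at(fit, heart_rate = 30), "outside")
})

test_that("identical groups give ratio 1 and p = 1", {
  base <- simulate_measurements(
    design = tibble::tibble(animal_id = rep(c("a", "b", "c", "d"), 2),
                            map_id = paste0("m", 1:8),
                            chamber = "RA", heart_rate = 90, sex = "m"),
    circles_per_map = 125, chamber_log_cv = c(RA = log(0.6)),
    chamber_va = c(RA = 6), resid_sd_log_cv = 0.06, seed = 13)
  # duplicate every row under a second chamber label: the two groups are
  # literally the same data, so the contrast is exactly zero
  dup <- base
  dup$chamber <- "LA"
  both <- dplyr::bind_rows(base, dup)
  fit <- fit_mixed_model(both, "log_cv")
  ct <- pairwise_contrasts(fit, adjust = "tukey")
  expect_equal(ct$ratio, 1, tolerance = 1e-12)
  expect_gt(ct$p_value, 0.9)
})

test_that("all-pairs contrasts have k(k-1)/2 rows and honest adjustment", {
  m <- simulate_measurements(circles_per_map = 30, seed = 17)
  fit <- fit_mixed_model(m, "log_cv")
  tk <- pairwise_contrasts(fit, adjust = "tukey")
  expect_equal(nrow(tk), 6)  # 4 chambers
  raw <- pairwise_contrasts(fit, adjust = "none")
  expect_true(all(tk$p_value >= raw$p_value - 1e-12))
  expect_true(all(tk$p_value <= 1))
  # log-scale contrasts surface as velocity ratios
  expect_true(all(grepl(" / ", tk$contrast)))
  expect_true(all(tk$ratio > 0))
  # voltage contrasts stay on the mV difference scale
  fv <- fit_mixed_model(m, "va")
  dv <- pairwise_contrasts(fv, adjust = "tukey")
  expect_true("difference" %in% names(dv))
})

test_that("targeted contrasts apply the closed-form Sidak adjustment", {
  m <- simulate_measurements(circles_per_map = 30, seed = 19)
  fit <- fit_mixed_model(m, "log_cv")
  raw <- pairwise_contrasts(fit, adjust = "none")
  pick <- raw$contrast[c(1, 4)]
  tg <- pairwise_contrasts(fit, which = "targeted", targeted = pick,
                           adjust = "sidak")
  expect_equal(nrow(tg), 2)
  want <- sidak_adjust(raw$p_value[c(1, 4)], m = 2)
  expect_equal(tg$p_value, want, tolerance = 1e-12)
  expect_true(all(tg$p_value >= raw$p_value[c(1, 4)] - 1e-12))
  expect_error(pairwise_contrasts(fit, which = "targeted",
                                  targeted = "XX / YY"), "matched")
})

test_that("single-level factors yield an empty contrast table", {
  m <- simulate_measurements(
    design = tibble::tibble(animal_id = c("a", "a", "b", "b"),
                            map_id = paste0("m", 1:4), chamber = "LV",
                            heart_rate = c(80, 95, 88, 102), sex = "m"),
    circles_per_map = 20, chamber_log_cv = c(LV = log(0.6)),
    chamber_va = c(LV = 9), seed = 2)
  fit <- fit_mixed_model(m, "log_cv")
  expect_equal(nrow(pairwise_contrasts(fit)), 0)
})

test_that("correlation follows the r(df) reporting convention", {
  d <- manual_measurements(cv = seq(0.2, 1.4, length.out = 30),
                           va = 2 + 3 * seq(0.2, 1.4, length.out = 30))
  res <- pearson_correlation(d)
  expect_equal(res$r, 1)
  expect_equal(res$df, 28)  # n - 2
  expect_equal(res$interpretation, "positive linear correlation")
  flat <- manual_measurements(cv = seq(0.2, 1.4, length.out = 30),
                              va = rep(5, 30))
  expect_error(pearson_correlation(flat), "constant")
  expect_error(pearson_correlation(d[1:2, ]), "at least 3")
})

test_that("weak correlations are labelled 'no linear correlation'", {
  set.seed(23)
  n <- 2000
  x <- rnorm(n)
  y <- 0.05 * x + rnorm(n)  # true rho ~ 0.05, well under 0.2
  d <- manual_measurements(cv = exp(x / 4), va = 5 + y)
  res <- pearson_correlation(d)
  expect_lt(abs(res$r), 0.2)
  expect_equal(res$interpretation, "no linear correlation")
  expect_equal(res$df, n - 2)
})

test_that("cv_cap restricts the correlated subset and its df", {
  m <- simulate_measurements(seed = 29)
  capped <- pearson_correlation(m, "overall", cv_cap = 1.5)
  full <- pearson_correlation(m, "overall")
  expect_lt(capped$n, full$n)
  expect_equal(capped$df, capped$n - 2)
  per <- pearson_correlation(m, "per_chamber", cv_cap = 1.5)
  expect_setequal(per$chamber, c("RA", "LA", "RV", "LV"))
})

test_that("a large planted sex effect is detected with high power", {
  m <- simulate_measurements(circles_per_map = 40,
                             sex_effect_log_cv = 5 * 0.30, seed = 31)
  p <- as.numeric(sex_effect_test(m, "log_cv"))
  expect_lt(p, 0.001)
})

test_that("sex p-values are calibrated under the null", {
  design <- tibble::tibble(
    animal_id = rep(paste0("a", 1:6), each = 4),
    map_id = paste0("m", 1:24),
    chamber = rep(c("RA", "LA", "RV", "LV"), 6),
    heart_rate = rep(c(85, 95, 105, 120, 90, 110), each = 4),
    sex = rep(c("m", "f"), each = 4, length.out = 24)
  )
  nrep <- 200
  ps <- vapply(seq_len(nrep), function(i) {
    m <- simulate_measurements(design = design, circles_per_map = 15,
                               sex_effect_log_cv = 0, seed = 5000 + i)
    as.numeric(suppressMessages(sex_effect_test(m, "log_cv")))
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
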