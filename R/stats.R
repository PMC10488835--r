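# Mixed-effects comparison of conduction velocity and voltage amplitude.
#
# The model: response ~ location + heart_rate + (1 | animal), fitted by
# REML. Velocity is analysed on the natural-log scale (and reported
# back-transformed as m/s and as ratios), voltage on the mV scale.
# Group means are compared through estimated marginal means evaluated at a
# reference heart rate of 90 bpm, with Tukey's HSD for all-pairs and Sidak
# for targeted contrast sets. Inference uses Satterthwaite denominator
# degrees of freedom (lmerTest), with a normal-approximation fallback.

#' Fit the chamber/wall mixed-effects model
#'
#' REML fit of `log(cv)` (or `va`) on a location factor and heart rate,
#' with a random intercept per animal absorbing inter-individual
#' variation. Only rows with `valid == TRUE` enter the fit — apply
#' [apply_outlier_filter()] first. A singular fit (random-intercept
#' variance estimated at zero) is flagged, not fatal; a rank-deficient
#' fixed-effects design is an error.
#'
#' @param measurements measurement tibble ([measure_circles()] /
#'   [simulate_measurements()] output, possibly many maps bound together).
#' @param response `"log_cv"` (natural log of conduction velocity) or
#'   `"va"` (voltage amplitude in mV).
#' @param location name of the stratifying column: `"chamber"` (default)
#'   or `"wall_assignment"`.
#' @param include_sex add sex as a fixed effect?
#' @param df_method `"satterthwaite"` (default) or `"normal"` (z-based
#'   fallback).
#' @return an `eamap_mixed_model`: list with the `lmerTest` fit (`$fit`),
#'   the model frame (`$data`), `response`, `location`, `singular`,
#'   `df_method`.
#' @export
fit_mixed_model <- function(measurements,
                            response = c("log_cv", "va"),
                            location = "chamber",
                            include_sex = FALSE,
                            df_method = c("satterthwaite", "normal")) {
  response <- match.arg(response)
  df_method <- match.arg(df_method)
  d <- filter(measurements, .data$valid)
  if (!location %in% names(d))
    abort(sprintf("no column '%s' in measurements", location))
  d <- filter(d, !is.na(.data[[location]]), !is.na(.data$heart_rate))
  if (response == "log_cv") {
    d <- filter(d, !is.na(.data$cv))
    if (any(d$cv <= 0)) abort("log_cv requires all cv > 0")
    d$.y <- log(d$cv)
  } else {
    d <- filter(d, !is.na(.data$va))
    d$.y <- d$va
  }
  if (length(unique(d$animal_id)) < 2)
    abort("mixed model needs >= 2 animals (random intercept unidentifiable)")
  if (include_sex && length(unique(d$sex)) < 2)
    abort("sex effect requires both sexes in the data")
  d$.loc <- factor(d[[location]])
  d$.animal <- factor(d$animal_id)

  loc_terms <- if (nlevels(d$.loc) >= 2) ".loc + " else ""
  fml <- stats::as.formula(sprintf(".y ~ %sheart_rate%s + (1 | .animal)",
                                   loc_terms,
                                   if (include_sex) " + sex" else ""))
  fit <- lmerTest::lmer(fml, data = d, REML = TRUE)
  X <- lme4::getME(fit, "X")
  if (qr(X)$rank < ncol(X))
    abort("fixed-effects design is rank deficient")
  structure(list(fit = fit, data = d, response = response,
                 location = location, include_sex = include_sex,
                 df_method = df_method,
                 singular = lme4::isSingular(fit)),
            class = "eamap_mixed_model")
}

#' @export
print.eamap_mixed_model <- function(x, ...) {
  cat(sprintf("<eamap_mixed_model> %s ~ %s + heart_rate%s + (1 | animal)\n",
              if (x$response == "log_cv") "log(cv)" else "va",
              x$location, if (x$include_sex) " + sex" else ""))
  cat(sprintf("  %d circles, %d animals, %d %s levels%s\n",
              nrow(x$data), nlevels(x$data$.animal), nlevels(x$data$.loc),
              x$location,
              if (x$singular) " [singular fit: zero random-intercept variance]"
              else ""))
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  cat(sprintf("  random-intercept sd %.4f, residual sd %.4f\n",
              vc$sdcor[1], vc$sdcor[nrow(vc)]))
  invisible(x)
}

emm_df_mode <- function(model) {
  if (model$df_method == "satterthwaite") "satterthwaite" else "asymptotic"
}

#' Estimated marginal means at a reference heart rate
#'
#' Per-location linear predictor evaluated at the reference heart rate
#' (90 bpm by default, the study's reporting convention). For the log-CV
#' model the estimate and its delta-method standard error are
#' back-transformed to m/s. Requesting a heart rate outside the observed
#' range triggers an extrapolation warning.
#'
#' @param model an [fit_mixed_model()] result.
#' @param heart_rate reference heart rate in bpm.
#' @param level confidence level for the interval columns.
#' @return a tibble: location level, `estimate` (m/s or mV), `se`, `df`,
#'   `lower`, `upper`.
#' @export
emm_at <- function(model, heart_rate = 90, level = 0.95) {
  rng <- range(model$data$heart_rate)
  if (heart_rate < rng[1] || heart_rate > rng[2])
    warn(sprintf("heart rate %g bpm is outside the observed range [%g, %g]: extrapolating",
                 heart_rate, rng[1], rng[2]))
  single <- nlevels(model$data$.loc) < 2
  em <- emmeans::emmeans(model$fit, if (single) "1" else ".loc",
                         at = list(heart_rate = heart_rate),
                         lmer.df = emm_df_mode(model))
  if (model$response == "log_cv") {
    # the response entered the fit as log(cv); declare the transform so the
    # estimate and delta-method SE are reported back on the m/s scale
    em <- update(em, tran = "log")
    s <- as.data.frame(summary(em, type = "response", level = level))
  } else {
    s <- as.data.frame(summary(em, level = level))
  }
  est_col <- intersect(c("response", "emmean"), names(s))[1]
  lcl <- intersect(c("lower.CL", "asymp.LCL"), names(s))[1]
  ucl <- intersect(c("upper.CL", "asymp.UCL"), names(s))[1]
  loc_val <- if (single) rep(levels(model$data$.loc), nrow(s))
             else as.character(s$.loc)
  tibble(!!model$location := loc_val,
         estimate = s[[est_col]], se = s$SE, df = s$df,
         lower = s[[lcl]], upper = s[[ucl]],
         heart_rate = heart_rate)
}

#' Adjusted pairwise contrasts between locations
#'
#' All-pairs contrasts of the location EMMs adjusted by Tukey's
#' studentized-range criterion, or a targeted subset adjusted by Sidak.
#' For the log-CV model contrasts are reported as ratios of velocities
#' (back-transformed log differences); for voltage as differences in mV.
#'
#' @param model an [fit_mixed_model()] result.
#' @param which `"all_pairs"` or `"targeted"`.
#' @param targeted for `which = "targeted"`: character vector of contrast
#'   labels to keep, matched against the `"A / B"` / `"A - B"` labels of
#'   the all-pairs set (e.g. `c("RA / LA", "RV / LV")`).
#' @param adjust `"tukey"` (default for all pairs) or `"sidak"` (default
#'   for targeted sets).
#' @param heart_rate reference heart rate in bpm.
#' @return a tibble: `contrast`, `ratio` or `difference`, `se`, `df`,
#'   `p_value`, `adjust`.
#' @export
pairwise_contrasts <- function(model, which = c("all_pairs", "targeted"),
                               targeted = NULL, adjust = NULL,
                               heart_rate = 90) {
  which <- match.arg(which)
  if (is.null(adjust)) adjust <- if (which == "all_pairs") "tukey" else "sidak"
  adjust <- match.arg(adjust, c("tukey", "sidak", "none"))
  if (nlevels(model$data$.loc) < 2)
    return(tibble(contrast = character(0), estimate = numeric(0),
                  se = numeric(0), df = numeric(0), p_value = numeric(0),
                  adjust = character(0)))
  em <- emmeans::emmeans(model$fit, ".loc",
                         at = list(heart_rate = heart_rate),
                         lmer.df = emm_df_mode(model))
  log_scale <- model$response == "log_cv"
  prs <- emmeans::contrast(em, method = "pairwise", adjust = "none")
  if (which == "targeted") {
    if (is.null(targeted) || !length(targeted))
      abort("which = 'targeted' needs a vector of contrast labels")
    s <- as.data.frame(summary(prs, adjust = "none"))
    labs <- as.character(s$contrast)
    keep <- labs %in% targeted | gsub(" - ", " / ", labs) %in% targeted
    if (!any(keep)) abort("no targeted contrasts matched the all-pairs labels")
    s <- s[keep, , drop = FALSE]
    if (adjust == "sidak") {
      s$p.value <- sidak_adjust(s$p.value, m = sum(keep))
    } else if (adjust == "tukey") {
      abort("use adjust = 'sidak' (or 'none') for targeted contrast sets")
    }
  } else {
    s <- as.data.frame(summary(prs, adjust = adjust))
  }
  est <- if (log_scale) exp(s$estimate) else s$estimate
  se <- if (log_scale) abs(est) * s$SE else s$SE  # delta method on exp
  out <- tibble(contrast = if (log_scale) gsub(" - ", " / ", s$contrast)
                           else as.character(s$contrast),
                estimate = est, se = se, df = s$df,
                p_value = s$p.value, adjust = adjust)
  names(out)[2] <- if (log_scale) "ratio" else "difference"
  out
}

#' Pearson correlation of conduction velocity and voltage amplitude
#'
#' Pearson's r on valid (cv, va) pairs, overall or per chamber, with the
#' study's reporting convention: degrees of freedom `n - 2`, and the
#' interpretation "no linear correlation" whenever `|r| < 0.2` regardless
#' of significance. `cv_cap` restricts to slow circles (`cv < cap`),
#' e.g. the < 1.5 m/s range where slow conduction and low voltage travel
#' together.
#'
#' @param measurements measurement tibble; invalid rows are dropped.
#' @param scope `"overall"` or `"per_chamber"`.
#' @param cv_cap optional m/s cap; only circles with `cv < cv_cap` enter.
#' @return a tibble: `scope`, `chamber` (NA for overall), `r`, `df`,
#'   `p_value`, `n`, `interpretation`.
#' @export
pearson_correlation <- function(measurements,
                                scope = c("overall", "per_chamber"),
                                cv_cap = NULL) {
  scope <- match.arg(scope)
  d <- filter(measurements, .data$valid, !is.na(.data$cv), !is.na(.data$va))
  if (!is.null(cv_cap)) d <- filter(d, .data$cv < cv_cap)
  one <- function(sub, chamber) {
    if (nrow(sub) < 3)
      abort("Pearson correlation needs at least 3 (cv, va) pairs")
    if (stats::sd(sub$cv) == 0 || stats::sd(sub$va) == 0)
      abort("Pearson correlation undefined for constant input")
    ct <- stats::cor.test(sub$cv, sub$va, method = "pearson")
    r <- unname(ct$estimate)
    tibble(scope = if (is.na(chamber)) "overall" else "per_chamber",
           chamber = chamber, r = r, df = unname(ct$parameter),
           p_value = ct$p.value, n = nrow(sub),
           interpretation = if (abs(r) < 0.2) "no linear correlation"
           else if (r > 0) "positive linear correlation"
           else "negative linear correlation")
  }
  if (scope == "overall") return(one(d, NA_character_))
  bind_rows(lapply(split(d, d$chamber),
                   function(sub) one(sub, sub$chamber[1])))
}

#' Test for a sex effect
#'
#' Refits the mixed model with sex added as a fixed effect and returns the
#' p-value of the sex term (Satterthwaite-t by default).
#'
#' @inheritParams fit_mixed_model
#' @return single p-value, with the refitted model as attribute `model`.
#' @export
sex_effect_test <- function(measurements, response = c("log_cv", "va"),
                            location = "chamber",
                            df_method = c("satterthwaite", "normal")) {
  response <- match.arg(response)
  df_method <- match.arg(df_method)
  m <- fit_mixed_model(measurements, response = response,
                       location = location, include_sex = TRUE,
                       df_method = df_method)
  co <- as.data.frame(stats::coef(summary(m$fit)))
  sex_rows <- grep("^sex", rownames(co))
  if (!length(sex_rows)) abort("no sex coefficient in the fitted model")
  if (df_method == "normal") {
    z <- co$`t value`[sex_rows[1]]
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    p <- co$`Pr(>|t|)`[sex_rows[1]]
  }
  structure(p, model = m)
}

#' Sidak adjustment (closed form)
#'
#' `p_adj = 1 - (1 - p)^m` for `m` simultaneous tests — the reference
#' formula the targeted-contrast adjustment is checked against.
#'
#' @param p vector of raw p-values.
#' @param m number of tests (default `length(p)`).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

# ---- broom-style methods ---------------------------------------------------

#' Tidy a fitted chamber/wall mixed model
#'
#' @param x an `eamap_mixed_model`.
#' @param effects `"fixed"` for fixed-effect coefficients,
#'   `"ran_pars"` for variance components.
#' @param ... unused.
#' @return a tibble of coefficient estimates (fixed: `term`, `estimate`,
#'   `std_error`, `df`, `statistic`, `p_value`) or variance components.
#' @method tidy eamap_mixed_model
#' @export
tidy.eamap_mixed_model <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    co <- as.data.frame(stats::coef(summary(x$fit)))
    tibble(term = rownames(co), estimate = co$Estimate,
           std_error = co$`Std. Error`,
           df = if ("df" %in% names(co)) co$df else NA_real_,
           statistic = co$`t value`,
           p_value = if ("Pr(>|t|)" %in% names(co)) co$`Pr(>|t|)` else NA_real_)
  } else {
    vc <- as.data.frame(lme4::VarCorr(x$fit))
    tibble(group = vc$grp, term = ifelse(is.na(vc$var1), "sd", vc$var1),
           variance = vc$vcov, sd = vc$sdcor)
  }
}

#' Glance at a fitted chamber/wall mixed model
#'
#' @param x an `eamap_mixed_model`.
#' @param ... unused.
#' @return a one-row tibble: observations, group count, variance
#'   components, REML criterion, singularity flag.
#' @method glance eamap_mixed_model
#' @export
glance.eamap_mixed_model <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble(n_obs = nrow(x$data),
         n_animals = nlevels(x$data$.animal),
         response = x$response,
         random_intercept_variance = vc$vcov[1],
         residual_variance = vc$vcov[nrow(vc)],
         reml_criterion = as.numeric(lme4::REMLcrit(x$fit)),
         singular = x$singular)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
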