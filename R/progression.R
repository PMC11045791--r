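#' Fit the longitudinal UPDRS-III mixed model
#'
#' Fits, by REML, a linear mixed model of the UPDRS-III total on the fixed
#' covariates (age at diagnosis, race/ethnicity, gender, PD duration at
#' baseline, PD family history, school years, study wave) and visit index,
#' with a correlated random intercept and random visit slope per subject
#' (unstructured 2x2 covariance). The empirical-Bayes (BLUP) slope per
#' subject is the fixed visit coefficient plus the conditional mode of the
#' subject's random slope. Subjects with a single visit are retained in the
#' fit; their EB slopes are strongly shrunken toward the population slope.
#'
#' Boundary (singular) fits — e.g. an estimated slope variance of zero —
#' are legitimate and returned as-is; only genuine optimizer
#' non-convergence raises an error, with the optimizer diagnostics in the
#' message.
#'
#' @param visits Tibble with `subject_id`, `visit` (integer, from 0) and
#'   `updrs3`.
#' @param subjects Subject covariate table (`subject_id`, `age_dx`,
#'   `ancestry`, `sex`, `pd_duration`, `family_history`,
#'   `education_years`, `wave`).
#' @return A list with `fit` (the `lmerMod`), `eb` (tibble: `subject_id`,
#'   `eb_slope`, `n_visits`), and `varcomp` (tibble of the REML variance
#'   components: `intercept_sd`, `slope_sd`, `corr`, `resid_sd`).
#' @export
fit_progression <- function(visits, subjects) {
  nv <- table(visits$subject_id)
  if (sum(nv >= 2) < 2) {
    stop("variance components unidentifiable: need at least 2 subjects ",
         "with at least 2 visits", call. = FALSE)
  }
  dat <- dplyr::inner_join(visits, subjects, by = "subject_id")
  dat$wave <- factor(dat$wave)
  covs <- c("age_dx", "ancestry", "sex", "pd_duration", "family_history",
            "education_years", "wave")
  covs <- covs[vapply(covs, function(v) length(unique(dat[[v]])) > 1,
                      logical(1))]
  form <- stats::reformulate(c(covs, "visit", "(1 + visit | subject_id)"),
                             response = "updrs3")
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code != 0) {
    stop("mixed-model fit did not converge: ",
         paste(unlist(conv$messages), collapse = "; "), call. = FALSE)
  }

  re <- lme4::ranef(fit)$subject_id
  eb <- tibble(subject_id = rownames(re),
               eb_slope = lme4::fixef(fit)[["visit"]] + re[["visit"]],
               n_visits = as.integer(nv[rownames(re)]))
  vc <- lme4::VarCorr(fit)$subject_id
  varcomp <- tibble(
    intercept_sd = sqrt(vc[1, 1]), slope_sd = sqrt(vc[2, 2]),
    corr = if (vc[1, 1] > 0 && vc[2, 2] > 0) {
      vc[1, 2] / sqrt(vc[1, 1] * vc[2, 2])
    } else NA_real_,
    resid_sd = attr(lme4::VarCorr(fit), "sc"))
  list(fit = fit, eb = eb, varcomp = varcomp)
}

#' Residualize EB slopes on covariates and build progression scores
#'
#' Regresses the empirical-Bayes slopes on the same fixed covariates by
#' ordinary least squares and takes the residuals as the progression
#' measure (centred by construction). The display score anchors the cohort
#' mean at 1 and the SD at 1:
#' `display_score = 1 + residual / SD(residual)`.
#' Collinear design columns are dropped (with a warning) rather than
#' failing.
#'
#' @param eb EB slope tibble from [fit_progression()].
#' @param subjects Subject covariate table.
#' @param cohort_ids Subjects over which to residualize and scale
#'   (defaults to all subjects in `eb`).
#' @param min_visits Minimum visit count for a subject to receive a score
#'   (default 2: a single examination cannot anchor an individual slope).
#' @return A tibble with `subject_id`, `eb_slope`, `residual`,
#'   `display_score`, `n_visits`.
#' @export
residualize_slopes <- function(eb, subjects, cohort_ids = NULL,
                               min_visits = 2) {
  dat <- dplyr::inner_join(eb, subjects, by = "subject_id")
  dat <- dat[dat$n_visits >= min_visits, ]
  if (!is.null(cohort_ids)) dat <- dat[dat$subject_id %in% cohort_ids, ]
  if (nrow(dat) < 2) {
    stop("fewer than 2 subjects with a progression score", call. = FALSE)
  }
  dat$wave <- factor(dat$wave)
  covs <- c("age_dx", "ancestry", "sex", "pd_duration", "family_history",
            "education_years", "wave")
  covs <- covs[vapply(covs, function(v) length(unique(dat[[v]])) > 1,
                      logical(1))]
  form <- if (length(covs)) {
    stats::reformulate(covs, response = "eb_slope")
  } else {
    eb_slope ~ 1
  }
  ols <- lm(form, data = dat)
  if (anyNA(coef(ols))) {
    warning("rank-deficient covariate design; collinear column(s) dropped",
            call. = FALSE)
  }
  dat$residual <- unname(resid(ols))
  s <- sd(dat$residual)
  dat$display_score <- if (is.na(s) || s == 0) {
    1
  } else {
    1 + dat$residual / s
  }
  dplyr::arrange(
    dat[, c("subject_id", "eb_slope", "residual", "display_score",
            "n_visits")],
    .data$subject_id)
}

#' One-call progression scoring
#'
#' Convenience wrapper: [fit_progression()] then [residualize_slopes()].
#'
#' @inheritParams fit_progression
#' @inheritParams residualize_slopes
#' @return The [residualize_slopes()] tibble, with the model fit attached
#'   as attribute `"fit"` and variance components as `"varcomp"`.
#' @export
progression_scores <- function(visits, subjects, cohort_ids = NULL,
                               min_visits = 2) {
  m <- fit_progression(visits, subjects)
  out <- residualize_slopes(m$eb, subjects, cohort_ids = cohort_ids,
                            min_visits = min_visits)
  attr(out, "fit") <- m$fit
  attr(out, "varcomp") <- m$varcomp
  out
}
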