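#' Generate synthetic subjects and longitudinal UPDRS-III visits
#'
#' Draws a cohort of PD patients with demographics, covariates and
#' longitudinal motor examinations. Each subject receives a true random
#' intercept and a true random visit slope (bivariate normal at the
#' configured SDs and correlation); the observed UPDRS-III total at visit
#' \eqn{t} is the fixed-effect linear predictor plus
#' \eqn{b_{0i} + b_{1i} t} plus residual noise. The baseline visit (index 0)
#' is always observed; each follow-up visit is retained independently with
#' probability `config$retention`, so some subjects contribute a single
#' visit only.
#'
#' Ground truth (the true slopes and intercepts) is returned alongside the
#' tables so downstream empirical-Bayes estimates can be checked against it.
#'
#' @param config A [sim_config()] object.
#' @return A list with `subjects` (one row per subject), `visits` (one row
#'   per observed visit: `subject_id`, `visit`, `updrs3`), and `truth` (a
#'   tibble of `subject_id`, `true_intercept`, `true_slope`).
#' @export
#' @examples
#' sim <- simulate_subjects(sim_config(n_subjects = 20))
#' head(sim$visits)
simulate_subjects <- function(config) {
  validate_sim_config(config)
  n <- config$n_subjects
  labels <- names(config$subpop_fractions)
  id <- sprintf("S%04d", seq_len(n))

  ancestry <- labels[sample.int(length(labels), n, replace = TRUE,
                                prob = config$subpop_fractions)]
  sex <- sample(c("Male", "Female"), n, replace = TRUE, prob = c(0.62, 0.38))
  age_dx <- pmin(pmax(round(rnorm(n, 67.7, 10.6), 1), 23), 89)
  years <- seq(config$dx_year_range[1], config$dx_year_range[2])
  dx_year <- years[sample.int(length(years), n, replace = TRUE)]
  dx_year[runif(n) < config$missing_dxyear_frac] <- NA_integer_
  education_years <- sample(6:20, n, replace = TRUE)
  family_history <- rbinom(n, 1, 0.15)
  wave <- sample(1:2, n, replace = TRUE, prob = c(0.55, 0.45))
  pd_duration <- round(pmin(abs(rnorm(n, 2.9, 2.5)), 12), 1)
  zero_exposure <- runif(n) < config$zero_exposure_frac

  subjects <- tibble(
    subject_id = id, ancestry = ancestry, sex = sex, age_dx = age_dx,
    dx_year = dx_year, education_years = education_years,
    family_history = family_history, wave = wave,
    pd_duration = pd_duration, zero_exposure = zero_exposure)

  ## true random effects: bivariate normal via Cholesky of the 2x2 G
  rho <- config$slope_intercept_corr
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  b0 <- config$intercept_sd * z1
  b1 <- config$slope_sd * (rho * z1 + sqrt(max(0, 1 - rho^2)) * z2)

  fe <- config$fixed_effects
  fe_get <- function(nm) if (is.null(fe[[nm]])) 0 else fe[[nm]]
  lp0 <- fe_get("intercept") +
    fe_get("age_dx") * (age_dx - 67) +
    fe_get("male") * (sex == "Male") +
    fe_get("hispanic") * (ancestry == "Hispanic") +
    fe_get("pd_duration") * pd_duration +
    fe_get("family_history") * family_history +
    fe_get("education_years") * (education_years - 12) +
    fe_get("wave2") * (wave == 2)

  n_follow <- config$n_visits_max - 1
  visits <- tidyr::expand_grid(subject_id = id,
                               visit = 0:n_follow)
  keep <- visits$visit == 0 | runif(nrow(visits)) < config$retention
  visits <- visits[keep, , drop = FALSE]
  idx <- match(visits$subject_id, id)
  visits$updrs3 <- lp0[idx] + fe_get("visit") * visits$visit +
    b0[idx] + b1[idx] * visits$visit +
    rnorm(nrow(visits), 0, config$resid_sd)

  truth <- tibble(subject_id = id, true_intercept = b0, true_slope = b1)
  list(subjects = subjects, visits = as_tibble(visits), truth = truth)
}
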