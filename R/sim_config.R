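#' Simulation configuration for the synthetic cohort generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_subjects()], [simulate_applications()], [simulate_panel()] and
#' [simulate_cohort()]. Defaults emulate the structure of a case-only
#' Parkinson's disease cohort from an agricultural region: 757 patients in
#' two self-reported ancestry groups, up to three UPDRS-III examinations per
#' subject, ambient exposure records for pesticides co-applied in clusters,
#' and an 85-gene panel split into five selection groups.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param subpop_fractions Named proportions of the ancestry groups; must
#'   sum to 1.
#' @param n_visits_max Maximum number of clinic visits (baseline plus
#'   follow-ups); visit index runs from 0.
#' @param retention Probability that each follow-up visit (independently) is
#'   observed.
#' @param fixed_effects Named list of fixed-effect coefficients on the
#'   UPDRS-III linear predictor. Recognised names: `intercept`, `visit`,
#'   `age_dx` (centred at 67), `male`, `hispanic`, `pd_duration`,
#'   `family_history`, `education_years` (centred at 12), `wave2`.
#' @param intercept_sd,slope_sd,resid_sd Standard deviations (UPDRS-III
#'   units) of the random intercept, the random visit slope, and the
#'   residual. Non-negative; zero gives a degenerate (noise-free) component.
#' @param slope_intercept_corr Correlation between random intercept and
#'   random slope.
#' @param missing_dxyear_frac Fraction of subjects with no recorded
#'   diagnosis year (these cannot be assigned an exposure window).
#' @param zero_exposure_frac Fraction of subjects with no ambient
#'   agricultural exposure at all (all application records zero).
#' @param workplace_frac Fraction of exposed subjects who are additionally
#'   exposed at a workplace address.
#' @param n_pesticides,n_clusters Number of pesticide active ingredients and
#'   the number of co-application clusters they are partitioned into.
#' @param within_cluster_corr Target pairwise Pearson correlation of
#'   long-term average exposures within a cluster, in `[0, 1)`.
#' @param year_log_sd Year-to-year log-scale noise of application intensity.
#' @param subject_log_sd Between-subject log-scale spread of exposure
#'   propensity (total, split between the cluster-shared and
#'   pesticide-specific components to hit `within_cluster_corr`).
#' @param n_panel_genes Number of genes on the panel.
#' @param group_sizes Integer vector of 5 gene-group sizes summing to
#'   `n_panel_genes`.
#' @param n_background_variants Number of background panel variants drawn at
#'   their reference frequency.
#' @param n_planted_variants Number of planted variants whose cohort
#'   frequency is inflated `enrichment_fold`-fold over reference and whose
#'   carriers are biased toward high exposure and fast progression.
#' @param enrichment_fold Frequency inflation factor for planted variants;
#'   must exceed 1 whenever `n_planted_variants > 0`.
#' @param exposure_progression_bias Exponential-tilting weight applied to
#'   the standardized sum of true exposure and true slope when sampling
#'   carriers of planted variants; 0 means unbiased carriers.
#' @param reference_absent_frac Fraction of background variants absent from
#'   the reference frequency table (they cannot be tested for enrichment).
#' @param n_related_pairs Number of planted related sample pairs. Expected
#'   kinship alternates between duplicate (`pi_hat` 1.0) and
#'   parent-offspring (`pi_hat` 0.5) pairs.
#' @param n_ibd_sites Number of biallelic SNPs in the relatedness genotype
#'   matrix. The default (20,000) keeps the per-pair sampling SD of the
#'   moment estimator near 0.01, so screening all cohort pairs at the 0.05
#'   exclusion threshold flags essentially no unrelated pair by chance.
#' @param ref_an Named allele numbers of the two reference populations.
#' @param pop_map Mapping from ancestry label to reference population.
#' @param cadd_bin_probs Mixture probabilities for planted-variant CADD
#'   scores over the bins `<10`, `10-20`, `>20`.
#' @param dx_year_range Range of diagnosis years to sample from.
#' @param seed Integer RNG seed used by [simulate_cohort()].
#'
#' @return A list of class `"agrivar_sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 50, seed = 7)
#' cfg$group_sizes
sim_config <- function(n_subjects = 757,
                       subpop_fractions = c(European = 0.83, Hispanic = 0.17),
                       n_visits_max = 3,
                       retention = 0.7,
                       fixed_effects = list(
                         intercept = 18, visit = 4, age_dx = 0.15,
                         male = 1.5, hispanic = 3, pd_duration = 0.5,
                         family_history = 1, education_years = -0.1,
                         wave2 = -1),
                       intercept_sd = 9,
                       slope_sd = 4,
                       resid_sd = 2.5,
                       slope_intercept_corr = 0.3,
                       missing_dxyear_frac = 0.05,
                       zero_exposure_frac = 0.10,
                       workplace_frac = 0.6,
                       n_pesticides = 20,
                       n_clusters = 2,
                       within_cluster_corr = 0.6,
                       year_log_sd = 0.5,
                       subject_log_sd = 0.7,
                       n_panel_genes = 85,
                       group_sizes = c(14, 13, 18, 36, 4),
                       n_background_variants = 250,
                       n_planted_variants = 12,
                       enrichment_fold = 8,
                       exposure_progression_bias = 1.5,
                       reference_absent_frac = 0.15,
                       n_related_pairs = 3,
                       n_ibd_sites = 20000,
                       ref_an = c(nfe = 113000, amr = 35000),
                       pop_map = c(European = "nfe", Hispanic = "amr"),
                       cadd_bin_probs = c(5, 11, 20) / 36,
                       dx_year_range = c(1990, 2010),
                       seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, subpop_fractions = subpop_fractions,
    n_visits_max = n_visits_max, retention = retention,
    fixed_effects = fixed_effects, intercept_sd = intercept_sd,
    slope_sd = slope_sd, resid_sd = resid_sd,
    slope_intercept_corr = slope_intercept_corr,
    missing_dxyear_frac = missing_dxyear_frac,
    zero_exposure_frac = zero_exposure_frac,
    workplace_frac = workplace_frac,
    n_pesticides = n_pesticides, n_clusters = n_clusters,
    within_cluster_corr = within_cluster_corr,
    year_log_sd = year_log_sd, subject_log_sd = subject_log_sd,
    n_panel_genes = n_panel_genes, group_sizes = group_sizes,
    n_background_variants = n_background_variants,
    n_planted_variants = n_planted_variants,
    enrichment_fold = enrichment_fold,
    exposure_progression_bias = exposure_progression_bias,
    reference_absent_frac = reference_absent_frac,
    n_related_pairs = n_related_pairs, n_ibd_sites = n_ibd_sites,
    ref_an = ref_an, pop_map = pop_map,
    cadd_bin_probs = cadd_bin_probs, dx_year_range = dx_year_range,
    seed = as.integer(seed))
  class(cfg) <- "agrivar_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config Object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "agrivar_sim_config"))
  if (!is.numeric(config$n_subjects) || length(config$n_subjects) != 1 ||
      config$n_subjects < 1) {
    stop("invalid config: `n_subjects` must be a positive count",
         call. = FALSE)
  }
  if (abs(sum(config$subpop_fractions) - 1) > 1e-8) {
    stop("invalid config: `subpop_fractions` must sum to 1", call. = FALSE)
  }
  if (is.null(names(config$subpop_fractions))) {
    stop("invalid config: `subpop_fractions` must be named", call. = FALSE)
  }
  if (length(config$group_sizes) != 5 ||
      sum(config$group_sizes) != config$n_panel_genes) {
    stop("invalid config: `group_sizes` must be 5 counts summing to ",
         "`n_panel_genes`", call. = FALSE)
  }
  sds <- c(config$intercept_sd, config$slope_sd, config$resid_sd)
  if (any(sds < 0)) {
    stop("invalid config: standard deviations must be non-negative",
         call. = FALSE)
  }
  if (config$within_cluster_corr < 0 || config$within_cluster_corr >= 1) {
    stop("invalid config: `within_cluster_corr` must lie in [0, 1)",
         call. = FALSE)
  }
  if (config$n_planted_variants > 0 && config$enrichment_fold <= 1) {
    stop("invalid config: `enrichment_fold` must exceed 1 when variants ",
         "are planted", call. = FALSE)
  }
  if (config$exposure_progression_bias < 0) {
    stop("invalid config: `exposure_progression_bias` must be >= 0",
         call. = FALSE)
  }
  invisible(config)
}
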