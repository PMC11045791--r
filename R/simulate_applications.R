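#' Generate synthetic ambient pesticide application records
#'
#' Emulates record-based ambient exposure estimates after GIS resolution:
#' for every subject, address type (residential, and workplace for a
#' configurable fraction), year from 1974 up to the diagnosis year, and
#' pesticide active ingredient, a non-negative lbs/acre value.
#'
#' Pesticides are partitioned into co-application clusters. Within a
#' cluster, a subject-level latent factor is shared across member
#' pesticides so that the pairwise Pearson correlations of *long-term
#' average* exposures match the configured `within_cluster_corr` on the raw
#' (lognormal) scale; across clusters the latent factors are independent,
#' so between-cluster correlations are near zero. The loading is obtained
#' by moment-matching: for log-scale subject SD \eqn{\tau}, a log-scale
#' correlation \eqn{\rho} gives lognormal correlation
#' \eqn{(e^{\rho\tau^2}-1)/(e^{\tau^2}-1)}, which is inverted at the target.
#'
#' Subjects in the zero-exposure stratum keep their residential record rows
#' with all values exactly zero. Subjects with a missing diagnosis year
#' receive records up to 2005; they are flagged unexposable downstream.
#'
#' @param config A [sim_config()] object.
#' @param subjects Subject table from [simulate_subjects()].
#' @return A list with `applications` (tibble: `subject_id`, `location`,
#'   `year`, `pesticide`, `lbs_per_acre`), `pesticides` (tibble:
#'   `pesticide`, `cluster`), and `truth` (tibble: `subject_id`,
#'   `true_exposure_sum`, the latent propensity used for carrier tilting).
#' @export
simulate_applications <- function(config, subjects) {
  validate_sim_config(config)
  n <- nrow(subjects)
  n_pest <- config$n_pesticides
  k <- config$n_clusters

  cluster_of <- rep(seq_len(k),
                    each = ceiling(n_pest / k))[seq_len(n_pest)]
  pest_names <- synthetic_pesticide_names(n_pest, cluster_of)
  mu_p <- rnorm(n_pest, -0.5, 0.5)

  ## moment-matched latent loading (see details)
  tau <- config$subject_log_sd
  cw <- config$within_cluster_corr
  rho <- if (tau > 0 && cw > 0) {
    log(1 + cw * (exp(tau^2) - 1)) / tau^2
  } else 0
  rho <- min(rho, 1)

  L <- matrix(rnorm(n * k), n, k)          # cluster-shared subject factor
  M <- matrix(rnorm(n * n_pest), n, n_pest) # pesticide-specific factor

  has_work <- runif(n) < config$workplace_frac & !subjects$zero_exposure
  end_year <- ifelse(is.na(subjects$dx_year), 2005L, subjects$dx_year)
  n_years <- end_year - 1974L + 1L

  one_location <- function(loc, s_idx) {
    si <- rep(s_idx, times = n_years[s_idx])
    yr <- unlist(lapply(s_idx, function(i) 1974L:end_year[i]),
                 use.names = FALSE)
    si <- rep(si, each = n_pest)
    yr <- rep(yr, each = n_pest)
    pi <- rep.int(seq_len(n_pest), length(yr) / n_pest)
    log_val <- mu_p[pi] +
      tau * (sqrt(rho) * L[cbind(si, cluster_of[pi])] +
               sqrt(1 - rho) * M[cbind(si, pi)]) +
      config$year_log_sd * rnorm(length(si))
    val <- exp(log_val)
    val[subjects$zero_exposure[si]] <- 0
    tibble(subject_id = subjects$subject_id[si], location = loc,
           year = yr, pesticide = pest_names[pi], lbs_per_acre = val)
  }

  applications <- dplyr::bind_rows(
    one_location("residential", seq_len(n)),
    one_location("workplace", which(has_work)))
  applications <- dplyr::arrange(applications, .data$subject_id,
                                 .data$location, .data$pesticide,
                                 .data$year)

  true_exposure <- tau * sqrt(rho) * L[, 1] + 0.4 * has_work
  true_exposure[subjects$zero_exposure] <- -3

  list(applications = applications,
       pesticides = tibble(pesticide = pest_names, cluster = cluster_of),
       truth = tibble(subject_id = subjects$subject_id,
                      true_exposure_sum = true_exposure))
}

## cluster 1 carries the names of a 10-member cotton co-application
## cluster; remaining pesticides get generic labels
synthetic_pesticide_names <- function(n_pest, cluster_of) {
  cotton <- c("trifluralin", "tribufos", "sodium cacodylate", "prometryn",
              "phorate", "aldicarb", "methamidophos", "dicrotophos",
              "cyanazine", "propargite")
  nm <- sprintf("PEST-%02d", seq_len(n_pest))
  c1 <- which(cluster_of == 1)
  take <- seq_len(min(length(c1), length(cotton)))
  nm[c1[take]] <- cotton[take]
  nm
}
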