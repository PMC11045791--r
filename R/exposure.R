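#' Exposure window definition
#'
#' The analysis window for long-term ambient exposure starts in 1974 (the
#' first year of mandatory application reporting) and ends `lag_years`
#' before each subject's diagnosis year, to exclude the prodromal period.
#'
#' @param start_year First calendar year of the window.
#' @param lag_years Years before diagnosis at which the window closes.
#' @return A list of class `"agrivar_window"`.
#' @export
#' @examples
#' exposure_window()          # 1974 .. diagnosis - 10
exposure_window <- function(start_year = 1974L, lag_years = 10L) {
  stopifnot(lag_years >= 0)
  structure(list(start_year = as.integer(start_year),
                 lag_years = as.integer(lag_years)),
            class = "agrivar_window")
}

#' Long-term average exposure per subject, pesticide and location
#'
#' Averages annual lbs/acre application estimates over each subject's
#' exposure window. Years inside the window with no recorded application
#' count as zero, i.e. the denominator is the full window length; this
#' avoids overweighting brief exposures. Subjects with a missing diagnosis
#' year, or whose window closes before it opens (diagnosed fewer than
#' `lag_years` after `start_year`), are flagged unexposable and carried in
#' the exclusion table rather than the estimates.
#'
#' @param applications Tibble with `subject_id`, `location`, `year`,
#'   `pesticide`, `lbs_per_acre`.
#' @param subjects Subject table with `subject_id` and `dx_year`.
#' @param window An [exposure_window()].
#' @return A list with `estimates` (tibble: `subject_id`, `pesticide`,
#'   `location`, `mean_lbs_per_acre`; a full subject x pesticide x location
#'   grid over exposable subjects, zero where nothing was applied) and
#'   `unexposable` (tibble: `subject_id`, `reason`).
#' @export
longterm_average <- function(applications, subjects,
                             window = exposure_window()) {
  stopifnot(inherits(window, "agrivar_window"))
  end_year <- subjects$dx_year - window$lag_years
  reason <- dplyr::case_when(
    is.na(subjects$dx_year) ~ "missing diagnosis year",
    end_year < window$start_year ~ "empty exposure window",
    TRUE ~ NA_character_)
  unexposable <- tibble(subject_id = subjects$subject_id,
                        reason = reason)
  unexposable <- unexposable[!is.na(unexposable$reason), ]

  keep <- is.na(match(subjects$subject_id, unexposable$subject_id))
  sub <- subjects[keep, c("subject_id", "dx_year")]
  sub$window_len <- sub$dx_year - window$lag_years - window$start_year + 1L

  pesticides <- sort(unique(applications$pesticide))
  locations <- sort(unique(applications$location))
  grid <- tidyr::expand_grid(subject_id = sub$subject_id,
                             pesticide = pesticides,
                             location = locations)

  inwin <- dplyr::inner_join(applications,
                             sub[, c("subject_id", "dx_year")],
                             by = "subject_id")
  inwin <- inwin[inwin$year >= window$start_year &
                   inwin$year <= inwin$dx_year - window$lag_years, ]
  sums <- dplyr::summarise(
    dplyr::group_by(inwin, .data$subject_id, .data$pesticide,
                    .data$location),
    total = sum(.data$lbs_per_acre), .groups = "drop")

  est <- dplyr::left_join(grid, sums,
                          by = c("subject_id", "pesticide", "location"))
  est$total[is.na(est$total)] <- 0
  est$mean_lbs_per_acre <-
    est$total / sub$window_len[match(est$subject_id, sub$subject_id)]
  est$total <- NULL
  list(estimates = est, unexposable = unexposable)
}

#' Discover co-application clusters by hierarchical correlation analysis
#'
#' Sums each subject's residential and workplace long-term averages per
#' pesticide, computes the pairwise Pearson correlation matrix across
#' subjects, and clusters pesticides by average-linkage hierarchical
#' clustering on the distance `1 - r`. The tree is cut so that members are
#' merged only while the linkage correlation strictly exceeds `cutpoint`;
#' singletons are allowed. Zero-variance pesticides cannot be correlated
#' and are excluded with a warning.
#'
#' @param longterm Estimates tibble from [longterm_average()].
#' @param cutpoint Correlation cut-point; groups merge only above it.
#' @return A tibble with `pesticide` and `cluster` (integer labels ordered
#'   by first appearance), with the `hclust` tree attached as attribute
#'   `"tree"`.
#' @export
correlation_cluster <- function(longterm, cutpoint = 0.45) {
  totals <- dplyr::summarise(
    dplyr::group_by(longterm, .data$subject_id, .data$pesticide),
    total = sum(.data$mean_lbs_per_acre), .groups = "drop")
  wide <- tidyr::pivot_wider(totals, names_from = "pesticide",
                             values_from = "total", values_fill = 0)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(mat) < 2 || nrow(mat) < 3) {
    stop("clustering needs at least 2 pesticides and 3 subjects",
         call. = FALSE)
  }
  vars <- apply(mat, 2, var)
  if (any(vars == 0)) {
    warning("excluding zero-variance pesticide(s) from clustering: ",
            paste(colnames(mat)[vars == 0], collapse = ", "),
            call. = FALSE)
    mat <- mat[, vars > 0, drop = FALSE]
  }
  r <- cor(mat)
  tree <- hclust(as.dist(1 - r), method = "average")
  ## strict "> cutpoint": heights at exactly 1 - cutpoint do not merge
  grp <- cutree(tree, h = 1 - cutpoint - 1e-9)
  out <- tibble(pesticide = names(grp),
                cluster = as.integer(factor(grp, levels = unique(grp))))
  attr(out, "tree") <- tree
  out
}

#' Build a cluster definition (members plus toxicity beta weights)
#'
#' @param members Character vector of pesticide names (at least 2).
#' @param betas Named numeric vector of log-odds association weights; every
#'   member must have one.
#' @return A list of class `"agrivar_cluster"`.
#' @export
cluster_definition <- function(members, betas) {
  if (length(members) < 2) {
    stop("a cluster needs at least 2 member pesticides", call. = FALSE)
  }
  if (!all(members %in% names(betas))) {
    stop("every cluster member needs a beta weight", call. = FALSE)
  }
  structure(list(members = members, betas = betas[members]),
            class = "agrivar_cluster")
}

#' The bundled cotton co-application cluster definition
#'
#' Ten pesticides typically co-applied on cotton, with synthetic log-odds
#' toxicity weights shipped as a YAML fixture. In a real analysis the betas
#' come from an external pesticide-disease association study and are
#' supplied through the run configuration.
#'
#' @return An `agrivar_cluster` object.
#' @export
default_cotton_cluster <- function() {
  path <- system.file("extdata", "cotton_cluster.yaml", package = "agrivar")
  spec <- yaml::read_yaml(path)
  betas <- vapply(spec$pesticides, function(p) p$beta, numeric(1))
  names(betas) <- vapply(spec$pesticides, function(p) p$name, character(1))
  cluster_definition(names(betas), betas)
}

#' Toxicity-weighted cluster exposure score
#'
#' For each subject in the analysis cohort and each member pesticide at
#' each location, the long-term average is log-transformed with
#' `log(1 + x)` (admitting zeros), scaled by the cohort SD of that term
#' (uncentred, preserving the natural zero of "no exposure"), and weighted
#' by the pesticide's log-odds beta; the weighted terms are summed over
#' pesticides and both locations, so exposure at two addresses scores
#' higher than the same exposure at one. The raw weighted sum is scaled to
#' the cohort SD (`scaled_score`, SD = 1 over the cohort), and a
#' display score anchors the cohort mean at 1:
#' `display_score = 1 + (scaled_score - mean(scaled_score))`.
#'
#' Cohort SDs are computed over the analysis cohort only. Degenerate terms
#' (cohort SD zero) contribute nothing, with a warning; an all-zero cohort
#' yields scaled scores of 0 and display scores of 1.
#'
#' @param longterm Estimates tibble from [longterm_average()].
#' @param cluster An [cluster_definition()] (or [default_cotton_cluster()]).
#' @param cohort_ids Subject ids forming the analysis cohort; defaults to
#'   every subject present in `longterm`.
#' @return A tibble with `subject_id`, `raw_weighted_sum`, `scaled_score`,
#'   `display_score`.
#' @export
weighted_cluster_score <- function(longterm, cluster, cohort_ids = NULL) {
  stopifnot(inherits(cluster, "agrivar_cluster"))
  if (is.null(cohort_ids)) cohort_ids <- unique(longterm$subject_id)
  lt <- longterm[longterm$subject_id %in% cohort_ids &
                   longterm$pesticide %in% cluster$members, ]
  grid <- tidyr::expand_grid(subject_id = cohort_ids,
                             pesticide = cluster$members,
                             location = c("residential", "workplace"))
  lt <- dplyr::left_join(grid, lt,
                         by = c("subject_id", "pesticide", "location"))
  lt$mean_lbs_per_acre[is.na(lt$mean_lbs_per_acre)] <- 0
  lt$t <- log1p(lt$mean_lbs_per_acre)

  lt <- dplyr::group_by(lt, .data$pesticide, .data$location)
  lt <- dplyr::mutate(lt, term_sd = sd(.data$t))
  lt <- dplyr::ungroup(lt)
  degenerate <- lt$term_sd == 0 | is.na(lt$term_sd)
  if (any(degenerate) && any(lt$t[degenerate] > 0)) {
    warning("zero-SD exposure term(s) contribute 0 to the weighted sum",
            call. = FALSE)
  }
  lt$z <- ifelse(degenerate, 0, lt$t / lt$term_sd)
  lt$w <- unname(cluster$betas[lt$pesticide]) * lt$z

  scores <- dplyr::summarise(dplyr::group_by(lt, .data$subject_id),
                             raw_weighted_sum = sum(.data$w),
                             .groups = "drop")
  s <- sd(scores$raw_weighted_sum)
  if (is.na(s) || s == 0) {
    scores$scaled_score <- 0
  } else {
    scores$scaled_score <- scores$raw_weighted_sum / s
  }
  scores$display_score <- 1 + (scores$scaled_score -
                                 mean(scores$scaled_score))
  dplyr::arrange(scores, .data$subject_id)
}
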