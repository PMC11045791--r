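#' Two-proportion z-test (pooled variance, continuity-corrected)
#'
#' Vectorized pooled-variance z-test of `ac1/an1` versus `ac2/an2`, with a
#' two-sided p-value from the normal tail. A Yates-style continuity
#' correction of `(1/an1 + 1/an2)/2` is subtracted from the absolute
#' difference (floored at zero, so equal proportions give exactly
#' `z = 0`), matching the default behaviour of R's own two-proportion
#' test; without it the normal approximation is sharply anticonservative
#' for the small cohort allele counts typical of a rare-variant panel
#' tested against a very large reference population. When the pooled
#' proportion is 0 or 1 there is no evidence either way: `z = 0`,
#' `p = 1`. P-values are clamped to `(1e-300, 1]` to stay strictly
#' positive.
#'
#' @param ac1,an1 Allele count and allele number of the first group.
#' @param ac2,an2 Allele count and allele number of the second group.
#' @return A tibble with `z` and `p`.
#' @export
#' @examples
#' two_proportion_test(5, 100, 50, 1000)   # equal proportions: z = 0, p = 1
two_proportion_test <- function(ac1, an1, ac2, an2) {
  if (any(an1 <= 0) || any(an2 <= 0)) {
    stop("allele numbers must be positive", call. = FALSE)
  }
  if (any(ac1 < 0 | ac1 > an1) || any(ac2 < 0 | ac2 > an2)) {
    stop("allele counts must lie in [0, allele number]", call. = FALSE)
  }
  p1 <- ac1 / an1
  p2 <- ac2 / an2
  pp <- (ac1 + ac2) / (an1 + an2)
  degenerate <- pp == 0 | pp == 1
  se <- sqrt(pp * (1 - pp) * (1 / an1 + 1 / an2))
  cc <- (1 / an1 + 1 / an2) / 2
  adj <- pmax(abs(p1 - p2) - cc, 0)
  z <- ifelse(degenerate, 0, sign(p1 - p2) * adj / se)
  p <- ifelse(degenerate, 1, 2 * pnorm(-abs(z)))
  tibble(z = z, p = pmin(pmax(p, 1e-300), 1))
}

#' Test every surviving variant for enrichment against the matched
#' reference population
#'
#' For each variant x subpopulation combination that survived QC and has
#' at least one carrier, computes the cohort allele count and allele
#' number (two alleles per sample genotyped at adequate depth at the
#' site), looks up the ancestry-matched reference population, and runs the
#' two-proportion test. A variant is flagged `enriched` only when the
#' cohort frequency exceeds the reference frequency *and* `p < alpha`
#' (directional requirement on a two-sided test). Variants absent from the
#' reference table cannot be scored: they are flagged `reference_absent`
#' with an undefined p-value and excluded downstream. No allele-frequency
#' floor or cap is applied, and no multiple-testing correction is made
#' (each variant is reported at the nominal alpha).
#'
#' @param variants Variant annotation tibble.
#' @param gt,dp Samples x variants dosage and depth matrices.
#' @param kept Variant x subpopulation keep table from
#'   [apply_call_filters()] (already restricted to the post-QC variant
#'   set).
#' @param reference Reference frequency tibble (`variant_id`,
#'   `population`, `ac`, `an`).
#' @param subpops Named list of analysis-cohort subject ids per
#'   subpopulation.
#' @param alpha Significance level (default 0.05).
#' @param pop_map Named map from subpopulation label to reference
#'   population.
#' @param min_depth Depth at which a sample counts as genotyped at the
#'   site (default 10).
#' @return A tibble with one row per tested variant x subpopulation:
#'   counts, frequencies, `z`, `p_value`, `enriched`, `reference_absent`.
#' @export
enrich_all <- function(variants, gt, dp, kept, reference, subpops,
                       alpha = 0.05,
                       pop_map = c(European = "nfe", Hispanic = "amr"),
                       min_depth = 10) {
  if (!all(names(subpops) %in% names(pop_map))) {
    stop("no reference population mapping for subpopulation(s): ",
         paste(setdiff(names(subpops), names(pop_map)), collapse = ", "),
         call. = FALSE)
  }
  kept <- kept[kept$variant_id %in% variants$variant_id, , drop = FALSE]
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    v <- kept$variant_id[i]
    sp <- kept$subpop[i]
    ids <- subpops[[sp]]
    if (length(ids) == 0) return(NULL)
    genotyped <- ids[dp[ids, v] >= min_depth]
    an <- 2L * length(genotyped)
    ac <- sum(gt[genotyped, v])
    if (ac < 1 || an < 1) return(NULL)
    tibble(variant_id = v, subpop = sp, cohort_ac = ac, cohort_an = an)
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    return(tibble(variant_id = character(0), subpop = character(0),
                  cohort_ac = integer(0), cohort_an = integer(0),
                  ref_ac = integer(0), ref_an = integer(0),
                  cohort_freq = numeric(0), ref_freq = numeric(0),
                  z = numeric(0), p_value = numeric(0),
                  enriched = logical(0), reference_absent = logical(0)))
  }
  res$population <- unname(pop_map[res$subpop])
  res <- dplyr::left_join(res, reference,
                          by = c("variant_id", "population"))
  res <- dplyr::rename(res, ref_ac = "ac", ref_an = "an")
  res$cohort_freq <- res$cohort_ac / res$cohort_an
  res$ref_freq <- res$ref_ac / res$ref_an
  res$reference_absent <- is.na(res$ref_ac)

  test <- res[!res$reference_absent, ]
  tt <- two_proportion_test(test$cohort_ac, test$cohort_an,
                            test$ref_ac, test$ref_an)
  res$z <- NA_real_
  res$p_value <- NA_real_
  res$z[!res$reference_absent] <- tt$z
  res$p_value[!res$reference_absent] <- tt$p
  res$enriched <- !res$reference_absent &
    res$cohort_freq > res$ref_freq & res$p_value < alpha
  res$population <- NULL
  dplyr::arrange(res, .data$variant_id, .data$subpop)
}

#' Replication test against an independent case/control cohort
#'
#' For each prioritized variant, compares case versus control allele
#' frequencies in an independent cohort with the same two-proportion test
#' and direction rule. Variants not observed in the replication data at
#' all are unevaluable and reported as `"absent"`.
#'
#' @param prioritized Prioritized variant tibble (needs `variant_id`).
#' @param replication Tibble with `variant_id`, `case_ac`, `case_an`,
#'   `control_ac`, `control_an`. Variants missing from this table are
#'   treated as absent from the replication cohort.
#' @param alpha Significance level.
#' @return A tibble with `variant_id`, `status` in
#'   `{"enriched", "not_enriched", "absent"}`, and the test columns where
#'   defined.
#' @export
replication_test <- function(prioritized, replication, alpha = 0.05) {
  vids <- unique(prioritized$variant_id)
  out <- tibble(variant_id = vids)
  out <- dplyr::left_join(out, replication, by = "variant_id")
  absent <- is.na(out$case_ac) |
    (out$case_ac + out$control_ac) == 0
  out$z <- NA_real_
  out$p_value <- NA_real_
  idx <- which(!absent)
  if (length(idx)) {
    tt <- two_proportion_test(out$case_ac[idx], out$case_an[idx],
                              out$control_ac[idx], out$control_an[idx])
    out$z[idx] <- tt$z
    out$p_value[idx] <- tt$p
  }
  out$status <- dplyr::case_when(
    absent ~ "absent",
    out$p_value < alpha &
      out$case_ac / out$case_an >
      out$control_ac / out$control_an ~ "enriched",
    TRUE ~ "not_enriched")
  out
}
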