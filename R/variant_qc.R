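#' Apply site-level call filters per subpopulation
#'
#' Keeps a variant, within each subpopulation in which it is evaluated,
#' when it has `FILTER == "PASS"`, a site Phred quality of at least
#' `min_qual` (inclusive), and depth of at least `min_depth` in at least
#' `min_frac` (inclusive) of that subpopulation's samples. The depth
#' criterion is evaluated per subpopulation independently, so a variant may
#' survive — and later be tested — in one subpopulation only. Every
#' exclusion is logged with a single primary reason.
#'
#' @param variants Variant annotation tibble (needs `variant_id`, `qual`,
#'   `filter`).
#' @param dp Samples x variants depth matrix (rownames = subject ids,
#'   colnames = variant ids).
#' @param subpops Named list of subject-id vectors, one per subpopulation.
#' @param min_qual Minimum site Phred quality (default 30, inclusive).
#' @param min_depth Minimum read depth per sample (default 10).
#' @param min_frac Minimum fraction of samples at depth (default 0.9,
#'   inclusive).
#' @return A list with `kept` (tibble: `variant_id`, `subpop`) and `log`
#'   (tibble: `variant_id`, `subpop`, `reason`).
#' @export
apply_call_filters <- function(variants, dp, subpops, min_qual = 30,
                               min_depth = 10, min_frac = 0.9) {
  res <- lapply(names(subpops), function(sp) {
    ids <- subpops[[sp]]
    frac <- colMeans(dp[ids, variants$variant_id, drop = FALSE] >=
                       min_depth)
    reason <- dplyr::case_when(
      variants$filter != "PASS" ~ "non-PASS filter status",
      variants$qual < min_qual ~ "site quality below threshold",
      frac < min_frac ~ "insufficient depth coverage",
      TRUE ~ NA_character_)
    tibble(variant_id = variants$variant_id, subpop = sp, reason = reason)
  })
  res <- dplyr::bind_rows(res)
  list(kept = res[is.na(res$reason), c("variant_id", "subpop")],
       log = res[!is.na(res$reason), ])
}

#' Restrict to exonic or splice-site variants on the canonical transcript
#'
#' @param variants Variant annotation tibble (needs `region`, `canonical`).
#' @return A list with `kept` (the surviving rows) and `log` (tibble:
#'   `variant_id`, `reason`).
#' @export
restrict_exonic_canonical <- function(variants) {
  ok <- variants$region %in% c("exonic", "splice") & variants$canonical
  reason <- ifelse(!variants$region %in% c("exonic", "splice"),
                   "not exonic or splice-site",
                   "not on canonical transcript")
  list(kept = variants[ok, , drop = FALSE],
       log = tibble(variant_id = variants$variant_id[!ok],
                    reason = reason[!ok]))
}

#' Gene-specific exclusion rules
#'
#' Drops `HTT` variants flagged as low-complexity-region calls, and
#' `HLA-DRB5` variants with a low-quality warning or a phasing warning
#' (phased variation alters the population frequency used for enrichment).
#' The rules apply only to those two genes; the same flags on other genes
#' are ignored.
#'
#' @param variants Variant annotation tibble (needs `gene`,
#'   `low_complexity`, `phase_warning`, `lowq_warning`).
#' @return A list with `kept` and `log` (as in
#'   [restrict_exonic_canonical()]).
#' @export
apply_special_gene_rules <- function(variants) {
  drop_htt <- variants$gene == "HTT" & variants$low_complexity
  drop_hla <- variants$gene == "HLA-DRB5" &
    (variants$phase_warning | variants$lowq_warning)
  reason <- dplyr::case_when(
    drop_htt ~ "HTT low-complexity region",
    drop_hla ~ "HLA-DRB5 quality/phase warning",
    TRUE ~ NA_character_)
  drop <- drop_htt | drop_hla
  list(kept = variants[!drop, , drop = FALSE],
       log = tibble(variant_id = variants$variant_id[drop],
                    reason = reason[drop]))
}

#' Method-of-moments identity-by-descent estimation
#'
#' Estimates the IBD sharing proportion pi-hat for every sample pair from
#' a biallelic dosage matrix, in the style of array-based kinship tools:
#' observed identity-by-state counts (IBS 0/1/2 over sites) are combined
#' with their expectations under the estimated allele frequencies to solve
#' for P(IBD = 0, 1, 2), and
#' `pi_hat = P(IBD = 2) + P(IBD = 1) / 2`, clamped to `[0, 1]`.
#' Monomorphic sites are uninformative and skipped; fewer than 100
#' informative sites triggers a low-confidence warning.
#'
#' All pairwise IBS counts are computed with three matrix products, so the
#' estimator scales to cohort-size sample sets.
#'
#' @param geno Samples x sites dosage matrix (0/1/2; rownames = ids).
#' @return A tibble with `id1`, `id2` (id1 < id2), `pihat`, and the raw
#'   (unclamped) `pihat_raw`.
#' @export
estimate_pihat <- function(geno) {
  p <- colMeans(geno) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 100) {
    warning("fewer than 100 informative sites; pi-hat estimates are ",
            "low-confidence", call. = FALSE)
  }
  g <- geno[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  m <- ncol(g)
  a0 <- (g == 0) * 1
  a1 <- (g == 1) * 1
  a2 <- (g == 2) * 1
  n2 <- tcrossprod(a0) + tcrossprod(a1) + tcrossprod(a2)
  n0 <- tcrossprod(a0, a2) + tcrossprod(a2, a0)
  n1 <- m - n0 - n2

  s0_0 <- sum(2 * p^2 * q^2)
  s1_0 <- sum(4 * p^3 * q + 4 * p * q^3)
  s2_0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  s1_1 <- sum(2 * p^2 * q + 2 * p * q^2)
  s2_1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)

  ids <- rownames(geno)
  pair <- which(upper.tri(n2), arr.ind = TRUE)
  p0 <- n0[pair] / s0_0
  p1 <- (n1[pair] - p0 * s1_0) / s1_1
  p2 <- (n2[pair] - p0 * s2_0 - p1 * s2_1) / m
  raw <- p2 + 0.5 * p1
  tibble(id1 = ids[pair[, 1]], id2 = ids[pair[, 2]],
         pihat = pmin(pmax(raw, 0), 1), pihat_raw = raw)
}

#' Exclude cryptically related samples
#'
#' Flags every pair with `pihat` strictly greater than `threshold` and
#' removes members greedily: the subject participating in the most flagged
#' pairs is dropped first (ties broken by subject id, lexicographically
#' smallest first) until no flagged pair remains. For an isolated related
#' pair this removes exactly one member; for a triangle of three mutually
#' related samples it removes two.
#'
#' @param kinship Pi-hat tibble from [estimate_pihat()].
#' @param threshold Exclusion threshold; strictly-greater comparison
#'   (a pair at exactly the threshold is retained). Default 0.05.
#' @return A list with `removed` (character vector, in removal order) and
#'   `flagged_pairs` (the offending rows of `kinship`).
#' @export
exclude_related <- function(kinship, threshold = 0.05) {
  flagged <- kinship[kinship$pihat > threshold, , drop = FALSE]
  pairs <- flagged[, c("id1", "id2")]
  removed <- character(0)
  while (nrow(pairs) > 0) {
    deg <- sort(table(c(pairs$id1, pairs$id2)), decreasing = TRUE)
    worst <- names(deg)[deg == max(deg)]
    victim <- sort(worst)[1]
    removed <- c(removed, victim)
    pairs <- pairs[pairs$id1 != victim & pairs$id2 != victim, ,
                   drop = FALSE]
  }
  list(removed = removed, flagged_pairs = flagged)
}

#' Split the cohort into analysis subpopulations by self-reported ancestry
#'
#' Partitions subjects on the self-reported ancestry field. Labels outside
#' `analysis_labels` are set aside: those subjects are not analyzed in any
#' subpopulation.
#'
#' @param subjects Subject table with `subject_id` and `ancestry`.
#' @param analysis_labels Ancestry labels that form analysis
#'   subpopulations.
#' @return A list with `groups` (named list of subject-id vectors) and
#'   `set_aside` (ids with other labels).
#' @export
split_subpopulations <- function(subjects,
                                 analysis_labels = c("European",
                                                     "Hispanic")) {
  groups <- lapply(analysis_labels, function(l) {
    subjects$subject_id[subjects$ancestry == l]
  })
  names(groups) <- analysis_labels
  list(groups = groups,
       set_aside = subjects$subject_id[
         !subjects$ancestry %in% analysis_labels])
}
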