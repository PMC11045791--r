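#' Carrier-averaged exposure and progression scores per enriched variant
#'
#' For each enriched variant x subpopulation entry, averages the display
#' exposure score and display progression score over that entry's carriers
#' within the analysis cohort (subjects with *both* scores; a carrier
#' lacking either score does not enter the averages). Entries with no
#' in-cohort carrier are dropped and logged.
#'
#' @param enrichment Enrichment tibble from [enrich_all()]; only rows with
#'   `enriched == TRUE` are averaged.
#' @param gt Samples x variants dosage matrix.
#' @param exposure Exposure score tibble ([weighted_cluster_score()]).
#' @param progression Progression score tibble ([progression_scores()]).
#' @param cohort Tibble with `subject_id` and `subpop` defining the
#'   analysis cohort.
#' @return A list with `averaged` (tibble: the enriched entries plus
#'   `carrier_count`, `carriers` (comma-separated), `avg_exposure`,
#'   `avg_progression`) and `log` (entries dropped for lack of in-cohort
#'   carriers).
#' @export
carrier_averages <- function(enrichment, gt, exposure, progression,
                             cohort) {
  enr <- enrichment[enrichment$enriched, , drop = FALSE]
  cohort <- cohort[cohort$subject_id %in% exposure$subject_id &
                     cohort$subject_id %in% progression$subject_id, ]
  expo <- setNames(exposure$display_score, exposure$subject_id)
  prog <- setNames(progression$display_score, progression$subject_id)

  rows <- lapply(seq_len(nrow(enr)), function(i) {
    v <- enr$variant_id[i]
    ids <- cohort$subject_id[cohort$subpop == enr$subpop[i]]
    carrier_ids <- ids[gt[ids, v] >= 1]
    tibble(variant_id = v, subpop = enr$subpop[i],
           carrier_count = length(carrier_ids),
           carriers = paste(sort(carrier_ids), collapse = ","),
           avg_exposure = mean(expo[carrier_ids]),
           avg_progression = mean(prog[carrier_ids]))
  })
  avg <- dplyr::bind_rows(rows)
  if (nrow(avg) == 0) {
    avg <- tibble(variant_id = character(0), subpop = character(0),
                  carrier_count = integer(0), carriers = character(0),
                  avg_exposure = numeric(0), avg_progression = numeric(0))
  }
  out <- dplyr::inner_join(enr, avg, by = c("variant_id", "subpop"))
  none <- out$carrier_count == 0
  list(averaged = out[!none, , drop = FALSE],
       log = tibble(variant_id = out$variant_id[none],
                    subpop = out$subpop[none],
                    reason = "no carrier in analysis cohort"))
}

#' Threshold prioritization on the two display scores
#'
#' Keeps entries whose carrier-averaged display exposure and display
#' progression are both at or above their thresholds (inclusive,
#' "1 or greater").
#'
#' @param averaged Averaged tibble from [carrier_averages()].
#' @param exposure_min,progression_min Inclusive thresholds (default 1:
#'   the cohort reference level of each display score).
#' @return The prioritized subset of `averaged`.
#' @export
threshold_prioritize <- function(averaged, exposure_min = 1,
                                 progression_min = 1) {
  averaged[which(averaged$avg_exposure >= exposure_min &
                   averaged$avg_progression >= progression_min), ,
           drop = FALSE]
}

#' Composite disease-severity x pesticide-exposure score and ranking
#'
#' Normalizes each factor by its maximum over the prioritized set (so each
#' factor lies in (0, 1]) and multiplies them:
#' `composite = (avg_progression / max) * (avg_exposure / max)`.
#' The set is ranked by descending composite, ties broken by gene symbol
#' then variant id. The composite is invariant to rescaling either score
#' column by a positive constant; the entry attaining both maxima (if one
#' does) scores exactly 1.
#'
#' @param prioritized Prioritized tibble from [threshold_prioritize()];
#'   must be non-empty and carry `gene` (joined from the variant table).
#' @return The tibble with `composite` and `rank` added, sorted.
#' @export
composite_score <- function(prioritized) {
  if (nrow(prioritized) == 0) {
    stop("cannot score an empty prioritized set", call. = FALSE)
  }
  np <- prioritized$avg_progression / max(prioritized$avg_progression)
  ne <- prioritized$avg_exposure / max(prioritized$avg_exposure)
  out <- prioritized
  out$composite <- np * ne
  out <- dplyr::arrange(out, dplyr::desc(.data$composite), .data$gene,
                        .data$variant_id)
  out$rank <- seq_len(nrow(out))
  out
}

#' Gene-level rollup of the prioritized set
#'
#' Groups prioritized entries by gene. A variant enriched in both
#' subpopulations contributes two entries, and the gene composite is the
#' mean of member entry composites (so cross-population entries are
#' averaged, not deduplicated). Flags genes with multiple distinct
#' variants and genes with any multi-carrier variant, and attaches
#' constraint annotations when provided: `pli_constrained` (pLI > 0.9)
#' and `misz_constrained` (missense Z > 2), left `NA` when the annotation
#' is missing.
#'
#' @param prioritized Scored tibble from [composite_score()].
#' @param constraint Optional tibble with `gene`, `pli`, `mis_z`.
#' @return A tibble with one row per gene.
#' @export
gene_rollup <- function(prioritized, constraint = NULL) {
  genes <- dplyr::summarise(
    dplyr::group_by(prioritized, .data$gene),
    n_entries = dplyr::n(),
    n_variants = dplyr::n_distinct(.data$variant_id),
    multi_variant = dplyr::n_distinct(.data$variant_id) >= 2,
    multi_carrier = any(.data$carrier_count >= 2),
    gene_composite = mean(.data$composite),
    .groups = "drop")
  if (!is.null(constraint)) {
    genes <- dplyr::left_join(genes, constraint, by = "gene")
  } else {
    genes$pli <- NA_real_
    genes$mis_z <- NA_real_
  }
  genes$pli_constrained <- genes$pli > 0.9
  genes$misz_constrained <- genes$mis_z > 2
  dplyr::arrange(genes, dplyr::desc(.data$gene_composite), .data$gene)
}

#' Bin CADD deleteriousness scores
#'
#' A scaled CADD score of 10 or more marks the 10% most deleterious
#' substitutions and 20 or more the top 1%. Bins: `[0, 10)` is `"<10"`,
#' `[10, 20]` is `"10-20"`, above 20 is `">20"`; missing scores are
#' `"unscored"`.
#'
#' @param cadd Numeric vector of scaled CADD scores (`NA` = unscored).
#' @return A factor with levels `"<10"`, `"10-20"`, `">20"`, `"unscored"`.
#' @export
#' @examples
#' cadd_bin(c(9.99, 10, 20, 24.4, NA))
cadd_bin <- function(cadd) {
  if (any(cadd < 0, na.rm = TRUE)) {
    stop("CADD scores cannot be negative", call. = FALSE)
  }
  lab <- dplyr::case_when(
    is.na(cadd) ~ "unscored",
    cadd < 10 ~ "<10",
    cadd <= 20 ~ "10-20",
    TRUE ~ ">20")
  factor(lab, levels = c("<10", "10-20", ">20", "unscored"))
}

#' Compare multi-variant carriers with single-variant carriers
#'
#' Each subject carrying at least one prioritized variant receives the
#' mean composite score of the prioritized entries they carry. Subjects
#' carrying two or more distinct prioritized variants are compared with
#' single-variant carriers by a Welch two-sample t-test; a clear
#' difference would argue against treating the variants as acting
#' independently.
#'
#' @param prioritized Scored tibble from [composite_score()] (needs the
#'   `carriers` column).
#' @return A list with `p_value`, `n_multi`, `n_single`, `mean_multi`,
#'   `mean_single`, and `per_subject` (the subject-level table). When
#'   either group has fewer than 2 subjects the test is skipped with a
#'   warning and `p_value` is `NA`.
#' @export
additivity_check <- function(prioritized) {
  long <- tidyr::separate_rows(
    prioritized[, c("variant_id", "composite", "carriers")],
    "carriers", sep = ",")
  per <- dplyr::summarise(
    dplyr::group_by(long, subject_id = .data$carriers),
    n_variants = dplyr::n_distinct(.data$variant_id),
    mean_composite = mean(.data$composite), .groups = "drop")
  multi <- per$mean_composite[per$n_variants >= 2]
  single <- per$mean_composite[per$n_variants == 1]
  if (length(multi) < 2 || length(single) < 2) {
    warning("a carrier group has fewer than 2 subjects; additivity test ",
            "skipped", call. = FALSE)
    return(list(p_value = NA_real_, n_multi = length(multi),
                n_single = length(single), mean_multi = mean(multi),
                mean_single = mean(single), per_subject = per))
  }
  tt <- t.test(multi, single)
  list(p_value = tt$p.value, n_multi = length(multi),
       n_single = length(single), mean_multi = mean(multi),
       mean_single = mean(single), per_subject = per)
}
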