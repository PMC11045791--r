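#' Summary report over a prioritized variant set
#'
#' Emits the headline counts and fractions of a prioritized set in the
#' style of a targeted-panel case-only study report: number of prioritized
#' variant entries and distinct variants, genes, genes with multiple
#' variants and with multi-carrier variants, CADD bin fractions, gene-group
#' fractions, and the ranked gene table. Every percentage is recomputed
#' from its own numerator and denominator at print time, so text and
#' tables cannot drift apart.
#'
#' The function accepts either a full pipeline prioritized table (with
#' per-entry `composite`, `carrier_count`, `cadd`, `group`) or a minimal
#' externally transcribed table with `gene`, `variant_id` and a per-gene
#' `gene_composite` column; summaries whose inputs are missing are
#' reported as `NA`.
#'
#' @param prioritized Prioritized variant tibble; needs at least `gene`
#'   and `variant_id`.
#' @param genes Optional gene summary from [gene_rollup()]; built from
#'   `prioritized` when omitted.
#' @param replication Optional [replication_test()] result.
#' @return A list of class `"agrivar_report"` with `counts`,
#'   `gene_table`, and `text` (markdown lines).
#' @export
report <- function(prioritized, genes = NULL, replication = NULL) {
  pr <- prioritized
  if (is.null(genes)) {
    has_comp <- "composite" %in% names(pr)
    has_cc <- "carrier_count" %in% names(pr)
    genes <- dplyr::summarise(
      dplyr::group_by(pr, .data$gene),
      n_variants = dplyr::n_distinct(.data$variant_id),
      multi_variant = dplyr::n_distinct(.data$variant_id) >= 2,
      multi_carrier = if (has_cc) any(.data$carrier_count >= 2) else NA,
      gene_composite = if (has_comp) {
        mean(.data$composite)
      } else if ("gene_composite" %in% names(pr)) {
        mean(.data$gene_composite)
      } else NA_real_,
      .groups = "drop")
    genes <- dplyr::arrange(genes, dplyr::desc(.data$gene_composite),
                            .data$gene)
  }

  n_entries <- nrow(pr)
  n_variants <- dplyr::n_distinct(pr$variant_id)
  n_genes <- dplyr::n_distinct(pr$gene)
  n_multi_variant <- sum(genes$multi_variant)
  n_multi_carrier <- if (all(is.na(genes$multi_carrier))) {
    NA_integer_
  } else {
    sum(genes$multi_carrier, na.rm = TRUE)
  }

  max_row <- min_row <- NULL
  if (n_genes > 0 && !all(is.na(genes$gene_composite))) {
    max_row <- genes[which.max(genes$gene_composite), ]
    min_row <- genes[which.min(genes$gene_composite), ]
  }

  cadd_frac <- group_frac <- NULL
  single_carrier_frac <- NA_real_
  if (n_variants > 0 && "cadd" %in% names(pr)) {
    dv <- dplyr::distinct(pr, .data$variant_id, .keep_all = TRUE)
    cadd_frac <- table(cadd_bin(dv$cadd)) / nrow(dv)
  }
  if (n_variants > 0 && "group" %in% names(pr)) {
    dv <- dplyr::distinct(pr, .data$variant_id, .keep_all = TRUE)
    group_frac <- table(factor(dv$group, levels = 1:5)) / nrow(dv)
  }
  if (n_variants > 0 && "carrier_count" %in% names(pr)) {
    dv <- dplyr::distinct(pr, .data$variant_id, .keep_all = TRUE)
    single_carrier_frac <- mean(dv$carrier_count == 1)
  }

  counts <- list(
    n_entries = n_entries, n_variants = n_variants, n_genes = n_genes,
    n_multi_variant_genes = n_multi_variant,
    n_multi_carrier_genes = n_multi_carrier,
    max_composite = if (is.null(max_row)) NA_real_ else
      max_row$gene_composite,
    max_composite_gene = if (is.null(max_row)) NA_character_ else
      max_row$gene,
    min_composite = if (is.null(min_row)) NA_real_ else
      min_row$gene_composite,
    min_composite_gene = if (is.null(min_row)) NA_character_ else
      min_row$gene,
    cadd_bin_fractions = cadd_frac,
    group_fractions = group_frac,
    single_carrier_fraction = single_carrier_frac)

  pct <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) return("NA")
    sprintf("%d/%d (%.0f%%)", num, den, 100 * num / den)
  }
  text <- c(
    "# Prioritized variant report",
    "",
    sprintf("- Prioritized variants: %d (%d entries) in %d genes",
            n_variants, n_entries, n_genes),
    sprintf("- Genes with multiple variants: %s",
            pct(n_multi_variant, n_genes)),
    sprintf("- Genes with a multi-carrier variant: %s",
            pct(n_multi_carrier, n_genes)))
  if (!is.null(max_row)) {
    text <- c(text, sprintf(
      "- Composite score range: %.3f (%s) to %.3f (%s)",
      min_row$gene_composite, min_row$gene,
      max_row$gene_composite, max_row$gene))
  }
  if (!is.null(cadd_frac)) {
    text <- c(text, sprintf(
      "- CADD bins (of %d variants): <10 %.0f%%, 10-20 %.0f%%, >20 %.0f%%, unscored %.0f%%",
      n_variants, 100 * cadd_frac["<10"], 100 * cadd_frac["10-20"],
      100 * cadd_frac[">20"], 100 * cadd_frac["unscored"]))
  }
  if (!is.null(replication)) {
    st <- table(factor(replication$status,
                       levels = c("enriched", "not_enriched", "absent")))
    text <- c(text, sprintf(
      "- Replication: %d enriched, %d not enriched, %d absent/unevaluable",
      st["enriched"], st["not_enriched"], st["absent"]))
  }

  structure(list(counts = counts, gene_table = genes, text = text),
            class = "agrivar_report")
}

#' @export
print.agrivar_report <- function(x, ...) {
  cat(paste(x$text, collapse = "\n"), "\n")
  invisible(x)
}

#' Exposure-by-progression scatter of enriched variants
#'
#' Plots carrier-averaged display exposure against display progression for
#' every enriched entry, highlighting the prioritization quadrant (both
#' scores at or above 1) and colouring by subpopulation.
#'
#' @param averaged Averaged entry tibble from [carrier_averages()].
#' @param exposure_min,progression_min Quadrant thresholds.
#' @return A `ggplot` object.
#' @export
plot_priority <- function(averaged, exposure_min = 1,
                          progression_min = 1) {
  ggplot2::ggplot(averaged,
                  ggplot2::aes(x = .data$avg_exposure,
                               y = .data$avg_progression,
                               colour = .data$subpop)) +
    ggplot2::annotate("rect", xmin = exposure_min, xmax = Inf,
                      ymin = progression_min, ymax = Inf,
                      alpha = 0.08, fill = "goldenrod") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = exposure_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = progression_min, linetype = 2) +
    ggplot2::labs(x = "Average weighted pesticide exposure (display)",
                  y = "Average disease progression (display)",
                  colour = "Subpopulation") +
    ggplot2::theme_minimal()
}

#' Example prioritized variant table
#'
#' A transcription of a published prioritized-variant ranking from a
#' targeted lysosomal-gene panel study of pesticide-exposed PD patients:
#' 36 enriched exonic variants in 26 genes with per-gene composite
#' disease-severity x pesticide-exposure scores. One variant (in `LAMP1`)
#' was enriched in both subpopulations and appears as two rows. Useful as
#' a worked example for [report()].
#'
#' @return A tibble with `gene`, `variant_id`, `subpopulation`,
#'   `p_value`, `gene_composite`.
#' @export
example_prioritized_table <- function() {
  path <- system.file("extdata", "example_prioritized_variants.tsv",
                      package = "agrivar")
  as_tibble(utils::read.delim(path, check.names = FALSE))
}
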