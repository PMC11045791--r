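#' Generate a complete synthetic cohort
#'
#' Seeds the RNG from `config$seed` and runs the three generator stages
#' ([simulate_subjects()], [simulate_applications()],
#' [simulate_panel()]), bundling their outputs and ground truth. With a
#' fixed seed the result — and everything written from it — is
#' reproducible bit for bit.
#'
#' @param config A [sim_config()] object.
#' @return A list with `subjects`, `visits`, `applications`,
#'   `pesticides`, `variants`, `gt`, `dp`, `reference`, `gene_panel`,
#'   `ibd_geno`, and `truth` (true slopes/intercepts, true exposure sums,
#'   planted variants and carrier sets, planted related pairs).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  subj <- simulate_subjects(config)
  appl <- simulate_applications(config, subj$subjects)
  truth <- dplyr::inner_join(subj$truth, appl$truth, by = "subject_id")
  panel <- simulate_panel(config, subj$subjects, truth)
  list(subjects = subj$subjects, visits = subj$visits,
       applications = appl$applications, pesticides = appl$pesticides,
       variants = panel$variants, gt = panel$gt, dp = panel$dp,
       reference = panel$reference, gene_panel = panel$gene_panel,
       ibd_geno = panel$ibd_geno,
       truth = c(as.list(truth), panel$truth))
}

#' Run configuration for the full pipeline
#'
#' @param sim A [sim_config()].
#' @param window An [exposure_window()].
#' @param cluster A [cluster_definition()]; defaults to the bundled cotton
#'   cluster.
#' @param alpha Enrichment significance level.
#' @param ibd_threshold Relatedness exclusion threshold (strict greater).
#' @param min_visits Visits required for a progression score.
#' @param exposure_min,progression_min Prioritization thresholds.
#' @return A list of class `"agrivar_run_config"`.
#' @export
run_config <- function(sim = sim_config(), window = exposure_window(),
                       cluster = default_cotton_cluster(), alpha = 0.05,
                       ibd_threshold = 0.05, min_visits = 2,
                       exposure_min = 1, progression_min = 1) {
  structure(list(sim = sim, window = window, cluster = cluster,
                 alpha = alpha, ibd_threshold = ibd_threshold,
                 min_visits = min_visits, exposure_min = exposure_min,
                 progression_min = progression_min),
            class = "agrivar_run_config")
}

#' Run the full case-only gene-environment pipeline
#'
#' Executes simulate, exposure, progression, QC, enrichment, prioritize
#' and report end to end on a synthetic cohort, optionally writing every
#' input and output table to `out_dir` as plain text (TSV, VCF, JSON,
#' markdown). The analysis cohort consists of subjects with a computable
#' exposure score (non-empty exposure window), a progression score (at
#' least `min_visits` visits), membership in one of the two analysis
#' subpopulations, and survival of the relatedness exclusion; display
#' scores are scaled over this cohort only.
#'
#' With a fixed `config$sim$seed`, repeated runs write byte-identical
#' files.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list with every intermediate and final table,
#'   including `prioritized`, `genes`, `report` and `additivity`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "agrivar_run_config"))
  sim <- simulate_cohort(config$sim)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_plain(sim$subjects, file.path(out_dir, "subjects.tsv"))
    write_tsv_plain(sim$visits, file.path(out_dir, "visits.tsv"))
    write_tsv_plain(sim$applications,
                    file.path(out_dir, "applications.tsv"))
    write_tsv_plain(sim$reference,
                    file.path(out_dir, "reference_freq.tsv"))
    write_panel_vcf(sim$variants, sim$gt, sim$dp,
                    file.path(out_dir, "panel.vcf"))
    write_tsv_plain(
      cbind(tibble(subject_id = rownames(sim$ibd_geno)),
            as.data.frame(sim$ibd_geno)),
      file.path(out_dir, "genotypes.tsv"))
    jsonlite::write_json(
      sim$truth[c("planted_variant_ids", "related_pairs")],
      file.path(out_dir, "truth.json"), digits = NA)
    panel_in <- read_panel_vcf(file.path(out_dir, "panel.vcf"))
  } else {
    panel_in <- list(variants = sim$variants, gt = sim$gt, dp = sim$dp)
  }

  ## exposure
  lt <- longterm_average(sim$applications, sim$subjects, config$window)
  clusters <- correlation_cluster(lt$estimates)

  ## progression model (fit over all subjects with visits)
  prog_fit <- fit_progression(sim$visits, sim$subjects)

  ## subpopulations and relatedness
  split <- split_subpopulations(sim$subjects)
  kin <- estimate_pihat(sim$ibd_geno)
  rel <- exclude_related(kin, config$ibd_threshold)

  ## analysis cohort: both scores, analysis ancestry, unrelated
  nv <- table(sim$visits$subject_id)
  scored_prog <- names(nv)[nv >= config$min_visits]
  cohort_ids <- intersect(unique(lt$estimates$subject_id), scored_prog)
  cohort_ids <- setdiff(cohort_ids, rel$removed)
  cohort_ids <- intersect(cohort_ids, unlist(split$groups))
  cohort <- tibble(
    subject_id = cohort_ids,
    subpop = sim$subjects$ancestry[match(cohort_ids,
                                         sim$subjects$subject_id)])
  cohort <- dplyr::arrange(cohort, .data$subject_id)
  subpops_cohort <- lapply(split$groups, intersect, x = cohort$subject_id)

  expo <- weighted_cluster_score(lt$estimates, config$cluster,
                                 cohort_ids = cohort$subject_id)
  prog <- residualize_slopes(prog_fit$eb, sim$subjects,
                             cohort_ids = cohort$subject_id,
                             min_visits = config$min_visits)

  ## variant QC
  f1 <- apply_call_filters(panel_in$variants, panel_in$dp, subpops_cohort)
  f2 <- restrict_exonic_canonical(panel_in$variants)
  f3 <- apply_special_gene_rules(f2$kept)
  kept <- f1$kept[f1$kept$variant_id %in% f3$kept$variant_id, ]
  exclusions <- dplyr::bind_rows(
    f1$log,
    tibble(variant_id = f2$log$variant_id, subpop = NA_character_,
           reason = f2$log$reason),
    tibble(variant_id = f3$log$variant_id, subpop = NA_character_,
           reason = f3$log$reason))

  ## enrichment
  enr <- enrich_all(panel_in$variants, panel_in$gt, panel_in$dp, kept,
                    sim$reference, subpops_cohort, alpha = config$alpha)

  ## prioritization
  ca <- carrier_averages(enr, panel_in$gt, expo, prog, cohort)
  pri <- threshold_prioritize(ca$averaged, config$exposure_min,
                              config$progression_min)
  meta <- panel_in$variants[, c("variant_id", "gene", "group", "cadd")]
  pri <- dplyr::left_join(pri, meta, by = "variant_id")
  additivity <- NULL
  genes <- NULL
  rep_counts <- NULL
  if (nrow(pri) > 0) {
    pri <- composite_score(pri)
    pri$cadd_bin <- as.character(cadd_bin(pri$cadd))
    genes <- gene_rollup(pri)
    additivity <- suppressWarnings(additivity_check(pri))
  }
  rpt <- if (nrow(pri) > 0) report(pri, genes) else
    report(tibble(gene = character(0), variant_id = character(0)))

  out <- list(config = config, sim = sim, longterm = lt,
              clusters = clusters, exposure = expo, progression = prog,
              cohort = cohort, kinship = kin, related_removed = rel,
              qc_kept = kept, exclusions = exclusions, enrichment = enr,
              averaged = ca$averaged, dropped_no_carrier = ca$log,
              prioritized = pri, genes = genes,
              additivity = additivity, report = rpt)

  if (!is.null(out_dir)) {
    write_tsv_plain(expo, file.path(out_dir, "exposure_scores.tsv"))
    write_tsv_plain(prog, file.path(out_dir, "progression_scores.tsv"))
    write_tsv_plain(clusters, file.path(out_dir, "clusters.tsv"))
    write_tsv_plain(kin[kin$pihat > 0.01, ],
                    file.path(out_dir, "kinship.tsv"))
    write_tsv_plain(exclusions, file.path(out_dir, "exclusions.tsv"))
    write_tsv_plain(enr, file.path(out_dir, "enrichment.tsv"))
    write_tsv_plain(pri, file.path(out_dir, "prioritized.tsv"))
    if (!is.null(genes)) {
      write_tsv_plain(genes, file.path(out_dir, "genes.tsv"))
    }
    writeLines(rpt$text, file.path(out_dir, "report.md"))
  }
  invisible(out)
}

## deterministic plain-text writer (fixed field order, no quoting games)
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], paste, "", collapse = ",")
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
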