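#' Generate a synthetic panel variant call set with planted enrichment
#'
#' Draws a targeted gene-panel call set over the cohort. Background
#' variants receive genotypes at their reference allele frequency (no
#' enrichment). Planted variants receive a cohort allele frequency of
#' `enrichment_fold` times their reference frequency, and their carriers
#' are sampled with exponential-tilting weights
#' \eqn{\exp\{b\,(z_{exposure} + z_{slope})\}} on the standardized true
#' exposure propensity and true progression slope, so planted variants are
#' concentrated in highly exposed, fast-progressing subjects. Planted
#' variants are always exonic, canonical, high-quality and present in the
#' reference table; a configurable fraction of background variants is
#' absent from the reference table and therefore untestable downstream.
#'
#' A separate biallelic SNP matrix (allele frequencies Uniform(0.05, 0.5))
#' is generated for relatedness estimation, with `n_related_pairs` planted
#' pairs: duplicates (expected pi-hat 1) and parent-offspring pairs built
#' by Mendelian-style mixing (one allele copied from the "parent", one
#' drawn from the population; expected pi-hat 0.5).
#'
#' @param config A [sim_config()] object.
#' @param subjects Subject table from [simulate_subjects()].
#' @param truth A tibble with `subject_id`, `true_slope` and
#'   `true_exposure_sum` (from [simulate_subjects()] and
#'   [simulate_applications()]).
#' @return A list with `variants` (annotation tibble), `gt` and `dp`
#'   (subjects x variants genotype-dosage and depth matrices), `reference`
#'   (tibble `variant_id`, `population`, `ac`, `an`), `gene_panel`,
#'   `ibd_geno` (subjects x SNP dosage matrix), and `truth` (list:
#'   `planted_variant_ids`, `planted_carrier_sets`, `related_pairs`).
#' @export
simulate_panel <- function(config, subjects, truth) {
  validate_sim_config(config)
  if (config$n_planted_variants > 0 && config$enrichment_fold <= 1) {
    stop("invalid config: `enrichment_fold` must exceed 1", call. = FALSE)
  }
  n <- nrow(subjects)
  m_bg <- config$n_background_variants
  m_pl <- config$n_planted_variants
  m <- m_bg + m_pl
  panel <- synthetic_gene_panel(config)

  chrom <- sample(1:22, m, replace = TRUE)
  pos <- sample(1e5:5e7, m)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- unname(vapply(ref, function(r) {
    others <- setdiff(bases, r)
    others[sample.int(3, 1)]
  }, ""))
  vid <- paste(chrom, pos, ref, alt, sep = ":")
  planted <- c(rep(FALSE, m_bg), rep(TRUE, m_pl))

  aa <- c("Ala", "Arg", "Asn", "Asp", "Gly", "Leu", "Lys", "Met", "Ser",
          "Thr", "Val")
  hgvs_p <- sprintf("p.%s%d%s", sample(aa, m, TRUE),
                    sample(50:1200, m, TRUE), sample(aa, m, TRUE))

  ## planted variants avoid the two special-rule genes so recovery is not
  ## confounded with the gene-specific exclusions
  ok_genes <- setdiff(panel$gene, c("HTT", "HLA-DRB5"))
  gene <- character(m)
  gene[!planted] <- sample(panel$gene, m_bg, replace = TRUE)
  gene[planted] <- sample(ok_genes, m_pl, replace = TRUE)
  group <- panel$group[match(gene, panel$gene)]

  region <- ifelse(planted, "exonic",
                   sample(c("exonic", "splice", "other"), m, TRUE,
                          prob = c(0.75, 0.10, 0.15)))
  canonical <- ifelse(planted, TRUE, runif(m) < 0.9)
  cadd <- draw_cadd(m, planted, config$cadd_bin_probs)
  qual <- ifelse(planted, runif(m, 40, 70),
                 ifelse(runif(m) < 0.93, runif(m, 32, 70),
                        runif(m, 10, 29.9)))
  filter <- ifelse(planted | runif(m) < 0.97, "PASS", "LowQ")
  low_complexity <- !planted &
    runif(m) < ifelse(gene == "HTT", 0.3, 0.05)
  phase_warning <- !planted &
    runif(m) < ifelse(gene == "HLA-DRB5", 0.3, 0.03)
  lowq_warning <- !planted &
    runif(m) < ifelse(gene == "HLA-DRB5", 0.3, 0.03)

  ## reference allele frequencies: a shared base frequency with mild
  ## population-specific departures, realised as integer AC over the
  ## population AN so the table frequency is exactly what the cohort is
  ## drawn from
  base_p <- ifelse(planted, runif(m, 0.002, 0.01), 10^runif(m, -4, -1.3))
  absent <- !planted & runif(m) < config$reference_absent_frac
  pops <- names(config$ref_an)
  p_pop <- matrix(pmin(base_p * exp(rnorm(m * length(pops), 0, 0.2)),
                       0.5),
                  m, length(pops), dimnames = list(vid, pops))
  ac_pop <- pmax(round(p_pop * rep(config$ref_an, each = m)), 1)
  p_pop <- ac_pop / rep(config$ref_an, each = m)
  reference <- tidyr::expand_grid(variant_id = vid[!absent],
                                  population = pops)
  reference$an <- unname(config$ref_an[reference$population])
  reference$ac <- ac_pop[cbind(match(reference$variant_id, vid),
                               match(reference$population, pops))]

  ## genotypes: background drawn at the subject's matched-population
  ## reference frequency (no enrichment by construction), planted tilted
  gt <- matrix(0L, n, m, dimnames = list(subjects$subject_id, vid))
  if (m_bg > 0) {
    pop_of <- config$pop_map[subjects$ancestry]
    pop_of[is.na(pop_of)] <- pops[1]
    p_subj <- p_pop[!planted, pop_of, drop = FALSE]   # m_bg x n
    gt[, !planted] <- t(matrix(rbinom(length(p_subj), 2, p_subj),
                               nrow = m_bg))
  }
  z_e <- as.numeric(scale(truth$true_exposure_sum))
  z_s <- as.numeric(scale(truth$true_slope))
  if (any(!is.finite(z_e))) z_e <- rep(0, n)
  if (any(!is.finite(z_s))) z_s <- rep(0, n)
  w <- exp(config$exposure_progression_bias * (z_e + z_s))
  carrier_sets <- list()
  for (j in which(planted)) {
    k <- max(2L, rbinom(1, 2L * n, min(config$enrichment_fold * base_p[j],
                                       0.5)))
    k <- min(k, n)
    carriers <- sample(subjects$subject_id, k, prob = w)
    gt[carriers, j] <- 1L
    carrier_sets[[vid[j]]] <- sort(carriers)
  }

  lambda <- ifelse(planted, runif(m, 40, 80),
                   ifelse(runif(m) < 0.95, runif(m, 30, 80),
                          runif(m, 4, 12)))
  dp <- matrix(rpois(n * m, rep(lambda, each = n)), n, m,
               dimnames = list(subjects$subject_id, vid))

  variants <- tibble(
    variant_id = vid, chrom = chrom, pos = pos, ref = ref, alt = alt,
    hgvs_p = hgvs_p, gene = gene, group = group, region = region,
    canonical = canonical, cadd = cadd, qual = round(qual, 2),
    filter = filter, low_complexity = low_complexity,
    phase_warning = phase_warning, lowq_warning = lowq_warning)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  gt <- gt[, variants$variant_id, drop = FALSE]
  dp <- dp[, variants$variant_id, drop = FALSE]

  ibd <- simulate_ibd_genotypes(config, subjects)

  list(variants = variants, gt = gt, dp = dp, reference = reference,
       gene_panel = panel, ibd_geno = ibd$geno,
       truth = list(planted_variant_ids = vid[planted],
                    planted_carrier_sets = carrier_sets,
                    related_pairs = ibd$related_pairs))
}

## planted CADD scores follow a three-bin mixture; background scores are a
## broad spread with a small unscored fraction
draw_cadd <- function(m, planted, bin_probs) {
  bin <- integer(m)
  bin[planted] <- sample(1:3, sum(planted), TRUE, prob = bin_probs)
  bin[!planted] <- sample(1:3, sum(!planted), TRUE,
                          prob = c(0.45, 0.3, 0.25))
  lo <- c(0.1, 10, 20.01)[bin]
  hi <- c(9.99, 20, 35)[bin]
  cadd <- round(runif(m, lo, hi), 2)
  cadd[!planted & runif(m) < 0.05] <- NA_real_
  cadd
}

#' Synthetic gene panel table
#'
#' 85 genes by default, split into the five selection groups at the
#' configured sizes. The first three names are the genes with dedicated
#' filtering rules or special interest (`HTT`, `HLA-DRB5`, `GBA1`); the
#' rest are synthetic placeholders.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with `gene` and `group`.
#' @export
synthetic_gene_panel <- function(config) {
  ng <- config$n_panel_genes
  gene <- sprintf("LFG%03d", seq_len(ng))
  special <- c("HTT", "HLA-DRB5", "GBA1")
  gene[seq_len(min(3, ng))] <- special[seq_len(min(3, ng))]
  tibble(gene = gene,
         group = rep(seq_len(5), times = config$group_sizes)[seq_len(ng)])
}

simulate_ibd_genotypes <- function(config, subjects) {
  n <- nrow(subjects)
  ms <- config$n_ibd_sites
  p <- runif(ms, 0.05, 0.5)
  geno <- matrix(rbinom(n * ms, 2, rep(p, each = n)), n, ms,
                 dimnames = list(subjects$subject_id, NULL))
  npairs <- min(config$n_related_pairs, floor(n / 2))
  related <- tibble(id1 = character(0), id2 = character(0),
                    expected_pihat = numeric(0))
  if (npairs > 0) {
    picks <- sample(subjects$subject_id, 2 * npairs)
    pihat <- rep(c(1, 0.5), length.out = npairs)
    for (q in seq_len(npairs)) {
      i <- picks[2 * q - 1]
      j <- picks[2 * q]
      if (pihat[q] == 1) {
        geno[j, ] <- geno[i, ]
      } else {
        a1 <- rbinom(ms, 1, geno[i, ] / 2)
        a2 <- rbinom(ms, 1, p)
        geno[j, ] <- a1 + a2
      }
    }
    related <- tibble(id1 = picks[seq(1, 2 * npairs, by = 2)],
                      id2 = picks[seq(2, 2 * npairs, by = 2)],
                      expected_pihat = pihat)
  }
  list(geno = geno, related_pairs = related)
}
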