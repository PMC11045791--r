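avg_fixture <- function() {
  ids <- c("S1", "S2", "S3", "S4")
  enr <- tibble::tibble(
    variant_id = c("v1", "v2", "v3"), subpop = "European",
    cohort_ac = 1L, cohort_an = 8L, ref_ac = 1L, ref_an = 10000L,
    cohort_freq = 1 / 8, ref_freq = 1e-4, z = 5, p_value = 1e-6,
    enriched = TRUE, reference_absent = FALSE)
  gt <- matrix(0L, 4, 3, dimnames = list(ids, enr$variant_id))
  gt["S1", "v1"] <- 1L
  gt[c("S1", "S2"), "v2"] <- 1L
  gt[c("S3", "S4"), "v3"] <- 1L
  exposure <- tibble::tibble(subject_id = c("S1", "S2", "S3"),
                             display_score = c(0.5, 1.5, 2.0))
  progression <- tibble::tibble(subject_id = c("S1", "S2", "S3"),
                                display_score = c(1.2, 0.8, 1.4))
  cohort <- tibble::tibble(subject_id = ids, subpop = "European")
  list(enr = enr, gt = gt, exposure = exposure,
       progression = progression, cohort = cohort)
}

test_that("carrier averages are means over in-cohort carriers with both
          scores", {
  fx <- avg_fixture()
  ca <- carrier_averages(fx$enr, fx$gt, fx$exposure, fx$progression,
                         fx$cohort)
  av <- ca$averaged
  ## single carrier: the variant inherits that carrier's scores
  expect_equal(av$avg_exposure[av$variant_id == "v1"], 0.5)
  expect_equal(av$avg_progression[av$variant_id == "v1"], 1.2)
  ## two carriers at 0.5 and 1.5 average to 1.0
  expect_equal(av$avg_exposure[av$variant_id == "v2"], 1.0)
  ## S4 has no scores: v3 averages over S3 alone (hand count)
  expect_equal(av$carrier_count[av$variant_id == "v3"], 1)
  expect_equal(av$avg_exposure[av$variant_id == "v3"], 2.0)
  expect_equal(av$avg_progression[av$variant_id == "v3"], 1.4)
})

test_that("entries with no in-cohort carrier are dropped and logged", {
  fx <- avg_fixture()
  fx$gt[, "v1"] <- 0L
  ca <- carrier_averages(fx$enr, fx$gt, fx$exposure, fx$progression,
                         fx$cohort)
  expect_false("v1" %in% ca$averaged$variant_id)
  expect_equal(ca$log$variant_id, "v1")
})

test_that("prioritization thresholds are inclusive at 1", {
  av <- tibble::tibble(variant_id = c("a", "b", "c"),
                       avg_exposure = c(1.0, 0.999, 2.0),
                       avg_progression = c(1.0, 2.0, 0.999))
  kept <- threshold_prioritize(av)
  expect_equal(kept$variant_id, "a")
})

test_that("composite scores normalize by the set maxima and rank
          deterministically", {
  pri <- tibble::tibble(
    variant_id = c("v1", "v2", "v3"), gene = c("G2", "G1", "G3"),
    avg_exposure = c(1, 2, 2), avg_progression = c(2, 1, 2))
  sc <- composite_score(pri)
  ## the entry holding both maxima scores exactly 1
  expect_equal(sc$composite[sc$variant_id == "v3"], 1)
  ## (prog 2, exp 1) and (prog 1, exp 2) tie at 0.5; gene breaks the tie
  expect_equal(sc$composite[sc$variant_id %in% c("v1", "v2")],
               c(0.5, 0.5))
  expect_equal(sc$variant_id, c("v3", "v2", "v1"))

  ## invariant under common positive rescaling of both columns
  pri2 <- pri
  pri2$avg_exposure <- pri2$avg_exposure * 7
  pri2$avg_progression <- pri2$avg_progression * 7
  expect_equal(composite_score(pri2)$composite, sc$composite)

  ## when no entry attains both maxima, the top composite is below 1
  pri3 <- pri[1:2, ]
  expect_lt(max(composite_score(pri3)$composite), 1)

  expect_error(composite_score(pri[0, ]), "empty")
})

test_that("gene rollup averages entries, flags multiplicity and applies
          constraint thresholds", {
  pri <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v3"),
    gene = c("GENEA", "GENEA", "LAMP1", "LAMP1"),
    subpop = c("European", "European", "European", "Hispanic"),
    carrier_count = c(1L, 1L, 2L, 1L),
    composite = c(0.4, 0.6, 0.3, 0.5))
  constraint <- tibble::tibble(gene = "GENEA", pli = 0.95, mis_z = 2.5)
  g <- gene_rollup(pri, constraint)
  ga <- g[g$gene == "GENEA", ]
  expect_equal(ga$gene_composite, 0.5)
  expect_true(ga$multi_variant)
  expect_false(ga$multi_carrier)
  expect_true(ga$pli_constrained)
  expect_true(ga$misz_constrained)
  ## same variant enriched in both subpopulations: two entries averaged
  gl <- g[g$gene == "LAMP1", ]
  expect_equal(gl$n_entries, 2)
  expect_false(gl$multi_variant)
  expect_true(gl$multi_carrier)
  expect_equal(gl$gene_composite, 0.4)
  ## missing constraint annotation leaves the flags NA, not FALSE
  expect_true(is.na(gl$pli_constrained))
})

test_that("CADD bins follow the published deleteriousness cut-offs", {
  expect_equal(as.character(cadd_bin(c(9.99, 10, 15, 20, 20.01, 24.4,
                                       NA))),
               c("<10", "10-20", "10-20", "10-20", ">20", ">20",
                 "unscored"))
  expect_error(cadd_bin(-1), "negative")
})

test_that("the multi- vs single-variant carrier comparison is calibrated
          under the null and powered under a shift", {
  make_pri <- function(shift = 0) {
    ## 30 single-variant carriers, 15 dual-variant carriers
    singles <- sprintf("P%02d", 1:30)
    multis <- sprintf("M%02d", 1:15)
    v_single <- tibble::tibble(
      variant_id = sprintf("sv%02d", 1:30),
      composite = runif(30, 0.2, 0.8), carriers = singles)
    v_multi1 <- tibble::tibble(
      variant_id = sprintf("ma%02d", 1:15),
      composite = runif(15, 0.2, 0.8) + shift, carriers = multis)
    v_multi2 <- tibble::tibble(
      variant_id = sprintf("mb%02d", 1:15),
      composite = runif(15, 0.2, 0.8) + shift, carriers = multis)
    dplyr::bind_rows(v_single, v_multi1, v_multi2)
  }
  set.seed(61)
  pvals <- vapply(1:200, function(i) {
    additivity_check(make_pri())$p_value
  }, numeric(1))
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  expect_lt(mean(pvals < 0.05), 0.12)

  set.seed(62)
  shifted <- additivity_check(make_pri(shift = 3 * 0.17))
  expect_lt(shifted$p_value, 0.01)
  expect_equal(shifted$n_multi, 15)
  expect_equal(shifted$n_single, 30)
})

test_that("additivity test is skipped with a warning when a group is too
          small", {
  pri <- tibble::tibble(variant_id = c("v1", "v2"),
                        composite = c(0.5, 0.6),
                        carriers = c("S1", "S2"))
  expect_warning(res <- additivity_check(pri), "skipped")
  expect_true(is.na(res$p_value))
})

test_that("the report recomputes its counts from the table it is given", {
  pr <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v3"),
    gene = c("GENEA", "GENEA", "LAMP1", "LAMP1"),
    carrier_count = c(1L, 1L, 2L, 1L),
    cadd = c(25, 15, 5, 5), group = c(1L, 1L, 3L, 3L),
    composite = c(0.4, 0.6, 0.3, 0.5))
  rp <- report(pr)
  expect_equal(rp$counts$n_variants, 3)
  expect_equal(rp$counts$n_entries, 4)
  expect_equal(rp$counts$n_genes, 2)
  expect_equal(rp$counts$n_multi_variant_genes, 1)
  expect_equal(unname(rp$counts$cadd_bin_fractions[">20"]), 1 / 3)
  expect_equal(rp$counts$single_carrier_fraction, 2 / 3)
})

test_that("an empty prioritized set still yields a well-formed report", {
  rp <- report(tibble::tibble(gene = character(0),
                              variant_id = character(0)))
  expect_equal(rp$counts$n_variants, 0)
  expect_equal(rp$counts$n_genes, 0)
  expect_type(rp$text, "character")
  expect_output(print(rp), "Prioritized variants: 0")
})

test_that("the bundled worked-example table reproduces its published
          structure", {
  tab <- example_prioritized_table()
  expect_equal(nrow(tab), 37)   # one variant appears in both subpops
  rp <- report(tab)
  expect_equal(rp$counts$n_variants, 36)
  expect_equal(rp$counts$n_genes, 26)
  expect_equal(rp$counts$n_multi_variant_genes, 10)
})
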