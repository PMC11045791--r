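make_records <- function(subject, years, value, pesticide = "phorate",
                         location = "residential") {
  tidyr::expand_grid(subject_id = subject, location = location,
                     year = years, pesticide = pesticide) |>
    dplyr::mutate(lbs_per_acre = value)
}

test_that("long-term averages use the full window length as denominator", {
  subjects <- tibble::tibble(subject_id = "A", dx_year = 1995)
  rec <- make_records("A", 1974:1983, 2.0)
  lt <- longterm_average(rec, subjects)   # window 1974..1985, length 12
  expect_equal(lt$estimates$mean_lbs_per_acre[
    lt$estimates$location == "residential"], 20 / 12)
  ## a single in-window record of value v averages to v / window_length
  rec1 <- make_records("A", 1980, 6.0)
  lt1 <- longterm_average(rec1, subjects)
  expect_equal(lt1$estimates$mean_lbs_per_acre[
    lt1$estimates$location == "residential"], 6 / 12)
})

test_that("subjects without a usable window are flagged, not dropped by
          crash", {
  subjects <- tibble::tibble(subject_id = c("A", "B", "C"),
                             dx_year = c(NA, 1980, 1995))
  rec <- make_records(c("A", "B", "C"), 1974:1976, 1.0)
  lt <- longterm_average(rec, subjects)
  expect_setequal(lt$unexposable$subject_id, c("A", "B"))
  expect_match(lt$unexposable$reason[lt$unexposable$subject_id == "A"],
               "missing diagnosis")
  expect_match(lt$unexposable$reason[lt$unexposable$subject_id == "B"],
               "empty")
  expect_setequal(unique(lt$estimates$subject_id), "C")
})

test_that("records outside the window and absent pesticides average to 0", {
  subjects <- tibble::tibble(subject_id = "A", dx_year = 1995)
  rec <- dplyr::bind_rows(make_records("A", 1990:1994, 9.0),
                          make_records("A", 1980, 3.0, "aldicarb"))
  lt <- longterm_average(rec, subjects)$estimates
  expect_equal(lt$mean_lbs_per_acre[lt$pesticide == "phorate" &
                                      lt$location == "residential"], 0)
  expect_equal(lt$mean_lbs_per_acre[lt$pesticide == "aldicarb" &
                                      lt$location == "residential"],
               3 / 12)
})

test_that("identical exposure columns cluster together; cutpoint 1 gives
          singletons", {
  set.seed(8)
  n <- 30
  x <- runif(n, 0, 5)
  lt <- dplyr::bind_rows(
    tibble::tibble(subject_id = sprintf("S%02d", 1:n), pesticide = "a",
                   location = "residential", mean_lbs_per_acre = x),
    tibble::tibble(subject_id = sprintf("S%02d", 1:n), pesticide = "b",
                   location = "residential", mean_lbs_per_acre = x),
    tibble::tibble(subject_id = sprintf("S%02d", 1:n), pesticide = "c",
                   location = "residential",
                   mean_lbs_per_acre = runif(n)))
  cl <- correlation_cluster(lt)
  expect_equal(cl$cluster[cl$pesticide == "a"],
               cl$cluster[cl$pesticide == "b"])
  expect_false(cl$cluster[cl$pesticide == "c"] ==
                 cl$cluster[cl$pesticide == "a"])
  singletons <- correlation_cluster(lt, cutpoint = 1)
  expect_equal(dplyr::n_distinct(singletons$cluster), 3)
})

test_that("the planted co-application structure is recovered exactly and
          within-cluster correlations exceed the cut-point", {
  cfg <- sim_config(n_subjects = 320, missing_dxyear_frac = 0,
                    zero_exposure_frac = 0.05, seed = 21)
  set.seed(21)
  sub <- simulate_subjects(cfg)
  app <- simulate_applications(cfg, sub$subjects)
  lt <- longterm_average(app$applications, sub$subjects)
  cl <- correlation_cluster(lt$estimates)
  truthcl <- app$pesticides
  ## discovered partition == planted partition (up to label permutation)
  cross <- table(cl$cluster,
                 truthcl$cluster[match(cl$pesticide, truthcl$pesticide)])
  expect_equal(dplyr::n_distinct(cl$cluster), 2)
  expect_true(all(rowSums(cross > 0) == 1))
  expect_true(all(colSums(cross > 0) == 1))

  ## all pairwise within-cluster correlations above 0.45
  totals <- dplyr::summarise(
    dplyr::group_by(lt$estimates, subject_id, pesticide),
    total = sum(mean_lbs_per_acre), .groups = "drop")
  wide <- tidyr::pivot_wider(totals, names_from = pesticide,
                             values_from = total)
  c1 <- truthcl$pesticide[truthcl$cluster == 1]
  r <- cor(as.matrix(wide[, c1]))
  expect_gt(min(r[upper.tri(r)]), 0.45)
})

test_that("zero-variance pesticides are excluded from clustering with a
          warning", {
  set.seed(9)
  lt <- dplyr::bind_rows(
    tibble::tibble(subject_id = sprintf("S%02d", 1:20), pesticide = "a",
                   location = "residential",
                   mean_lbs_per_acre = runif(20)),
    tibble::tibble(subject_id = sprintf("S%02d", 1:20), pesticide = "b",
                   location = "residential",
                   mean_lbs_per_acre = runif(20)),
    tibble::tibble(subject_id = sprintf("S%02d", 1:20), pesticide = "z",
                   location = "residential", mean_lbs_per_acre = 0))
  expect_warning(cl <- correlation_cluster(lt), "zero-variance")
  expect_false("z" %in% cl$pesticide)
})

test_that("weighted cluster scores: degenerate cohorts and monotonicity", {
  cl <- cluster_definition(c("a", "b"), c(a = 1, b = 1))
  ids <- sprintf("S%02d", 1:10)
  zero <- tidyr::expand_grid(subject_id = ids, pesticide = c("a", "b"),
                             location = "residential") |>
    dplyr::mutate(mean_lbs_per_acre = 0)
  sc0 <- weighted_cluster_score(zero, cl, ids)
  expect_true(all(sc0$scaled_score == 0))
  expect_true(all(sc0$display_score == 1))

  ## one exposed subject tops the cohort
  one <- zero
  one$mean_lbs_per_acre[one$subject_id == "S03"] <- 4
  sc1 <- weighted_cluster_score(one, cl, ids)
  expect_equal(sc1$subject_id[which.max(sc1$raw_weighted_sum)], "S03")

  ## adding exposure never lowers the subject's raw weighted sum
  more <- one
  more$mean_lbs_per_acre[more$subject_id == "S05"] <- 2
  sc2 <- weighted_cluster_score(more, cl, ids)
  expect_gte(sc2$raw_weighted_sum[sc2$subject_id == "S05"],
             sc1$raw_weighted_sum[sc1$subject_id == "S05"])
})

test_that("exposure at both locations scores strictly higher than the same
          exposure at one", {
  cl <- cluster_definition(c("a", "b"), c(a = 0.5, b = 0.3))
  ids <- sprintf("S%02d", 1:12)
  set.seed(10)
  base <- tidyr::expand_grid(subject_id = ids, pesticide = c("a", "b"),
                             location = c("residential", "workplace")) |>
    dplyr::mutate(mean_lbs_per_acre = runif(dplyr::n(), 0.5, 2))
  dual <- base
  single <- base
  single$mean_lbs_per_acre[single$subject_id == "S01" &
                             single$location == "workplace"] <- 0
  dual_sc <- weighted_cluster_score(dual, cl, ids)
  single_sc <- weighted_cluster_score(single, cl, ids)
  expect_gt(dual_sc$raw_weighted_sum[dual_sc$subject_id == "S01"],
            single_sc$raw_weighted_sum[single_sc$subject_id == "S01"])
})

test_that("scaled scores have unit SD and match a direct recomputation", {
  cl <- default_cotton_cluster()
  cfg <- sim_config(n_subjects = 80, missing_dxyear_frac = 0, seed = 13)
  set.seed(13)
  sub <- simulate_subjects(cfg)
  app <- simulate_applications(cfg, sub$subjects)
  lt <- longterm_average(app$applications, sub$subjects)$estimates
  ids <- sort(unique(lt$subject_id))
  sc <- weighted_cluster_score(lt, cl, ids)
  expect_equal(sd(sc$scaled_score), 1, tolerance = 1e-12)
  expect_equal(mean(sc$display_score), 1, tolerance = 1e-12)

  ## independent recomputation with explicit loops
  raw <- setNames(numeric(length(ids)), ids)
  for (p in cl$members) for (loc in c("residential", "workplace")) {
    v <- vapply(ids, function(s) {
      x <- lt$mean_lbs_per_acre[lt$subject_id == s & lt$pesticide == p &
                                  lt$location == loc]
      if (length(x) == 0) 0 else x
    }, numeric(1))
    t <- log(1 + v)
    if (sd(t) > 0) raw <- raw + cl$betas[[p]] * t / sd(t)
  }
  expect_equal(sc$raw_weighted_sum, unname(raw[sc$subject_id]),
               tolerance = 1e-10)
})
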