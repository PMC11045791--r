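# shared fixtures built in code; kept tiny so the suite stays fast

quick_sim_cfg <- function(...) {
  defaults <- list(n_subjects = 120, n_background_variants = 60,
                   n_planted_variants = 5, n_ibd_sites = 400,
                   n_related_pairs = 2, seed = 11)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# minimal variant annotation rows with sensible defaults
variant_rows <- function(n = 1, variant_id = sprintf("1:%d:A:G", seq_len(n)),
                         gene = "LFG010", group = 2L, region = "exonic",
                         canonical = TRUE, cadd = 15, qual = 50,
                         filter = "PASS", low_complexity = FALSE,
                         phase_warning = FALSE, lowq_warning = FALSE) {
  tibble::tibble(variant_id = variant_id, gene = gene, group = group,
                 region = region, canonical = canonical, cadd = cadd,
                 qual = qual, filter = filter,
                 low_complexity = low_complexity,
                 phase_warning = phase_warning,
                 lowq_warning = lowq_warning)
}

# independent BLUP oracle for the random intercept+slope model: conditional
# modes computed from the REML variance components by the closed-form
# mixed-model equations, per subject
blup_slope_oracle <- function(fit) {
  vc <- lme4::VarCorr(fit)$subject_id
  G <- matrix(c(vc[1, 1], vc[1, 2], vc[1, 2], vc[2, 2]), 2, 2)
  sigma2 <- attr(lme4::VarCorr(fit), "sc")^2
  X <- lme4::getME(fit, "X")
  y <- lme4::getME(fit, "y")
  beta <- lme4::fixef(fit)
  fr <- fit@frame
  ids <- unique(as.character(fr$subject_id))
  out <- vapply(ids, function(s) {
    i <- which(as.character(fr$subject_id) == s)
    Zi <- cbind(1, fr$visit[i])
    Vi <- Zi %*% G %*% t(Zi) + sigma2 * diag(length(i))
    b <- G %*% t(Zi) %*% solve(Vi, y[i] - X[i, , drop = FALSE] %*% beta)
    b[2, 1]
  }, numeric(1))
  tibble::tibble(subject_id = ids,
                 eb_slope = unname(beta["visit"] + out))
}
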