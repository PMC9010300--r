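test_that("a clean single-residue dataset is recovered to optimiser tolerance", {
  d <- make_curves("I75", kex = 800, p_b = 0.04, dw_c = 1.8, dw_h = 0.06,
                   r2_0 = 14, noise = 0)
  fit <- fit_single_residue(d)
  expect_equal(fit$kex, 800, tolerance = 1e-3)
  expect_equal(fit$p_b, 0.04, tolerance = 1e-3)
  expect_equal(fit$residues$dw_c, 1.8, tolerance = 1e-3)
  expect_equal(fit$residues$dw_h, 0.06, tolerance = 1e-2)
  expect_equal(fit$curves$r2_0, rep(14, 2), tolerance = 1e-4)
  expect_true(fit$identifiable)
  expect_lt(fit$chi2, 1e-3)
  expect_true(fit$p_b < 0.5)
})

test_that("flat data are flagged unidentifiable instead of over-reported", {
  d <- make_curves("I4", kex = 800, p_b = 0.04, dw_c = 0, dw_h = 0,
                   r2_0 = 12, noise = 0.3, seed = 3)
  fit <- fit_single_residue(d)
  expect_false(fit$identifiable)
  expect_lt(max(abs(delta_r2(d)$delta_r2)), 1)
})

test_that("single-residue recovery at the fast-exchange study conditions hits the uncertainty band", {
  d <- make_curves("I34", kex = 1194, p_b = 0.10, dw_c = 1.2, dw_h = 0.05,
                   r2_0 = 16, noise = 0.3, seed = 11,
                   experiments = list(
                     list(experiment = "MQ", field_mhz = 600, t_relax_s = 0.025,
                          nu_cpmg_hz = seq(80, 880, 80)),
                     list(experiment = "MQ", field_mhz = 800, t_relax_s = 0.025,
                          nu_cpmg_hz = seq(80, 960, 80)),
                     list(experiment = "SQ_H", field_mhz = 800, t_relax_s = 0.025,
                          nu_cpmg_hz = seq(80, 1000, 80))))
  fit <- fit_single_residue(d)
  expect_lt(abs(fit$kex - 1194), 154)
  expect_lt(abs(fit$p_b - 0.10), 0.024)
})

test_that("the global fit shares one process and prunes a planted discordant residue", {
  res <- paste0("I", c(11, 22, 33, 44, 55, 66, 77, 88))
  concordant <- make_curves(res, kex = 500, p_b = 0.02,
                            dw_c = c(1.0, 1.5, 2.0, 1.2, 0.8, 1.7, 1.4, 2.2),
                            dw_h = c(0.03, -0.02, 0.04, 0, 0.05, 0.02, -0.04, 0.01),
                            r2_0 = 15, noise = 0.15, seed = 5)
  fit0 <- fit_global(concordant)
  expect_equal(max(fit0$pruning$iteration), 1)          # nothing pruned
  expect_false(any(fit0$pruning$removed))
  expect_lt(abs(fit0$kex - 500), 4 * fit0$se_kex)
  expect_equal(fit0$kex, 500, tolerance = 0.25)
  expect_equal(fit0$p_b, 0.02, tolerance = 0.25)

  rogue <- make_curves("I99", kex = 2500, p_b = 0.02, dw_c = 2, dw_h = 0.03,
                       r2_0 = 15, noise = 0.15, seed = 6)
  fit1 <- fit_global(dplyr::bind_rows(concordant, rogue))
  pruned <- unique(fit1$pruning$residue[fit1$pruning$removed])
  expect_true("I99" %in% pruned)
  expect_false("I99" %in% fit1$residues$residue)
  # pruning is recorded with the ratio that triggered the removal
  lg <- pruning_log(fit1)
  expect_gt(lg$ratio[lg$residue == "I99" & lg$removed], 2)
  # the rogue is by far the worst offender
  expect_equal(lg$residue[lg$iteration == 1][which.max(lg$ratio[lg$iteration == 1])], "I99")
  # final iteration satisfies the rule for every survivor
  expect_true(all(lg$ratio[lg$iteration == max(lg$iteration)] <= 2))

  # worst-first mode removes exactly the planted residue
  fit1w <- fit_global(dplyr::bind_rows(concordant, rogue), prune_worst_only = TRUE)
  expect_identical(unique(fit1w$pruning$residue[fit1w$pruning$removed]), "I99")

  # idempotence: refitting the post-pruning set removes nothing further
  fit2 <- fit_global(dplyr::filter(concordant, residue %in% fit1$residues$residue))
  expect_false(any(fit2$pruning$removed))
})

test_that("covariance errors scale linearly with the data noise", {
  d <- make_curves("I64", kex = 600, p_b = 0.03, dw_c = 1.5, dw_h = 0.04,
                   r2_0 = 12, noise = 0.2, seed = 9)
  f1 <- fit_single_residue(d)
  d2 <- dplyr::mutate(d, sigma = sigma * 2)
  f2 <- fit_single_residue(d2)
  expect_equal(f2$se_kex / f1$se_kex, 2, tolerance = 0.15)
  expect_equal(f2$se_p_b / f1$se_p_b, 2, tolerance = 0.15)
})

test_that("covariance errors are calibrated against Monte-Carlo scatter", {
  # 50 stochastic replicates of a well-conditioned single-residue dataset;
  # the empirical SD of recovered kex should match the reported one-sigma
  # errors within a factor of two either way
  starts <- data.frame(kex = c(500, 1000, 2000), p_b = c(0.05, 0.1, 0.2))
  fits <- lapply(1:50, function(s) {
    d <- make_curves("I85", kex = 1194, p_b = 0.10, dw_c = 1.3, dw_h = 0.05,
                     r2_0 = 15, noise = 0.3, seed = 100 + s)
    fit_single_residue(d, starts = starts)
  })
  kexs <- vapply(fits, function(f) f$kex, numeric(1))
  ses <- vapply(fits, function(f) f$se_kex, numeric(1))
  ratio <- sd(kexs) / median(ses)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  # and the recovery is unbiased at this noise level
  expect_lt(abs(median(kexs) - 1194), 60)
})

test_that("duplicate-based error propagation follows the pooled-SD rules", {
  base <- tibble::tibble(
    residue = "I75", experiment = "MQ", field_mhz = 800, t_relax_s = 0.025,
    nu_cpmg_hz = c(0, 80, 80, 400, 960), intensity = c(1000, 600, 600, 700, 750),
    sigma = 5)
  # identical replicates: pooled SD is 0, the nominal noise floor survives
  out <- propagate_duplicate_errors(base)
  expect_equal(out$sigma_i, rep(5, 5))
  expect_equal(out$sigma_r2eff[out$nu_cpmg_hz == 400], 5 / (0.025 * 700))

  # distinct replicates drive sigma through the propagation formula
  two <- dplyr::mutate(base, intensity = c(1000, 100, 90, 700, 750))
  out2 <- propagate_duplicate_errors(two)
  expect_equal(out2$sigma_i[1], sd(c(100, 90)))  # pooled SD = 7.071...
  expect_equal(out2$sigma_r2eff[out2$nu_cpmg_hz == 400],
               sd(c(100, 90)) / (0.025 * 700))

  # three replicates use the n - 1 denominator
  three <- tibble::tibble(
    residue = "I75", experiment = "MQ", field_mhz = 800, t_relax_s = 0.025,
    nu_cpmg_hz = c(0, 80, 80, 80), intensity = c(1000, 95, 100, 105), sigma = 0.1)
  out3 <- propagate_duplicate_errors(three)
  expect_equal(out3$sigma_i[1], sd(c(95, 100, 105)))

  # no duplicates and no noise estimate: cannot weight a fit
  bare <- tibble::tibble(
    residue = "I75", experiment = "MQ", field_mhz = 800, t_relax_s = 0.025,
    nu_cpmg_hz = c(0, 80, 400), intensity = c(1000, 600, 700))
  expect_error(propagate_duplicate_errors(bare), "cannot weight")
})

test_that("dynamic-residue classification matches the construction", {
  res <- paste0("I", 1:8)
  dw <- c(2, 1.5, 2.5, 0, 0, 0, 1.8, 0)
  d <- make_curves(res, kex = 510, p_b = 0.0083, dw_c = dw, dw_h = rep(0, 8),
                   r2_0 = 15, noise = 0.05, seed = 2)
  dyn <- classify_dynamic_residues(d, threshold = 2)
  expect_setequal(dyn$residue, res[dw > 0])
  expect_true(all(grepl("MQ@", dyn$triggered_by)))
  # a zero threshold admits everything whose amplitude beats the noise
  dyn0 <- classify_dynamic_residues(d, threshold = 0)
  expect_true(all(res[dw > 0] %in% dyn0$residue))
  # an all-flat dataset yields an empty set
  flat <- make_curves(res[1:3], kex = 510, p_b = 0.0083, dw_c = rep(0, 3),
                      dw_h = rep(0, 3), noise = 0.05, seed = 2)
  expect_equal(nrow(classify_dynamic_residues(flat, threshold = 2)), 0)
})

test_that("fit inputs are validated", {
  d <- make_curves("I75", kex = 800, p_b = 0.04, dw_c = 1.8, dw_h = 0.06)
  expect_error(fit_global(d), ">= 2 residues")
  expect_error(fit_single_residue(d[0, ]), "empty")
  expect_error(fit_single_residue(dplyr::mutate(d, sigma = 0)), "sigma")
  few <- d[d$nu_cpmg_hz %in% c(80, 160, 240), ]
  expect_error(fit_single_residue(few), ">= 4 distinct")
})

test_that("tidy, glance and augment expose the fit in broom style", {
  d <- make_curves(c("I1", "I2"), kex = 600, p_b = 0.03, dw_c = c(1.5, 2),
                   dw_h = c(0.04, -0.03), r2_0 = 12, noise = 0.25, seed = 8)
  fit <- fit_global(d)
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("kex", "p_b", "dw_c", "dw_h", "r2_0"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$n_data, gl$n_params)
  au <- augment(fit)
  expect_equal(nrow(au), nrow(d))
  expect_lt(mean(au$.resid^2), 2)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
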