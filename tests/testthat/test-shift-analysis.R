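test_that("the combined shift perturbation is the weighted 1H/13C norm", {
  expect_equal(csp(0, 0), 0)
  expect_equal(csp(0.03, 0.2), sqrt(0.0009 + 0.0025))
  expect_equal(csp(0.03, 0.2), 0.0583, tolerance = 1e-3)
  # sign-flip invariance and the triangle inequality (it is a norm)
  draws <- draw_params(30, seed = 13)
  a_h <- draws$dw_h; a_c <- draws$dw_c
  expect_equal(csp(a_h, a_c), csp(-a_h, a_c))
  expect_equal(csp(a_h, a_c), csp(a_h, -a_c))
  b_h <- rev(a_h); b_c <- rev(a_c)
  expect_true(all(csp(a_h + b_h, a_c + b_c) <= csp(a_h, a_c) + csp(b_h, b_c) + 1e-12))
})

test_that("perturbed residues are flagged by mean and fixed thresholds", {
  even <- tibble::tibble(residue = paste0("I", 1:5), delta = rep(0.05, 5))
  expect_equal(nrow(flag_perturbed(even, method = "mean")), 0)  # strict >
  mix <- tibble::tibble(residue = paste0("I", 1:24),
                        delta = c(rep(0.08, 8), rep(0.01, 16)))
  big <- paste0("I", 1:8)
  expect_setequal(flag_perturbed(mix, method = "mean")$residue, big)
  expect_setequal(flag_perturbed(mix, method = "fixed", cutoff = 0.04)$residue, big)
  one <- tibble::tibble(residue = paste0("I", 1:6), delta = c(0.3, rep(0.01, 5)))
  expect_equal(flag_perturbed(one, method = "mean")$residue, "I1")
  # csp_table wires peak lists into the same machinery
  a <- tibble::tibble(residue = c("I1", "I2"), delta_h_ppm = c(0.5, 0.7),
                      delta_c_ppm = c(12, 13))
  b <- tibble::tibble(residue = c("I1", "I2"), delta_h_ppm = c(0.53, 0.7),
                      delta_c_ppm = c(12.2, 13))
  tab <- csp_table(a, b)
  expect_equal(tab$delta, c(csp(0.03, 0.2), 0))
})

test_that("sign determination follows the eigenvalue oracle and flips with dw_c", {
  p_pos <- two_state_params(kex = 1200, p_b = 0.1, dw_c = 1.2, dw_h = 0.2)
  x <- simulate_sign_inputs(p_pos, field_h1 = 800, position_sigma = 0.001, seed = 2)
  expect_equal(determine_sign(x$delta_c_sq, x$delta_c_mq, p_pos, 800, 0.001), 1)
  p_neg <- two_state_params(kex = 1200, p_b = 0.1, dw_c = -1.2, dw_h = -0.2)
  y <- simulate_sign_inputs(p_neg, field_h1 = 800, position_sigma = 0.001, seed = 2)
  expect_equal(determine_sign(y$delta_c_sq, y$delta_c_mq, p_neg, 800, 0.001), -1)

  # antisymmetry over a seeded parameter sweep
  draws <- draw_params(20, seed = 21)
  ok <- vapply(seq_len(nrow(draws)), function(i) {
    dw_c <- max(abs(draws$dw_c[i]), 0.4)
    dw_h <- max(abs(draws$dw_h[i]), 0.1)
    pp <- two_state_params(draws$kex[i], max(draws$p_b[i], 0.02), dw_c = dw_c,
                           dw_h = dw_h)
    pn <- two_state_params(draws$kex[i], max(draws$p_b[i], 0.02), dw_c = -dw_c,
                           dw_h = -dw_h)
    xp <- simulate_sign_inputs(pp, 800, position_sigma = 1e-4, seed = 100 + i)
    xn <- simulate_sign_inputs(pn, 800, position_sigma = 1e-4, seed = 100 + i)
    sp <- determine_sign(xp$delta_c_sq, xp$delta_c_mq, pp, 800, 1e-4)
    sn <- determine_sign(xn$delta_c_sq, xn$delta_c_mq, pn, 800, 1e-4)
    isTRUE(sp == -sn) || (is.na(sp) && is.na(sn))
  }, logical(1))
  expect_true(all(ok))
  determined <- vapply(seq_len(nrow(draws)), function(i) {
    dw_c <- max(abs(draws$dw_c[i]), 0.4)
    pp <- two_state_params(draws$kex[i], max(draws$p_b[i], 0.02), dw_c = dw_c,
                           dw_h = max(abs(draws$dw_h[i]), 0.1))
    xp <- simulate_sign_inputs(pp, 800, position_sigma = 1e-4, seed = 100 + i)
    !is.na(determine_sign(xp$delta_c_sq, xp$delta_c_mq, pp, 800, 1e-4))
  }, logical(1))
  expect_gt(mean(determined), 0.8)

  # no shift difference: the peaks coincide and the sign is undetermined
  p0 <- two_state_params(kex = 1200, p_b = 0.1, dw_c = 0)
  z <- simulate_sign_inputs(p0, 800, position_sigma = 1e-4, seed = 3)
  expect_equal(z$true_sq, z$true_mq)
  expect_true(is.na(determine_sign(z$delta_c_sq, z$delta_c_mq, p0, 800, 1e-4)))

  # position noise far above the predicted separation: undetermined
  pw <- two_state_params(kex = 1200, p_b = 0.1, dw_c = 1.2)
  w <- simulate_sign_inputs(pw, 800, position_sigma = 0.5, seed = 4)
  expect_true(is.na(determine_sign(w$delta_c_sq, w$delta_c_mq, pw, 800, 0.5)))

  # the two-field HSQC comparison is available as an alternative mode
  s2 <- determine_sign(.02, .01, p_pos, 800, 1e-4, mode = "two_field", field_h1_b = 600)
  expect_true(s2 %in% c(-1, 1))
})

test_that("excited-state shifts are the ground shifts displaced by signed dw", {
  d <- make_curves(c("I5", "I7"), kex = 600, p_b = 0.05, dw_c = c(1.2, 0.9),
                   dw_h = c(0.05, -0.03), r2_0 = 12, noise = 0.02, seed = 14)
  fit <- fit_global(d)
  ground <- tibble::tibble(residue = c("I5", "I7"), delta_h_ppm = c(0.6, 0.8),
                           delta_c_ppm = c(13.5, 11.0), sigma_h = 0.001, sigma_c = 0.01)
  signs <- tibble::tibble(residue = c("I5", "I7"), sign_c = c(1, 1))
  exc <- reconstruct_excited_shifts(ground, fit, signs)
  expect_equal(exc$delta_c_ppm, c(13.5 + 1.2, 11.0 + 0.9), tolerance = 0.05)
  expect_equal(exc$delta_h_ppm, c(0.6 + 0.05, 0.8 - 0.03), tolerance = 0.05)
  expect_false(any(exc$ambiguous))
  expect_true(all(exc$sigma_c >= 0.01))

  # a negative sign displaces the other way, and dw_h follows the joint flip
  neg <- reconstruct_excited_shifts(ground, fit,
                                    tibble::tibble(residue = c("I5", "I7"),
                                                   sign_c = c(-1, -1)))
  expect_equal(neg$delta_c_ppm, c(13.5 - 1.2, 11.0 - 0.9), tolerance = 0.05)
  expect_equal(neg$delta_h_ppm, c(0.6 - 0.05, 0.8 + 0.03), tolerance = 0.05)

  # undetermined signs produce both candidates, flagged ambiguous
  amb <- reconstruct_excited_shifts(ground, fit,
                                    tibble::tibble(residue = c("I5", "I7"),
                                                   sign_c = c(NA, 1)))
  expect_equal(sum(amb$residue == "I5"), 2)
  expect_true(all(amb$ambiguous[amb$residue == "I5"]))

  # zero shift difference leaves the excited state on the ground position
  flat_fit <- fit
  flat_fit$residues$dw_c <- 0
  flat_fit$residues$dw_h <- 0
  same <- reconstruct_excited_shifts(ground, flat_fit, signs)
  expect_equal(same$delta_c_ppm, ground$delta_c_ppm)

  bad_ground <- ground[1, ]
  expect_error(reconstruct_excited_shifts(bad_ground, fit, signs), "absent")
})

test_that("state-model comparison recovers the generating hypothesis", {
  for (hyp in c("two_state", "three_state", "four_state")) {
    sc <- simulate_shift_tables(hyp, separation = 0.5, seed = 5)
    v <- compare_state_models(sc$tables, exclude = sc$exclude)
    expect_equal(v$verdict, c(two_state = "2-state", three_state = "3-state", four_state = "4-state")[[hyp]])
  }
  # zero separation: the four tables coincide and nothing can be resolved
  sc0 <- simulate_shift_tables("four_state", separation = 0, seed = 6)
  expect_equal(compare_state_models(sc0$tables, exclude = sc0$exclude)$verdict,
               "indistinguishable")
  # everything excluded: no evidence left
  sc <- simulate_shift_tables("four_state", separation = 0.5, seed = 7)
  all_res <- sc$tables$ATP$residue
  expect_equal(compare_state_models(sc$tables, exclude = all_res)$verdict,
               "insufficient evidence")
})

test_that("the verdict is stable under permutation and extra exclusions", {
  sc <- simulate_shift_tables("four_state", separation = 0.6, seed = 8)
  v0 <- compare_state_models(sc$tables, exclude = sc$exclude)
  perm <- lapply(sc$tables, function(t) t[sample(nrow(t)), ])
  v1 <- withr::with_seed(9, compare_state_models(perm, exclude = sc$exclude))
  expect_equal(v1$verdict, v0$verdict)
  extra <- c(sc$exclude, setdiff(sc$tables$ATP$residue, sc$exclude)[1:3])
  v2 <- compare_state_models(sc$tables, exclude = extra)
  expect_equal(v2$verdict, v0$verdict)
  # methods expose the evidence
  expect_s3_class(tidy(v0), "tbl_df")
  expect_equal(glance(v0)$verdict, v0$verdict)
  expect_s3_class(autoplot(v0), "ggplot")
})
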