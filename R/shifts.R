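# Chemical-shift analysis: perturbation mapping between ligand states,
# sign determination of fitted shift differences from SQ/MQ peak-position
# comparisons, excited-state shift reconstruction, and discrimination among
# 2-/3-/4-state conformational equilibria.

#' Combined chemical shift perturbation
#'
#' Weighted 1H/13C shift distance `Delta = sqrt(delta_h^2 +
#' (0.25 * delta_c)^2)` (ppm) between two states of the same methyl probe.
#'
#' @param delta_h,delta_c Shift differences in ppm (vectors).
#' @return `Delta` in ppm.
#' @examples
#' csp(0.03, 0.2)
#' @export
csp <- function(delta_h, delta_c) {
  stopifnot(is.numeric(delta_h), is.numeric(delta_c),
            all(is.finite(delta_h)), all(is.finite(delta_c)))
  sqrt(delta_h^2 + (0.25 * delta_c)^2)
}

#' Per-residue chemical shift perturbations between two peak lists
#'
#' @param a,b Peak lists (tibbles with `residue`, `delta_h_ppm`,
#'   `delta_c_ppm`), e.g. the two ligand states of a protein.
#' @return A tibble with `residue`, the per-nucleus differences `d_h`,
#'   `d_c` (`b` minus `a`) and the combined perturbation `delta`.
#' @export
csp_table <- function(a, b) {
  for (t in list(a, b)) .validate_r2eff_table(t, need = c("residue", "delta_h_ppm", "delta_c_ppm"))
  m <- dplyr::inner_join(as_tibble(a), as_tibble(b), by = "residue",
                         suffix = c("_a", "_b"))
  if (!nrow(m)) abort("the two peak lists share no residues")
  tibble(residue = m$residue,
         d_h = m$delta_h_ppm_b - m$delta_h_ppm_a,
         d_c = m$delta_c_ppm_b - m$delta_c_ppm_a,
         delta = csp(m$delta_h_ppm_b - m$delta_h_ppm_a,
                     m$delta_c_ppm_b - m$delta_c_ppm_a))
}

#' Flag residues with outstanding shift perturbations
#'
#' Residues whose combined perturbation exceeds either the mean perturbation
#' over all residues (default) or a fixed cutoff (0.04 ppm by default in
#' `"fixed"` mode).
#'
#' @param csp_tbl Output of [csp_table()] (needs `residue`, `delta`).
#' @param method `"mean"` or `"fixed"`.
#' @param cutoff Cutoff in ppm for `"fixed"` mode.
#' @return The input restricted to flagged residues, with the applied
#'   threshold as attribute `"threshold"`.
#' @export
flag_perturbed <- function(csp_tbl, method = c("mean", "fixed"), cutoff = 0.04) {
  method <- match.arg(method)
  csp_tbl <- .validate_r2eff_table(csp_tbl, need = c("residue", "delta"))
  if (nrow(csp_tbl) < 2) abort("need >= 2 residues to flag perturbations")
  thr <- if (method == "mean") mean(csp_tbl$delta) else cutoff
  out <- csp_tbl %>% filter(delta > thr)
  attr(out, "threshold") <- thr
  out
}

# Exchange-induced displacement (ppm) of the observed ground-state 13C peak
# in SQ (HSQC-type) and MQ (HMQC-type) spectra: the imaginary part of the
# slowest-decaying eigenvalue of the free-precession evolution matrix of
# each coherence.  The 13C dimension of an HMQC evolves as multiple quantum,
# so its apparent 13C frequency is (omega_DQ - omega_ZQ) / 2.
.exchange_peak_shifts <- function(params, field_h1) {
  kab <- params$p_b * params$kex
  kba <- (1 - params$p_b) * params$kex
  k_mat <- matrix(c(-kab, kab, kba, -kba), 2)
  slow_freq <- function(w) {
    ev <- eigen(k_mat + 1i * diag(c(0, w)), only.values = TRUE)$values
    Im(ev[which.max(Re(ev))])
  }
  dwh <- ppm_to_rad_s(params$dw_h, "H1", field_h1)
  dwc <- ppm_to_rad_s(params$dw_c, "C13", field_h1)
  hz_per_ppm_c <- field_h1 * GAMMA_C_OVER_H
  sq <- slow_freq(dwc) / (2 * pi * hz_per_ppm_c)
  mq <- (slow_freq(dwh + dwc) - slow_freq(dwh - dwc)) / 2 / (2 * pi * hz_per_ppm_c)
  list(sq = sq, mq = mq)
}

#' Determine the sign of a 13C shift difference
#'
#' The exchange-shifted position of the ground-state 13C peak differs
#' between single-quantum (HSQC-type) and multiple-quantum (HMQC-type)
#' spectra — or between two static fields — in a direction set by the sign
#' of `dw_c`.  Given the exchange parameters from dispersion fitting (which
#' fix only `|dw_c|`), the observed position difference is compared with the
#' difference predicted from the slowly decaying eigenvalue of the exchange
#' evolution matrix for each candidate sign; `"undetermined"` (NA) is
#' returned when the predicted separation is below the supplied position
#' uncertainty.
#'
#' @param observed_sq,observed_mq Observed ground-state 13C positions (ppm)
#'   in the SQ and MQ spectra.  In `mode = "two_field"` these are instead
#'   the SQ positions at `field_h1` and `field_h1_b`.
#' @param params A [two_state_params()] carrying `kex`, `p_b` and the
#'   magnitude `|dw_c|` (and `dw_h`) from fitting; the stored sign of
#'   `dw_c` is ignored.
#' @param field_h1 1H Larmor frequency (MHz) of the (first) spectrum.
#' @param position_sigma One-sigma uncertainty of the observed position
#'   difference (ppm).
#' @param mode `"sq_mq"` (single-field HSQC vs HMQC, default) or
#'   `"two_field"` (HSQC at two fields).
#' @param field_h1_b Second field for `mode = "two_field"`.
#' @return `+1`, `-1` or `NA` (undetermined).
#' @examples
#' p <- two_state_params(kex = 1200, p_b = 0.1, dw_c = 1.2)
#' x <- simulate_sign_inputs(p, field_h1 = 800, seed = 2)
#' determine_sign(x$delta_c_sq, x$delta_c_mq, p, 800, x$position_sigma)
#' @export
determine_sign <- function(observed_sq, observed_mq, params, field_h1,
                           position_sigma, mode = c("sq_mq", "two_field"),
                           field_h1_b = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "two_state_params"))
  if (is.na(params$dw_c)) {
    abort("a fitted |dw_c| is required for sign determination")
  }
  predict_diff <- function(sgn) {
    p <- two_state_params(params$kex, params$p_b, dw_h = sgn * params$dw_h,
                          dw_c = sgn * abs(params$dw_c), r2_0 = params$r2_0)
    if (mode == "sq_mq") {
      s <- .exchange_peak_shifts(p, field_h1)
      s$sq - s$mq
    } else {
      if (is.null(field_h1_b)) abort("`field_h1_b` is required in two_field mode")
      .exchange_peak_shifts(p, field_h1)$sq - .exchange_peak_shifts(p, field_h1_b)$sq
    }
  }
  pred_pos <- predict_diff(+1)
  pred_neg <- predict_diff(-1)
  obs <- observed_sq - observed_mq
  if (max(abs(pred_pos), abs(pred_neg)) < position_sigma) return(NA_real_)
  if (abs(obs - pred_pos) <= abs(obs - pred_neg)) 1 else -1
}

#' Reconstruct excited-state chemical shifts
#'
#' `delta_excited = delta_ground + sign * |dw|` per nucleus, combining the
#' ground-state peak list, the fitted shift-difference magnitudes and the
#' signs from [determine_sign()].  The fitted `dw_h` carries only the sign
#' relative to `dw_c` (the multiple-quantum model is invariant under a joint
#' sign flip), so the absolute sign of `dw_c` fixes both nuclei.  Residues
#' with undetermined signs yield both candidate entries, flagged
#' `ambiguous`.
#'
#' @param ground Ground-state peak list (tibble with `residue`,
#'   `delta_h_ppm`, `delta_c_ppm` and optional `sigma_h`, `sigma_c`).
#' @param fit A `"disp_fit"` object covering the residues to reconstruct.
#' @param signs Tibble with `residue` and `sign_c` (`+1`, `-1` or NA).
#' @return A shift table: `residue`, `delta_h_ppm`, `delta_c_ppm`,
#'   `sigma_h`, `sigma_c` (fit errors and ground uncertainties combined in
#'   quadrature), `ambiguous`.
#' @export
reconstruct_excited_shifts <- function(ground, fit, signs) {
  ground <- .validate_r2eff_table(ground, need = c("residue", "delta_h_ppm", "delta_c_ppm"))
  signs <- .validate_r2eff_table(signs, need = c("residue", "sign_c"))
  stopifnot(inherits(fit, "disp_fit"))
  res <- fit$residues
  missing_res <- setdiff(res$residue, ground$residue)
  if (length(missing_res)) {
    abort(paste0("residue(s) in fit but absent from the ground-state table: ",
                 paste(missing_res, collapse = ", ")))
  }
  if (!"sigma_h" %in% names(ground)) ground$sigma_h <- 0
  if (!"sigma_c" %in% names(ground)) ground$sigma_c <- 0
  out <- lapply(seq_len(nrow(res)), function(i) {
    g <- ground[ground$residue == res$residue[i], ]
    s <- signs$sign_c[match(res$residue[i], signs$residue)]
    sgns <- if (length(s) == 0 || is.na(s)) c(1, -1) else s
    tibble(residue = res$residue[i],
           delta_h_ppm = g$delta_h_ppm + sgns * res$dw_h[i],
           delta_c_ppm = g$delta_c_ppm + sgns * abs(res$dw_c[i]),
           sigma_h = sqrt(g$sigma_h^2 + res$se_dw_h[i]^2),
           sigma_c = sqrt(g$sigma_c^2 + res$se_dw_c[i]^2),
           ambiguous = length(sgns) > 1)
  })
  bind_rows(out)
}

#' Discriminate 2-, 3- and 4-state conformational equilibria
#'
#' Given the four shift tables (two ground states and the two reconstructed
#' excited states) the hypotheses imply characteristic coincidences:
#' in a two-state equilibrium the ATP excited state is the ADP ground state
#' (and vice versa); in a three-state equilibrium the two excited states
#' coincide; in a four-state equilibrium all four conformations differ.
#' For each relevant pair the per-residue 13C shift difference of
#' non-excluded residues is compared against `z` pooled sigmas;
#' a pair is discordant when at least `min_off` residues lie off the
#' diagonal.  Residues whose ground-state shifts differ between the two
#' ligand states ("boxed") must be excluded, since nucleotide chemistry
#' alone can explain their differences.
#'
#' @param tables Named list of four shift tables: `ATP`, `ADP`, `ATP*`,
#'   `ADP*` (tibbles with `residue`, `delta_c_ppm`, optionally
#'   `delta_h_ppm`, `sigma_c`).
#' @param exclude Character vector of boxed residues.
#' @param z Off-diagonal significance threshold in pooled sigmas.
#' @param min_off Minimum number of off-diagonal residues for a pair to be
#'   called discordant.
#' @return A `"state_model_verdict"`: list with `verdict` (`"2-state"`,
#'   `"3-state"`, `"4-state"`, `"indistinguishable"` or
#'   `"insufficient evidence"`), `comparisons` (per-residue concordance
#'   table over all compared pairs) and `pair_summary`.
#' @examples
#' sc <- simulate_shift_tables("two_state", separation = 0.5, seed = 4)
#' compare_state_models(sc$tables, exclude = sc$exclude)$verdict
#' @export
compare_state_models <- function(tables, exclude = character(0), z = 3, min_off = 2) {
  need <- c("ATP", "ADP", "ATP*", "ADP*")
  if (!all(need %in% names(tables))) {
    abort(paste0("`tables` must contain: ", paste(need, collapse = ", ")))
  }
  tables <- lapply(tables, .validate_r2eff_table, need = c("residue", "delta_c_ppm"))
  shared <- Reduce(intersect, lapply(tables, function(t) t$residue))
  used <- setdiff(shared, exclude)
  pairs <- list(c("ADP", "ATP*"), c("ATP", "ADP*"), c("ATP*", "ADP*"), c("ATP", "ADP"))
  comparisons <- bind_rows(lapply(pairs, function(pr) {
    a <- tables[[pr[1]]]; b <- tables[[pr[2]]]
    ia <- match(shared, a$residue); ib <- match(shared, b$residue)
    sa <- if ("sigma_c" %in% names(a)) a$sigma_c[ia] else 0
    sb <- if ("sigma_c" %in% names(b)) b$sigma_c[ib] else 0
    pooled <- sqrt(sa^2 + sb^2)
    pooled[pooled == 0] <- 1e-6
    tibble(pair = paste(pr, collapse = " vs "),
           residue = shared,
           diff_c = a$delta_c_ppm[ia] - b$delta_c_ppm[ib],
           pooled_sigma = pooled,
           excluded = shared %in% exclude,
           off_diagonal = abs(a$delta_c_ppm[ia] - b$delta_c_ppm[ib]) > z * pooled)
  }))
  if (!length(used)) {
    verdict <- "insufficient evidence"
  } else {
    n_off <- function(pr) {
      d <- comparisons[comparisons$pair == pr & !comparisons$excluded, ]
      sum(d$off_diagonal)
    }
    discordant <- vapply(c("ADP vs ATP*", "ATP vs ADP*", "ATP* vs ADP*", "ATP vs ADP"),
                         function(pr) n_off(pr) >= min_off, logical(1))
    verdict <- if (!any(discordant)) "indistinguishable"
      else if (!discordant[["ADP vs ATP*"]]) "2-state"
      else if (!discordant[["ATP* vs ADP*"]]) "3-state"
      else "4-state"
  }
  pair_summary <- comparisons %>%
    filter(!excluded) %>%
    group_by(pair) %>%
    summarise(n_off = sum(off_diagonal), n_used = n(), .groups = "drop")
  structure(list(verdict = verdict, comparisons = comparisons,
                 pair_summary = pair_summary, z = z, min_off = min_off,
                 excluded = exclude),
            class = "state_model_verdict")
}

#' @export
print.state_model_verdict <- function(x, ...) {
  cat(sprintf("<state_model_verdict> minimal consistent model: %s\n", x$verdict))
  cat(sprintf("  off-diagonal threshold: %g pooled sigma(s); discordance at >= %d residue(s)\n",
              x$z, x$min_off))
  print(x$pair_summary)
  invisible(x)
}

#' @export
tidy.state_model_verdict <- function(x, ...) x$comparisons

#' @export
glance.state_model_verdict <- function(x, ...) {
  tibble(verdict = x$verdict, n_excluded = length(x$excluded),
         z = x$z, min_off = x$min_off)
}

#' Scatter plots of state-model shift comparisons
#'
#' One panel per compared pair of states, 13C shifts of one state against
#' the other; boxed (excluded) residues are hollow, off-diagonal residues
#' highlighted.
#'
#' @param object A `"state_model_verdict"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_model_verdict <- function(object, ...) {
  d <- object$comparisons %>%
    mutate(x = diff_c, status = dplyr::case_when(
      excluded ~ "excluded",
      off_diagonal ~ "off-diagonal",
      TRUE ~ "on-diagonal"))
  ggplot2::ggplot(d, ggplot2::aes(residue, diff_c, colour = status, shape = status)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ pair) +
    ggplot2::labs(y = expression(Delta * delta * ""^13 * C ~ "(ppm)"), x = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}
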