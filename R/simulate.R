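# Synthetic-data generator: dispersion datasets, shift tables and
# sign-determination inputs with the statistical structure the analysis
# assumes, so that every pipeline stage is testable end to end.  All
# residue-level quantities (per-residue shift differences, intrinsic rates,
# noise realisations) are synthetic draws; only the global exchange
# parameters of the built-in scenarios are anchored to reported values.

# Isoleucine delta1-methyl probes.  The resolved set and the subsets that
# show dispersion in each ligand state mirror the study design; labels
# beyond the named dynamic residues are synthetic placeholders.
.ILE_RESOLVED <- c("I4", "I34", "I64", "I71", "I75", "I85", "I93", "I104",
                   "I122", "I151", "I165", "I175", "I188", "I208", "I223",
                   "I250", "I274", "I282", "I289", "I298", "I317", "I327",
                   "I341", "I357")
.ILE_OVERLAPPED <- c("I136", "I309", "I369")
.DYNAMIC <- list(
  ATP   = c("I64", "I75", "I175", "I208", "I274", "I282", "I289", "I317", "I327"),
  ADP   = c("I34", "I64", "I71", "I75", "I85", "I317"),
  K118N = c("I64", "I75", "I175", "I208", "I274", "I282", "I289", "I317", "I327"))

.default_experiments <- function(name) {
  mq600 <- list(experiment = "MQ", field_mhz = 600, t_relax_s = 0.025,
                nu_cpmg_hz = seq(80, 880, by = 80))
  mq800 <- list(experiment = "MQ", field_mhz = 800, t_relax_s = 0.025,
                nu_cpmg_hz = seq(80, 960, by = 80))
  sq_atp <- function(f) list(experiment = "SQ_H", field_mhz = f, t_relax_s = 0.030,
                             nu_cpmg_hz = c(2, 3, 5, 7, 10, 13, 16, 20, 24, 27, 30) / 0.030)
  sq_adp <- function(f) list(experiment = "SQ_H", field_mhz = f, t_relax_s = 0.025,
                             nu_cpmg_hz = c(2, 3, 5, 7, 10, 13, 16, 19, 22, 25) / 0.025)
  sq_c   <- function(f) list(experiment = "SQ_C", field_mhz = f, t_relax_s = 0.025,
                             nu_cpmg_hz = c(2, 3, 5, 7, 10, 13, 16, 19, 22, 25) / 0.025)
  switch(name,
    ATP   = list(mq600, mq800, sq_atp(600), sq_atp(800)),
    ADP   = list(mq600, mq800, sq_adp(600), sq_adp(800)),
    K118N = list(mq600, mq800, sq_c(600), sq_c(800)))
}

#' Define a synthetic-dispersion scenario
#'
#' A scenario fixes the ground truth of a synthetic multi-field CPMG study:
#' shared two-state exchange parameters (`kex`, `p_b`), which residues carry
#' exchange, the ranges the per-residue shift differences and intrinsic
#' rates are drawn from, the experiment geometries, the intensity noise and
#' the replicate schedule.  The built-in scenarios use the fitted global
#' parameters reported for Ca2+-ATP-actin (`kex = 510` 1/s, `p_b = 0.83%`,
#' 9 dispersive residues, 1H/13C MQ + 1H SQ at 600 and 800 MHz),
#' Ca2+-ADP-actin (`kex = 1194` 1/s, `p_b = 10%`, 6 dispersive residues)
#' and the fast-nucleating K118N mutant (`kex = 450` 1/s, `p_b = 1.6%`,
#' MQ + 13C SQ) as ground truth.
#'
#' @param name `"ATP"`, `"ADP"` or `"K118N"`.
#' @param ... Overrides for any spec field: `kex`, `p_b`, `residues`
#'   (character vector of resolved residues), `dynamic_residues`,
#'   `dw_c_range` / `dw_h_range` (ppm magnitude ranges for dispersive
#'   residues; signs are drawn at random), `r2_0_range` (1/s),
#'   `experiments` (list of lists with `experiment`, `field_mhz`,
#'   `t_relax_s`, `nu_cpmg_hz`), `noise_frac` (intensity noise as a
#'   fraction of the reference intensity), `i0` (reference intensity),
#'   `n_duplicates` (named vector, replicated points per dataset by field).
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec("ATP")
#' scenario_spec("ADP", noise_frac = 0.002)
#' @export
scenario_spec <- function(name = c("ATP", "ADP", "K118N"), ...) {
  name <- match.arg(name)
  spec <- list(
    name = name,
    kex = switch(name, ATP = 510, ADP = 1194, K118N = 450),
    p_b = switch(name, ATP = 0.0083, ADP = 0.10, K118N = 0.016),
    residues = .ILE_RESOLVED,
    dynamic_residues = .DYNAMIC[[name]],
    dw_c_range = c(0.5, 2.5),
    dw_h_range = switch(name, ADP = c(0.02, 0.08), c(0, 0.05)),
    r2_0_range = c(8, 25),
    experiments = .default_experiments(name),
    noise_frac = 0.005,
    i0 = 1000,
    n_duplicates = c("600" = 2, "800" = 3))
  over <- list(...)
  unknown <- setdiff(names(over), names(spec))
  if (length(unknown)) abort(paste0("unknown scenario field(s): ", paste(unknown, collapse = ", ")))
  spec <- modifyList(spec, over)
  stopifnot(spec$kex > 0, spec$p_b > 0, spec$p_b < 0.5,
            all(spec$dynamic_residues %in% spec$residues))
  structure(spec, class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: kex = %g /s, p_b = %g, %d/%d dispersive residues, %d experiments\n",
              x$name, x$kex, x$p_b, length(x$dynamic_residues),
              length(x$residues), length(x$experiments)))
  invisible(x)
}

#' Simulate a multi-field CPMG dispersion dataset
#'
#' Draws per-residue ground truths (signed `dw_h`, `dw_c` for dispersive
#' residues, zero otherwise; per-curve intrinsic rates), evaluates the exact
#' forward model for every experiment, adds Gaussian noise at the intensity
#' level (including the reference point), inserts replicate measurements
#' according to the schedule, and converts back to `R2eff` through
#' [add_r2eff()] so the synthetic data pass through the same reduction as a
#' real dataset.
#'
#' @param spec A [scenario_spec()] (or a scenario name).
#' @param seed Integer seed; the same spec and seed reproduce the dataset
#'   bit for bit.
#' @return A tidy R2eff table (class `"disp_data"`).  Attributes: `truth`
#'   (list with the generating `kex`, `p_b`, per-residue shift differences
#'   and per-curve `r2_0`), `intensities` (the intensity-level table) and
#'   `spec`.
#' @examples
#' d <- simulate_dispersion(scenario_spec("ATP"), seed = 1)
#' dplyr::count(d, experiment, field_mhz)
#' @export
simulate_dispersion <- function(spec, seed) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"), is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer(seed), {
    res_truth <- tibble(
      residue = spec$residues,
      dynamic = spec$residues %in% spec$dynamic_residues) %>%
      mutate(
        dw_c = ifelse(dynamic, runif(n(), spec$dw_c_range[1], spec$dw_c_range[2]) *
                        sample(c(-1, 1), n(), replace = TRUE), 0),
        dw_h = ifelse(dynamic, runif(n(), spec$dw_h_range[1], spec$dw_h_range[2]) *
                        sample(c(-1, 1), n(), replace = TRUE), 0))
    sigma_i <- spec$noise_frac * spec$i0
    rows <- list(); truth_r2 <- list()
    for (ex in spec$experiments) {
      ndup <- spec$n_duplicates[[as.character(ex$field_mhz)]]
      if (is.null(ndup) || is.na(ndup)) ndup <- 2
      nu <- ex$nu_cpmg_hz
      dup_idx <- if (ndup <= length(nu)) {
        unique(round(seq(1, length(nu), length.out = ndup)))
      } else {
        rep(seq_along(nu), length.out = ndup)   # heavy replicate schedules
      }
      nu_all <- sort(c(nu, nu[dup_idx]))
      n_pulses <- .snap_ncpmg(nu_all, ex$t_relax_s, even = ex$experiment == "MQ")
      nu_snap <- n_pulses / ex$t_relax_s
      for (i in seq_len(nrow(res_truth))) {
        r2_0 <- runif(1, spec$r2_0_range[1], spec$r2_0_range[2])
        r2 <- .r2eff_model(ex$experiment, ex$field_mhz, ex$t_relax_s, n_pulses,
                           spec$kex, spec$p_b, res_truth$dw_h[i], res_truth$dw_c[i], r2_0)
        ideal <- spec$i0 * exp(-r2 * ex$t_relax_s)
        rows[[length(rows) + 1]] <- tibble(
          residue = res_truth$residue[i], experiment = ex$experiment,
          field_mhz = ex$field_mhz, t_relax_s = ex$t_relax_s,
          nu_cpmg_hz = c(0, nu_snap),
          intensity = c(spec$i0, ideal) + rnorm(length(nu_snap) + 1, 0, sigma_i),
          sigma = sigma_i)
        truth_r2[[length(truth_r2) + 1]] <- tibble(
          residue = res_truth$residue[i], experiment = ex$experiment,
          field_mhz = ex$field_mhz, t_relax_s = ex$t_relax_s, r2_0 = r2_0)
      }
    }
    intens <- bind_rows(rows)
    out <- add_r2eff(intens)
    attr(out, "truth") <- list(kex = spec$kex, p_b = spec$p_b,
                               residues = res_truth, r2_0 = bind_rows(truth_r2),
                               sigma_i = sigma_i, seed = as.integer(seed))
    attr(out, "intensities") <- intens
    attr(out, "spec") <- spec
    class(out) <- c("disp_data", class(out))
    out
  })
}

#' Ground truth of a simulated dataset
#'
#' @param data A `"disp_data"` object from [simulate_dispersion()].
#' @return The truth record: a list with `kex`, `p_b`, a per-residue tibble
#'   (`residues`) and per-curve intrinsic rates (`r2_0`).
#' @export
dispersion_truth <- function(data) {
  truth <- attr(data, "truth")
  if (is.null(truth)) abort("`data` carries no truth record (not simulated?)")
  truth
}

#' Simulate ground- and excited-state shift tables under a state-model
#' hypothesis
#'
#' Builds the four chemical-shift tables (ATP and ADP ground states, ATP*
#' and ADP* excited states) that a conformational-equilibrium comparison
#' consumes, under a chosen hypothesis: `"two_state"` (ATP* coincides with
#' the ADP ground state and ADP* with ATP), `"three_state"` (ATP* and ADP*
#' share one conformation distinct from both grounds) or `"four_state"`
#' (all four conformations distinct).  A subset of residues is given
#' ground-state differences between the two ligand states ("boxed"
#' residues) to exercise the exclusion logic.
#'
#' @param hypothesis `"two_state"`, `"three_state"` or `"four_state"`.
#' @param separation Conformational separation scale in ppm (13C; the 1H
#'   scale is one tenth of it), `>= 0`.  At `0` all four tables coincide.
#' @param seed Integer seed.
#' @param n_residues Number of residues in the tables.
#' @param n_boxed Number of residues given ground-state differences.
#' @param sigma_c,sigma_h Per-residue one-sigma shift uncertainties (ppm).
#' @return A list with elements `tables` (named list of four shift tables:
#'   tibbles with `residue`, `delta_h_ppm`, `delta_c_ppm`, `sigma_h`,
#'   `sigma_c`), `exclude` (the boxed residues) and `hypothesis`.
#' @examples
#' sc <- simulate_shift_tables("four_state", separation = 0.5, seed = 1)
#' compare_state_models(sc$tables, exclude = sc$exclude)
#' @export
simulate_shift_tables <- function(hypothesis = c("two_state", "three_state", "four_state"),
                                  separation = 0.5, seed = 1,
                                  n_residues = 24, n_boxed = 6,
                                  sigma_c = 0.01, sigma_h = 0.002) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(separation >= 0, n_boxed < n_residues)
  withr::with_seed(as.integer(seed), {
    residues <- .ILE_RESOLVED[seq_len(min(n_residues, length(.ILE_RESOLVED)))]
    if (n_residues > length(residues)) {
      residues <- c(residues, sprintf("I%d", 400 + seq_len(n_residues - length(residues))))
    }
    base <- tibble(residue = residues,
                   delta_h_ppm = runif(n_residues, 0.4, 1.1),
                   delta_c_ppm = runif(n_residues, 9.5, 14.5))
    boxed <- sample(residues, n_boxed)
    offset <- function(scale_c) {
      # offset magnitudes bounded away from zero so `separation` really is
      # the conformational separation scale
      tibble(residue = residues,
             off_h = sample(c(-1, 1), n_residues, TRUE) *
               runif(n_residues, 0.5, 1.5) * scale_c / 10,
             off_c = sample(c(-1, 1), n_residues, TRUE) *
               runif(n_residues, 0.5, 1.5) * scale_c)
    }
    apply_off <- function(tbl, off, which_res = residues) {
      i <- match(tbl$residue, off$residue)
      sel <- tbl$residue %in% which_res
      tbl$delta_h_ppm <- tbl$delta_h_ppm + ifelse(sel, off$off_h[i], 0)
      tbl$delta_c_ppm <- tbl$delta_c_ppm + ifelse(sel, off$off_c[i], 0)
      tbl
    }
    finish <- function(tbl) {
      tbl %>% mutate(sigma_h = sigma_h, sigma_c = sigma_c,
                     delta_h_ppm = delta_h_ppm + rnorm(n(), 0, sigma_h),
                     delta_c_ppm = delta_c_ppm + rnorm(n(), 0, sigma_c))
    }
    atp <- base
    adp <- apply_off(base, offset(separation), boxed)   # boxed ground differences
    conf1 <- offset(separation)                         # conformational change 1
    conf2 <- offset(separation)                         # conformational change 2
    tabs <- switch(hypothesis,
      two_state = list(ATP = atp, ADP = apply_off(atp, conf1),
                       `ATP*` = apply_off(atp, conf1), `ADP*` = atp),
      three_state = list(ATP = atp, ADP = adp,
                         `ATP*` = apply_off(base, conf1), `ADP*` = apply_off(base, conf1)),
      four_state = list(ATP = atp, ADP = adp,
                        `ATP*` = apply_off(base, conf1), `ADP*` = apply_off(base, conf2)))
    exclude <- if (hypothesis == "two_state") character(0) else boxed
    list(tables = lapply(tabs, finish), exclude = exclude, hypothesis = hypothesis)
  })
}

#' Simulate peak positions for shift-difference sign determination
#'
#' Computes the exchange-shifted ground-state 13C peak positions expected in
#' single-quantum (HSQC-type) and multiple-quantum (HMQC-type) spectra from
#' the slow eigenvalue of the coherence evolution matrix, then adds Gaussian
#' position noise, producing the observed-position inputs that
#' [determine_sign()] consumes.
#'
#' @param params A [two_state_params()] with the signed `dw_c` (and `dw_h`)
#'   to emulate.
#' @param field_h1 1H Larmor frequency in MHz.
#' @param delta_c0 Exchange-free ground-state 13C shift (ppm).
#' @param position_sigma One-sigma peak-position noise in ppm.
#' @param seed Integer seed.
#' @return A tibble with one row: `delta_c_sq`, `delta_c_mq` (observed
#'   positions, ppm), the noise level and the true underlying positions.
#' @export
simulate_sign_inputs <- function(params, field_h1 = 800, delta_c0 = 12,
                                 position_sigma = 0.002, seed = 1) {
  stopifnot(inherits(params, "two_state_params"))
  pos <- .exchange_peak_shifts(params, field_h1)
  withr::with_seed(as.integer(seed), {
    tibble(delta_c_sq = delta_c0 + pos$sq + rnorm(1, 0, position_sigma),
           delta_c_mq = delta_c0 + pos$mq + rnorm(1, 0, position_sigma),
           position_sigma = position_sigma,
           true_sq = delta_c0 + pos$sq, true_mq = delta_c0 + pos$mq)
  })
}
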