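# Intensity-level preprocessing: conversion of raw peak-intensity tables to
# effective relaxation rates with per-point uncertainties estimated from
# replicated nu_CPMG measurements.

#' Per-point R2eff uncertainties from replicated measurements
#'
#' Estimates the intensity noise of each dataset (one `experiment` x
#' `field_mhz` combination) as the pooled standard deviation over all
#' replicated `nu_CPMG` points (pooled with `n - 1` denominators across
#' replicate groups), floors it by the nominal spectral noise in the `sigma`
#' column when one is provided, and propagates it to each point as
#' `sigma(R2eff) = sigma_I / (t_relax * I)`.
#'
#' @param data An intensity-level dispersion table: columns `residue`,
#'   `experiment`, `field_mhz`, `t_relax_s`, `nu_cpmg_hz`, `intensity`, and
#'   optionally `sigma` (nominal intensity noise) and `replicate`.
#'   Reference (no relaxation delay) rows are marked by `nu_cpmg_hz == 0`.
#' @return The input with columns `sigma_i` (intensity noise used) and
#'   `sigma_r2eff` added.
#' @examples
#' x <- tibble::tibble(
#'   residue = "I75", experiment = "MQ", field_mhz = 800, t_relax_s = 0.025,
#'   nu_cpmg_hz = c(0, 80, 80, 400), intensity = c(1000, 610, 590, 655))
#' propagate_duplicate_errors(x)
#' @export
propagate_duplicate_errors <- function(data) {
  data <- .validate_r2eff_table(data, need = c("residue", "experiment", "field_mhz",
                                               "t_relax_s", "nu_cpmg_hz", "intensity"))
  has_sigma <- "sigma" %in% names(data)
  data %>%
    group_by(experiment, field_mhz) %>%
    dplyr::group_modify(function(d, key) {
      reps <- d %>%
        filter(nu_cpmg_hz > 0) %>%
        group_by(residue, t_relax_s, nu_cpmg_hz) %>%
        summarise(nrep = n(), v = stats::var(intensity), .groups = "drop") %>%
        filter(nrep > 1)
      pooled <- if (nrow(reps)) {
        sqrt(sum((reps$nrep - 1) * reps$v) / sum(reps$nrep - 1))
      } else NA_real_
      nominal <- if (has_sigma) d$sigma else rep(NA_real_, nrow(d))
      if (is.na(pooled) && all(is.na(nominal))) {
        abort(sprintf(
          "dataset %s/%g MHz has no replicated nu_CPMG points and no `sigma` column: cannot weight the fit",
          key$experiment[[1]], key$field_mhz[[1]]))
      }
      sigma_i <- pmax(if (is.na(pooled)) 0 else pooled,
                      ifelse(is.na(nominal), 0, nominal))
      d$sigma_i <- sigma_i
      d$sigma_r2eff <- ifelse(d$nu_cpmg_hz > 0,
                              r2eff_sigma(d$intensity, sigma_i, d$t_relax_s),
                              NA_real_)
      d
    }) %>%
    ungroup()
}

#' Convert an intensity table to effective relaxation rates
#'
#' Applies the intensity equation `R2eff = -(1/t_relax) * log(I / I0)` per
#' point, taking `I0` as the mean of the reference rows (`nu_cpmg_hz == 0`)
#' of each curve, with per-point uncertainties from
#' [propagate_duplicate_errors()].
#'
#' @inheritParams propagate_duplicate_errors
#' @return A tidy R2eff table (columns `residue`, `experiment`, `field_mhz`,
#'   `t_relax_s`, `nu_cpmg_hz`, `r2eff`, `sigma`, `replicate`), ready for
#'   [fit_global()].
#' @export
add_r2eff <- function(data) {
  data <- propagate_duplicate_errors(data)
  refs <- data %>%
    filter(nu_cpmg_hz == 0) %>%
    group_by(residue, experiment, field_mhz, t_relax_s) %>%
    summarise(i0 = mean(intensity), .groups = "drop")
  if (!nrow(refs)) abort("no reference rows (nu_cpmg_hz == 0) found")
  out <- data %>%
    filter(nu_cpmg_hz > 0) %>%
    left_join(refs, by = c("residue", "experiment", "field_mhz", "t_relax_s"))
  if (any(is.na(out$i0))) {
    abort(paste0("missing reference intensity for: ",
                 paste(unique(out$residue[is.na(out$i0)]), collapse = ", ")))
  }
  out %>%
    mutate(r2eff = r2eff_from_intensities(intensity, i0, t_relax_s),
           sigma = sigma_r2eff) %>%
    group_by(residue, experiment, field_mhz, t_relax_s, nu_cpmg_hz) %>%
    mutate(replicate = row_number()) %>%
    ungroup() %>%
    select(residue, experiment, field_mhz, t_relax_s, nu_cpmg_hz,
           r2eff, sigma, replicate)
}
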