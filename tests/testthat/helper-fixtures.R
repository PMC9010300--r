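# Shared test utilities: independent limiting-law oracle, quick builders for
# clean synthetic curves, and a cheap scenario for fast fitting tests.

# Luz-Meiboom fast-exchange limit, written directly from the limiting law
# (independent of the package's propagator machinery).  nu convention:
# nu_cpmg = N / t_relax, half-echo delta = t_relax / (2 N).
luz_meiboom <- function(nu_cpmg, kex, p_b, dw_rad, r2_0, t_relax) {
  n <- round(nu_cpmg * t_relax)
  nu_lm <- 1 / (4 * (t_relax / (2 * n)))   # 1/(4 delta)
  r2_0 + (1 - p_b) * p_b * dw_rad^2 / kex *
    (1 - 4 * nu_lm / kex * tanh(kex / (4 * nu_lm)))
}

# Exact dispersion table for a set of residues from the forward model, with
# optional Gaussian noise; sigma is reported honestly either way.
make_curves <- function(residues, kex, p_b, dw_c, dw_h, r2_0 = 15,
                        noise = 0, seed = 1,
                        experiments = list(
                          list(experiment = "MQ", field_mhz = 600, t_relax_s = 0.025,
                               nu_cpmg_hz = seq(80, 880, 80)),
                          list(experiment = "MQ", field_mhz = 800, t_relax_s = 0.025,
                               nu_cpmg_hz = seq(80, 960, 80)))) {
  withr::with_seed(seed, {
    rows <- list()
    for (ex in experiments) {
      g <- experiment_geometry(ex$experiment, ex$field_mhz, ex$t_relax_s, ex$nu_cpmg_hz)
      for (i in seq_along(residues)) {
        p <- two_state_params(kex, p_b, dw_h = dw_h[i], dw_c = dw_c[i], r2_0 = r2_0)
        m <- closed_form_r2eff(p, g)
        rows[[length(rows) + 1]] <- tibble::tibble(
          residue = residues[i], experiment = ex$experiment,
          field_mhz = ex$field_mhz, t_relax_s = ex$t_relax_s,
          nu_cpmg_hz = m$nu_cpmg_hz,
          r2eff = m$r2eff + rnorm(nrow(m), 0, noise),
          sigma = max(noise, 1e-3))
      }
    }
    dplyr::bind_rows(rows)
  })
}

# Random valid parameter draws over the regime the models must cover.
draw_params <- function(n, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      kex = runif(n, 100, 3000),
      p_b = runif(n, 0.005, 0.2),
      dw_c = runif(n, 0, 3) * sample(c(-1, 1), n, TRUE),
      dw_h = runif(n, 0, 0.3) * sample(c(-1, 1), n, TRUE),
      field = sample(c(600, 800), n, TRUE),
      coherence = sample(c("MQ", "SQ_H", "SQ_C"), n, TRUE))
  })
}
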