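# Forward models for two-state chemical exchange in constant-time CPMG
# experiments: exact spectral propagation of single-quantum (1H or 13C) and
# 1H/13C multiple-quantum coherences through the explicit pulse train.

#' Describe a CPMG experiment
#'
#' Bundles the acquisition geometry of one constant-time CPMG experiment:
#' the coherence that relaxes during the pulse train, the static field
#' (expressed as the 1H Larmor frequency), the constant relaxation delay and
#' the grid of CPMG frequencies.
#'
#' The CPMG frequency convention is `nu_cpmg = N / t_relax`, with `N` the
#' number of 180-degree refocusing pulses in the constant-time element
#' (equivalently `1/(2*delta)` with `delta` the half-echo delay).  Requested
#' frequencies are snapped to the nearest realisable integer pulse count; a
#' warning is issued when the relative snap error exceeds 2%.  Multiple-
#' quantum experiments additionally require an even pulse count because a
#' single 1H refocusing pulse is applied at the midpoint of the element.
#'
#' @param coherence_type One of `"MQ"` (1H/13C multiple quantum), `"SQ_H"`
#'   (1H single quantum) or `"SQ_C"` (13C single quantum).
#' @param field_h1 1H Larmor frequency in MHz (e.g. 600 or 800).
#' @param t_relax Constant relaxation delay in seconds (e.g. 0.025).
#' @param nu_cpmg Numeric vector of CPMG frequencies in Hz.
#' @return An object of class `"experiment_geometry"`.
#' @examples
#' experiment_geometry("MQ", 800, 0.025, seq(80, 960, by = 80))
#' @export
experiment_geometry <- function(coherence_type = c("MQ", "SQ_H", "SQ_C"),
                                field_h1, t_relax, nu_cpmg) {
  coherence_type <- match.arg(coherence_type)
  stopifnot(is.numeric(field_h1), length(field_h1) == 1, field_h1 > 0,
            is.numeric(t_relax), length(t_relax) == 1, t_relax > 0,
            is.numeric(nu_cpmg), length(nu_cpmg) >= 1, all(nu_cpmg > 0))
  n <- .snap_ncpmg(nu_cpmg, t_relax, even = coherence_type == "MQ")
  structure(list(coherence_type = coherence_type, field_h1 = field_h1,
                 t_relax = t_relax, nu_cpmg = nu_cpmg, n_pulses = n),
            class = "experiment_geometry")
}

#' @export
print.experiment_geometry <- function(x, ...) {
  cat(sprintf("<experiment_geometry> %s at %g MHz, T_relax = %g ms, %d nu_CPMG points (%g-%g Hz)\n",
              x$coherence_type, x$field_h1, 1000 * x$t_relax,
              length(x$nu_cpmg), min(x$nu_cpmg), max(x$nu_cpmg)))
  invisible(x)
}

# Snap requested CPMG frequencies to integer pulse counts N = nu * t_relax.
.snap_ncpmg <- function(nu_cpmg, t_relax, even = FALSE) {
  n <- if (even) 2L * pmax(1L, as.integer(round(nu_cpmg * t_relax / 2)))
       else pmax(1L, as.integer(round(nu_cpmg * t_relax)))
  rel <- abs(n / t_relax - nu_cpmg) / nu_cpmg
  bad <- rel > .SNAP_TOL
  if (any(bad)) {
    warning(sprintf(
      "snapped %d nu_CPMG value(s) to an integer pulse count with > %g%% error: %s",
      sum(bad), 100 * .SNAP_TOL,
      paste(sprintf("%g -> %g Hz", nu_cpmg[bad], n[bad] / t_relax), collapse = ", ")))
  }
  n
}

#' Two-state exchange parameters
#'
#' Container for the parameters of a two-state (ground A, excited B)
#' exchange process as seen by one methyl probe: the global exchange rate
#' `kex = k_AB + k_BA` and excited-state population `p_b`, the per-residue
#' ground-to-excited chemical shift differences (`dw_h`, `dw_c`, in ppm,
#' signed as excited minus ground), and the exchange-free intrinsic
#' relaxation rate `r2_0` of the curve being modelled.  The ground and
#' excited states are assumed to share `r2_0`.
#'
#' @param kex Exchange rate in 1/s, `> 0`.
#' @param p_b Excited-state population, in `(0, 0.5)`; the `p_b < 0.5`
#'   convention breaks the `p_b <-> 1 - p_b` labelling symmetry.  `p_b = 0`
#'   is accepted as the degenerate no-exchange limit.
#' @param dw_h,dw_c 1H and 13C shift differences in ppm (signed).
#' @param r2_0 Intrinsic (exchange-free) transverse relaxation rate in 1/s.
#' @return An object of class `"two_state_params"`.
#' @examples
#' two_state_params(kex = 510, p_b = 0.0083, dw_c = 1.2)
#' @export
two_state_params <- function(kex, p_b, dw_h = 0, dw_c = 0, r2_0 = 0) {
  stopifnot(is.numeric(kex), length(kex) == 1, kex > 0,
            is.numeric(p_b), length(p_b) == 1, p_b >= 0, p_b < 0.5,
            is.numeric(dw_h), length(dw_h) == 1, is.finite(dw_h),
            is.numeric(dw_c), length(dw_c) == 1, is.finite(dw_c),
            is.numeric(r2_0), length(r2_0) == 1, r2_0 >= 0)
  structure(list(kex = kex, p_b = p_b, dw_h = dw_h, dw_c = dw_c, r2_0 = r2_0),
            class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf("<two_state_params> kex = %g /s, p_b = %g, dw_h = %g ppm, dw_c = %g ppm, r2_0 = %g /s\n",
              x$kex, x$p_b, x$dw_h, x$dw_c, x$r2_0))
  invisible(x)
}

#' Effective relaxation rate from peak intensities
#'
#' Converts a peak intensity measured after a constant relaxation delay into
#' an effective transverse relaxation rate,
#' `R2eff = -(1/t_relax) * log(i_nu / i0)`, where `i0` is the intensity in a
#' reference spectrum recorded without the relaxation delay.
#'
#' @param i_nu Peak intensity (vector) at a given CPMG frequency.
#' @param i0 Reference intensity, `> 0`.
#' @param t_relax Constant relaxation delay in seconds, `> 0`.
#' @return `R2eff` in 1/s.
#' @seealso [r2eff_sigma()] for first-order error propagation.
#' @examples
#' r2eff_from_intensities(60, 100, 0.030)
#' @export
r2eff_from_intensities <- function(i_nu, i0, t_relax) {
  if (any(!is.finite(i0)) || any(i0 <= 0)) abort("invalid reference intensity: `i0` must be > 0")
  if (any(t_relax <= 0)) abort("`t_relax` must be > 0")
  if (any(!is.finite(i_nu)) || any(i_nu <= 0)) {
    abort("non-physical intensity: `i_nu` must be > 0 (peak lost in noise?)")
  }
  -log(i_nu / i0) / t_relax
}

#' @rdname r2eff_from_intensities
#' @param sigma_i One-sigma intensity noise.
#' @return `r2eff_sigma()` returns the propagated `sigma(R2eff) =
#'   sigma_i / (t_relax * i_nu)` in 1/s.
#' @export
r2eff_sigma <- function(i_nu, sigma_i, t_relax) {
  stopifnot(all(i_nu > 0), all(sigma_i >= 0), all(t_relax > 0))
  sigma_i / (t_relax * i_nu)
}

#' Microscopic rate constants of a two-state exchange
#'
#' `k_AB = p_b * kex` and `k_BA = (1 - p_b) * kex`, so that
#' `k_AB + k_BA = kex` and detailed balance `p_a * k_AB = p_b * k_BA` holds.
#'
#' @param p_b Excited-state population(s), in `[0, 1)`.
#' @param kex Exchange rate(s) in 1/s, `>= 0`.
#' @return A tibble with columns `k_ab` and `k_ba` (1/s).
#' @examples
#' derive_rates(p_b = 0.0083, kex = 510)
#' @export
derive_rates <- function(p_b, kex) {
  if (any(p_b < 0 | p_b >= 1)) abort("`p_b` must lie in [0, 1)")
  if (any(kex < 0)) abort("`kex` must be >= 0")
  tibble(k_ab = p_b * kex, k_ba = (1 - p_b) * kex)
}

#' Convert a chemical shift difference from ppm to rad/s
#'
#' `2 * pi * delta_ppm * nu_nucleus(field_h1)` with the 13C Larmor frequency
#' derived from the 1H frequency through the fixed ratio [GAMMA_C_OVER_H].
#'
#' @param delta_ppm Shift difference(s) in ppm.
#' @param nucleus `"H1"` or `"C13"`.
#' @param field_h1 1H Larmor frequency in MHz.
#' @return Angular frequency in rad/s.
#' @examples
#' ppm_to_rad_s(1, "C13", 800)
#' @export
ppm_to_rad_s <- function(delta_ppm, nucleus = c("H1", "C13"), field_h1) {
  nucleus <- match.arg(nucleus)
  if (any(field_h1 <= 0)) abort("`field_h1` must be > 0")
  nu_mhz <- switch(nucleus, H1 = field_h1, C13 = field_h1 * GAMMA_C_OVER_H)
  2 * pi * delta_ppm * nu_mhz
}

# ---- closed-form (spectral) engines -------------------------------------
#
# Single quantum: the element (delta - 180 - delta) maps the transverse
# magnetisation vector m -> A Conj(A m) with A = exp((K + i W) delta); over
# pairs of echoes the propagator is W2 = A Ab Ab A (Ab = Conj(A)), applied
# via its spectral decomposition.  Intensity is the ground-state component,
# normalised to the reference p_a.
.r2eff_sq_closed <- function(n_pulses, t_relax, kex, p_b, dw_rad, r2_0) {
  kab <- p_b * kex; kba <- (1 - p_b) * kex; pa <- 1 - p_b
  d <- t_relax / (2 * n_pulses)
  a <- .m2_exp_exchange(kab, kba, dw_rad, d)
  ab <- .m2_conj(a)
  aab <- .m2_mul(a, ab)
  w2 <- .m2_mul(aab, .m2_mul(ab, a))
  k <- n_pulses %/% 2L
  even <- n_pulses %% 2L == 0L
  prop <- .m2_pow(w2, k)
  if (!all(even)) {
    odd_prop <- .m2_mul(aab, .m2_pow(.m2_conj(w2), k))
    for (f in names(prop)) prop[[f]][!even] <- odd_prop[[f]][!even]
  }
  v <- .m2_vec(prop, list(x1 = rep(pa + 0i, length(n_pulses)), x2 = rep(p_b + 0i, length(n_pulses))))
  intens <- pmax(Re(v$x1), 1e-300)
  r2_0 - log(intens / pa) / t_relax
}

# Multiple quantum: the methyl 1H/13C MQ coherence passes alternately
# through double-quantum (frequency WH + WC) and zero-quantum (WH - WC)
# evolution as the 13C 180 train interchanges the two; the ground-state
# component is detected.  The first half-echo evolves as DQ, so one pair of
# echoes is propagated by A B B A with A = exp((K + i(WH+WC))d),
# B = exp((K + i(WH-WC))d).  This is what makes MQ dispersion sensitive to
# the relative sign of the two shift differences (at WH = 0 it reduces
# exactly to the single-quantum propagator).  Pulse counts are even.
.r2eff_mq_closed <- function(n_pulses, t_relax, kex, p_b, dwh_rad, dwc_rad, r2_0) {
  kab <- p_b * kex; kba <- (1 - p_b) * kex; pa <- 1 - p_b
  d <- t_relax / (2 * n_pulses)
  a_m <- .m2_exp_exchange(kab, kba, dwh_rad + dwc_rad, d)
  b_m <- .m2_exp_exchange(kab, kba, dwh_rad - dwc_rad, d)
  w2 <- .m2_mul(.m2_mul(a_m, b_m), .m2_mul(b_m, a_m))   # two echoes: A B B A
  len <- length(n_pulses)
  v <- .m2_vec(.m2_pow(w2, n_pulses %/% 2L),
               list(x1 = rep(pa + 0i, len), x2 = rep(p_b + 0i, len)))
  intens <- pmax(Re(v$x1), 1e-300)
  r2_0 - log(intens / pa) / t_relax
}

# Dispatch on coherence type; dw in ppm, converted here and only here.
.r2eff_model <- function(coherence_type, field_h1, t_relax, n_pulses,
                         kex, p_b, dw_h, dw_c, r2_0 = 0) {
  if (p_b == 0 || kex == 0) return(rep(r2_0, length(n_pulses)))
  dwh_rad <- ppm_to_rad_s(dw_h, "H1", field_h1)
  dwc_rad <- ppm_to_rad_s(dw_c, "C13", field_h1)
  switch(coherence_type,
    MQ   = .r2eff_mq_closed(n_pulses, t_relax, kex, p_b, dwh_rad, dwc_rad, r2_0),
    SQ_H = .r2eff_sq_closed(n_pulses, t_relax, kex, p_b, dwh_rad, r2_0),
    SQ_C = .r2eff_sq_closed(n_pulses, t_relax, kex, p_b, dwc_rad, r2_0),
    abort(paste0("unknown coherence type: ", coherence_type)))
}

#' Closed-form dispersion profile for two-state exchange
#'
#' Computes `R2eff` at each CPMG frequency of `geometry` for a two-state
#' exchange process, using the exact spectral (eigenvalue) solution of the
#' pulse-train propagator: the Carver-Richards-type result for single-
#' quantum coherences and its multiple-quantum extension (joint evolution of
#' double- and zero-quantum coherences, which depends on the relative sign
#' of `dw_h` and `dw_c`).  Agrees with the brute-force propagator
#' [bloch_mcconnell_r2eff()] to numerical precision and is fast enough to
#' serve as the fitting workhorse.
#'
#' @param params A [two_state_params()] object.
#' @param geometry An [experiment_geometry()] object.
#' @return A tibble with columns `nu_cpmg_hz` (snapped to the realised pulse
#'   count) and `r2eff` (1/s).
#' @examples
#' g <- experiment_geometry("MQ", 800, 0.025, seq(80, 960, 80))
#' closed_form_r2eff(two_state_params(510, 0.0083, dw_c = 1), g)
#' @export
closed_form_r2eff <- function(params, geometry) {
  stopifnot(inherits(params, "two_state_params"), inherits(geometry, "experiment_geometry"))
  r2 <- .r2eff_model(geometry$coherence_type, geometry$field_h1, geometry$t_relax,
                     geometry$n_pulses, params$kex, params$p_b,
                     params$dw_h, params$dw_c, params$r2_0)
  tibble(nu_cpmg_hz = geometry$n_pulses / geometry$t_relax, r2eff = r2)
}

# ---- brute-force numerical oracle ---------------------------------------

.cmat_exp <- function(l) {
  ev <- eigen(l)
  ev$vectors %*% diag(exp(ev$values), nrow(l)) %*% solve(ev$vectors)
}

#' Numerically propagated dispersion profile (oracle)
#'
#' Brute-force counterpart of [closed_form_r2eff()]: propagates the
#' two-state evolution matrix for the named coherence pulse by pulse through
#' the explicit CPMG train (complex 2x2 exponentials per free-precession
#' interval; 180-degree pulses as conjugation for single-quantum, as
#' double-/zero-quantum interchange for multiple-quantum) and converts the end-point ground-state magnetisation
#' to `R2eff` through the intensity equation.  Slow but assumption-free; it
#' is the numerical oracle the closed form is tested against.
#'
#' @inheritParams closed_form_r2eff
#' @return A tibble with columns `nu_cpmg_hz` and `r2eff`.
#' @export
bloch_mcconnell_r2eff <- function(params, geometry) {
  stopifnot(inherits(params, "two_state_params"), inherits(geometry, "experiment_geometry"))
  kab <- params$p_b * params$kex
  kba <- (1 - params$p_b) * params$kex
  pa <- 1 - params$p_b
  k_mat <- matrix(c(-kab, kab, kba, -kba), 2)
  t_relax <- geometry$t_relax
  dwh <- ppm_to_rad_s(params$dw_h, "H1", geometry$field_h1)
  dwc <- ppm_to_rad_s(params$dw_c, "C13", geometry$field_h1)
  r2 <- vapply(geometry$n_pulses, function(n) {
    d <- t_relax / (2 * n)
    if (geometry$coherence_type == "MQ") {
      a <- .cmat_exp((k_mat + 1i * diag(c(0, dwh + dwc))) * d)
      b <- .cmat_exp((k_mat + 1i * diag(c(0, dwh - dwc))) * d)
      v <- c(pa, params$p_b)
      evo <- list(a, b)                 # first half-echo evolves as DQ
      for (j in seq_len(n)) {
        v <- evo[[2]] %*% (evo[[1]] %*% v)   # delta, 180C, delta
        evo <- rev(evo)
      }
      intens <- Re(v[1])
    } else {
      dw <- if (geometry$coherence_type == "SQ_H") dwh else dwc
      a <- .cmat_exp((k_mat + 1i * diag(c(0, dw))) * d)
      v <- c(pa, params$p_b)
      for (j in seq_len(n)) v <- a %*% Conj(a %*% v)
      intens <- Re(v[1])
    }
    params$r2_0 - log(max(intens, 1e-300) / pa) / t_relax
  }, numeric(1))
  tibble(nu_cpmg_hz = geometry$n_pulses / t_relax, r2eff = r2)
}

#' Carver-Richards approximation for single-quantum dispersion
#'
#' The classical analytical dispersion curve for single-quantum two-state
#' exchange (dominant-eigenvalue approximation, equal intrinsic rates).  It
#' neglects the finite-length amplitude ("end") effects that the exact
#' spectral solution [closed_form_r2eff()] retains, and deviates from it at
#' large excited-state populations in slow exchange; it is provided as an
#' independent reference expression.
#'
#' @inheritParams closed_form_r2eff
#' @return A tibble with columns `nu_cpmg_hz` and `r2eff`.
#' @export
carver_richards_r2eff <- function(params, geometry) {
  stopifnot(inherits(params, "two_state_params"), inherits(geometry, "experiment_geometry"))
  if (geometry$coherence_type == "MQ") {
    abort("carver_richards_r2eff() covers single-quantum coherences; use closed_form_r2eff() for MQ")
  }
  dw <- ppm_to_rad_s(if (geometry$coherence_type == "SQ_H") params$dw_h else params$dw_c,
                     if (geometry$coherence_type == "SQ_H") "H1" else "C13",
                     geometry$field_h1)
  kex <- params$kex; p_b <- params$p_b
  kab <- p_b * kex; kba <- (1 - p_b) * kex
  d <- geometry$t_relax / (2 * geometry$n_pulses)
  psi <- kex^2 - dw^2
  zeta <- -2 * dw * (kab - kba)
  s <- sqrt(psi^2 + zeta^2)
  dpos <- 0.5 * (1 + (psi + 2 * dw^2) / s)
  dneg <- 0.5 * (-1 + (psi + 2 * dw^2) / s)
  etap <- sqrt(2) * d * sqrt(psi + s)
  etam <- sqrt(2) * d * sqrt(pmax(-psi + s, 0))
  arg <- pmax(dpos * cosh(etap) - dneg * cos(etam), 1)
  tibble(nu_cpmg_hz = geometry$n_pulses / geometry$t_relax,
         r2eff = params$r2_0 + kex / 2 - acosh(arg) / (4 * d))
}

#' Dispersion amplitude of a measured profile
#'
#' `delta_r2 = R2eff(lowest nu_CPMG) - R2eff(highest nu_CPMG)`, the
#' difference in effective relaxation rate between the slowest and fastest
#' pulsing rates, computed per dispersion curve.  Replicate measurements at
#' an endpoint are averaged first.
#'
#' @param data A tidy dispersion table with columns `residue`, `experiment`,
#'   `field_mhz`, `t_relax_s`, `nu_cpmg_hz`, `r2eff`.
#' @return A tibble with one row per curve (`residue`, `experiment`,
#'   `field_mhz`, `t_relax_s`) and a `delta_r2` column (1/s).
#' @examples
#' d <- simulate_dispersion(scenario_spec("ATP"), seed = 1)
#' delta_r2(d)
#' @export
delta_r2 <- function(data) {
  data <- .validate_r2eff_table(data)
  out <- data %>%
    group_by(residue, experiment, field_mhz, t_relax_s) %>%
    summarise(delta_r2 = {
      if (dplyr::n_distinct(nu_cpmg_hz) < 2) {
        abort("delta_r2() needs >= 2 distinct nu_CPMG values per curve")
      }
      mean(r2eff[nu_cpmg_hz == min(nu_cpmg_hz)]) -
        mean(r2eff[nu_cpmg_hz == max(nu_cpmg_hz)])
    }, .groups = "drop")
  out
}

.validate_r2eff_table <- function(data, need = c("residue", "experiment", "field_mhz",
                                                 "t_relax_s", "nu_cpmg_hz", "r2eff")) {
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  as_tibble(data)
}
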