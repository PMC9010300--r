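# Individual and global two-state fitting of multi-field MQ + SQ dispersion
# data: variable-projection least squares (per-curve intrinsic rates are
# profiled out analytically), multi-start initialisation, covariance-based
# errors and the iterative chi-square-ratio pruning of discordant residues.
#
# For speed, all curves sharing a coherence type are evaluated in one
# vectorised pass (the spectral engine is elementwise in field, pulse count
# and shift difference), and the Jacobian exploits the fact that a
# residue's shift differences only touch its own points.

.FIT_BOUNDS <- list(kex = c(10, 1e4), p_b = c(1e-4, 0.499),
                    dw_c = c(0, 6), dw_h = c(-1, 1), r2_0 = c(0, 200))

# Default multi-start grid for per-residue fits.
.START_KEX <- c(100, 250, 500, 1000, 2000, 3000)
.START_PB <- c(0.005, 0.01, 0.05, 0.1, 0.2)

# Precompute the fitting structure: per-coherence point batches with pulse
# counts snapped once, plus curve and residue indices per point.
.fit_struct <- function(data) {
  data <- .validate_r2eff_table(data, need = c("residue", "experiment", "field_mhz",
                                               "t_relax_s", "nu_cpmg_hz", "r2eff", "sigma"))
  if (!nrow(data)) abort("no curves: the dispersion table is empty")
  if (any(!is.finite(data$sigma) | data$sigma <= 0)) {
    abort("every point needs a finite positive `sigma`")
  }
  curves <- data %>% distinct(residue, experiment, field_mhz, t_relax_s) %>%
    mutate(curve_id = row_number())
  residues <- unique(curves$residue)
  data <- data %>% left_join(curves, by = c("residue", "experiment", "field_mhz", "t_relax_s"))
  n_pulses <- integer(nrow(data))
  for (ci in curves$curve_id) {
    sel <- data$curve_id == ci
    n_pulses[sel] <- .snap_ncpmg(data$nu_cpmg_hz[sel], data$t_relax_s[sel][1],
                                 even = data$experiment[sel][1] == "MQ")
  }
  groups <- lapply(split(seq_len(nrow(data)), data$experiment), function(idx) {
    list(idx = idx, coherence = data$experiment[idx[1]],
         n_pulses = n_pulses[idx], t_relax = data$t_relax_s[idx],
         field = data$field_mhz[idx],
         res_i = match(data$residue[idx], residues))
  })
  list(data = data, curves = curves, residues = residues, groups = groups,
       obs = data$r2eff, w = 1 / data$sigma,
       curve_of_point = data$curve_id,
       residue_of_point = match(data$residue, residues),
       n_curves = nrow(curves))
}

# Exchange-free model vector (r2_0 = 0) over all points, struct order.
.model_vec <- function(struct, kex, p_b, dw_c, dw_h) {
  m <- numeric(length(struct$obs))
  for (g in struct$groups) {
    dwh_rad <- 2 * pi * dw_h[g$res_i] * g$field
    dwc_rad <- 2 * pi * dw_c[g$res_i] * g$field * GAMMA_C_OVER_H
    m[g$idx] <- switch(g$coherence,
      MQ   = .r2eff_mq_closed(g$n_pulses, g$t_relax, kex, p_b, dwh_rad, dwc_rad, 0),
      SQ_H = .r2eff_sq_closed(g$n_pulses, g$t_relax, kex, p_b, dwh_rad, 0),
      SQ_C = .r2eff_sq_closed(g$n_pulses, g$t_relax, kex, p_b, dwc_rad, 0),
      abort(paste0("unknown coherence type: ", g$coherence)))
  }
  m
}

# Profiled per-curve intrinsic rates: r2_0 enters the model additively, so
# its weighted least-squares optimum is a per-curve weighted mean.
.profile_r2_0 <- function(struct, m) {
  w2 <- struct$w^2
  cid <- struct$curve_of_point
  c0 <- as.vector(rowsum(w2 * (struct$obs - m), cid) / rowsum(w2, cid))
  pmin(pmax(c0, .FIT_BOUNDS$r2_0[1]), .FIT_BOUNDS$r2_0[2])
}

.residuals_profiled <- function(struct, kex, p_b, dw_c, dw_h) {
  m <- .model_vec(struct, kex, p_b, dw_c, dw_h)
  c0 <- .profile_r2_0(struct, m)
  res <- (struct$obs - m - c0[struct$curve_of_point]) * struct$w
  attr(res, "r2_0") <- c0
  res
}

.par_pack <- function(kex, p_b, dw_c, dw_h) c(kex, p_b, dw_c, dw_h)
.par_unpack <- function(par, n_res) {
  par <- unname(par)
  list(kex = par[1], p_b = par[2],
       dw_c = par[2 + seq_len(n_res)],
       dw_h = par[2 + n_res + seq_len(n_res)])
}

# Jacobian of the profiled residuals w.r.t. the nonlinear parameters, by
# forward differences on the model only: kex and p_b need one full model
# evaluation each; all dw_c (dw_h) columns come from a single evaluation
# with every residue perturbed at once, since a residue's shift difference
# only affects its own points.  Profiling contributes the projection
# d(resid)/d(theta) = (-dm + <dm>_curve) * w.
.jac_profiled <- function(struct, par, n_res) {
  u <- .par_unpack(par, n_res)
  m0 <- .model_vec(struct, u$kex, u$p_b, u$dw_c, u$dw_h)
  w <- struct$w; w2 <- w^2
  cid <- struct$curve_of_point
  sw2 <- as.vector(rowsum(w2, cid))
  project <- function(dm) {
    mean_c <- as.vector(rowsum(w2 * dm, cid)) / sw2
    (-dm + mean_c[cid]) * w
  }
  jac <- matrix(0, length(m0), 2 + 2 * n_res)
  h_kex <- max(abs(u$kex) * 1e-6, 1e-4)
  jac[, 1] <- project((.model_vec(struct, u$kex + h_kex, u$p_b, u$dw_c, u$dw_h) - m0) / h_kex)
  h_pb <- max(abs(u$p_b) * 1e-6, 1e-9)
  jac[, 2] <- project((.model_vec(struct, u$kex, u$p_b + h_pb, u$dw_c, u$dw_h) - m0) / h_pb)
  h_dw <- 1e-6
  dmc <- (.model_vec(struct, u$kex, u$p_b, u$dw_c + h_dw, u$dw_h) - m0) / h_dw
  dmh <- (.model_vec(struct, u$kex, u$p_b, u$dw_c, u$dw_h + h_dw) - m0) / h_dw
  for (r in seq_len(n_res)) {
    sel <- struct$residue_of_point == r
    col_c <- numeric(length(m0)); col_c[sel] <- dmc[sel]
    col_h <- numeric(length(m0)); col_h[sel] <- dmh[sel]
    jac[, 2 + r] <- project(col_c)
    jac[, 2 + n_res + r] <- project(col_h)
  }
  jac
}

.fit_once <- function(struct, start, maxiter = 200) {
  n_res <- length(struct$residues)
  lower <- c(.FIT_BOUNDS$kex[1], .FIT_BOUNDS$p_b[1],
             rep(.FIT_BOUNDS$dw_c[1], n_res), rep(.FIT_BOUNDS$dw_h[1], n_res))
  upper <- c(.FIT_BOUNDS$kex[2], .FIT_BOUNDS$p_b[2],
             rep(.FIT_BOUNDS$dw_c[2], n_res), rep(.FIT_BOUNDS$dw_h[2], n_res))
  fn <- function(par) {
    u <- .par_unpack(par, n_res)
    as.numeric(.residuals_profiled(struct, u$kex, u$p_b, u$dw_c, u$dw_h))
  }
  jac <- function(par) .jac_profiled(struct, par, n_res)
  fit <- withCallingHandlers(
    minpack.lm::nls.lm(par = pmin(pmax(start, lower), upper), fn = fn, jac = jac,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-10, ptol = 1e-10)),
    warning = function(w) {
      # truncated scans from multi-start nodes are intentional
      if (grepl("maxiter", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  u <- .par_unpack(fit$par, n_res)
  res <- .residuals_profiled(struct, u$kex, u$p_b, u$dw_c, u$dw_h)
  list(par = fit$par, chi2 = sum(res^2), r2_0 = attr(res, "r2_0"),
       residuals = as.numeric(res), info = fit$info, niter = fit$niter)
}

# crude per-curve dispersion amplitude, used for identifiability flags
.max_amplitude <- function(struct) {
  d <- struct$data
  amps <- vapply(split(seq_len(nrow(d)), struct$curve_of_point), function(i) {
    nu <- d$nu_cpmg_hz[i]
    mean(d$r2eff[i][nu == min(nu)]) - mean(d$r2eff[i][nu == max(nu)])
  }, numeric(1))
  max(amps)
}

#' Fit one residue's dispersion curves to a two-state exchange model
#'
#' Simultaneous weighted least-squares fit of all curves of a single residue
#' (all coherence types and fields) with free `kex`, `p_b`, `dw_c`
#' (magnitude; the sign of `dw_h` is relative to it) and one intrinsic rate
#' `r2_0` per curve, minimising `sum(((obs - calc) / sigma)^2)`.  The
#' dispersion objective is multimodal, so the optimiser is restarted from a
#' grid of `kex` x `p_b` nodes and the best refined solution is kept.  Flat
#' data (dispersion amplitude below the noise) are flagged as unidentifiable
#' rather than reported with spurious precision.
#'
#' @param data Tidy R2eff table for exactly one residue, with >= 4 distinct
#'   `nu_CPMG` points in at least one curve.
#' @param starts Optional data frame of `kex`, `p_b` start nodes (defaults
#'   to the built-in 6 x 5 grid).
#' @param maxiter_scan,maxiter_polish Iteration caps for the scan of start
#'   nodes and the final polish.
#' @return A `"disp_fit"` object; see [fit_global()] for the fields.
#' @examples
#' d <- simulate_dispersion(scenario_spec("ADP"), seed = 1)
#' fit <- fit_single_residue(dplyr::filter(d, residue == "I34"))
#' glance(fit)
#' @export
fit_single_residue <- function(data, starts = NULL,
                               maxiter_scan = 40, maxiter_polish = 300) {
  struct <- .fit_struct(data)
  if (length(struct$residues) != 1) {
    abort("`data` must contain exactly one residue; use fit_global() for several")
  }
  npts <- tapply(struct$data$nu_cpmg_hz, struct$curve_of_point,
                 function(x) length(unique(x)))
  if (max(npts) < 4) abort("need at least one curve with >= 4 distinct nu_CPMG points")
  if (is.null(starts)) starts <- expand.grid(kex = .START_KEX, p_b = .START_PB)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- .fit_once(struct, .par_pack(starts$kex[i], starts$p_b[i], 1, 0.05),
                   maxiter = maxiter_scan)
    if (is.null(best) || f$chi2 < best$chi2) best <- f
  }
  # allow the opposite relative sign of dw_h from the best node
  u <- .par_unpack(best$par, 1)
  f2 <- .fit_once(struct, .par_pack(u$kex, u$p_b, u$dw_c, -u$dw_h - 0.01),
                  maxiter = maxiter_scan)
  if (f2$chi2 < best$chi2) best <- f2
  best <- .fit_once(struct, best$par, maxiter = maxiter_polish)
  .finish_fit(struct, best, pruning = NULL, chi2_indiv = NULL)
}

#' Global two-state fit with iterative chi-square-ratio pruning
#'
#' Fits all residues simultaneously to one exchange process: `kex` and `p_b`
#' are shared, each residue keeps its own `dw_h` and `dw_c` (in ppm, shared
#' across fields), and every curve its own intrinsic rate.  Each residue is
#' first fit individually ([fit_single_residue()]), giving `chi2_indiv`;
#' after the global fit the same residue's share of the global chi-square
#' (`chi2_group`, over the same points and sigmas) is compared with it, and
#' all residues with `chi2_group / chi2_indiv > 2` are removed together and
#' the global fit repeated, until every remaining ratio is `<= 2`.
#'
#' @param data Tidy R2eff table (>= 2 residues).
#' @param max_prune Iteration cap for the pruning loop.
#' @param prune_worst_only If `TRUE`, remove only the worst offender per
#'   iteration instead of all residues over the threshold.
#' @param prune_ratio Pruning threshold on `chi2_group / chi2_indiv`.
#' @param extra_starts Additional `(kex, p_b)` start nodes for the global
#'   stage, besides the consensus of the individual fits.
#' @return A `"disp_fit"` object: a list with elements `kex`, `p_b` (and
#'   `se_kex`, `se_p_b`), `residues` (per-residue tibble with `dw_c`,
#'   `dw_h`, errors, `chi2_indiv`, `chi2_group`, `ratio`), `curves`
#'   (per-curve `r2_0` and errors), `chi2`, `n_data`, `n_params`,
#'   `reduced_chi2`, `pruning` (the iteration log) and `data`.
#'   Methods: [tidy()], [glance()], [augment()], [autoplot()], `print()`.
#' @examples
#' d <- simulate_dispersion(scenario_spec("ADP"), seed = 1)
#' dyn <- classify_dynamic_residues(d)
#' fit <- fit_global(dplyr::filter(d, residue %in% dyn$residue))
#' glance(fit)
#' @export
fit_global <- function(data, max_prune = 10, prune_worst_only = FALSE,
                       prune_ratio = 2,
                       extra_starts = data.frame(kex = c(300, 1000, 2500),
                                                 p_b = c(0.01, 0.05, 0.1))) {
  all_struct <- .fit_struct(data)
  if (length(all_struct$residues) < 2) {
    abort("global fitting needs >= 2 residues with measurable dispersion")
  }
  data <- all_struct$data[names(all_struct$data) != "curve_id"]
  indiv <- lapply(all_struct$residues, function(r) {
    fit_single_residue(data[data$residue == r, ])
  })
  names(indiv) <- all_struct$residues
  chi2_indiv <- vapply(indiv, function(f) f$chi2, numeric(1))

  active <- all_struct$residues
  log_rows <- list()
  for (iter in seq_len(max_prune)) {
    struct <- .fit_struct(data[data$residue %in% active, , drop = FALSE])
    ord <- match(struct$residues, names(indiv))
    kex0 <- median(vapply(indiv[ord], function(f) f$kex, numeric(1)))
    pb0 <- median(vapply(indiv[ord], function(f) f$p_b, numeric(1)))
    dwc0 <- vapply(indiv[ord], function(f) f$residues$dw_c, numeric(1))
    dwh0 <- vapply(indiv[ord], function(f) f$residues$dw_h, numeric(1))
    cand <- rbind(data.frame(kex = kex0, p_b = pb0), extra_starts)
    best <- NULL
    for (i in seq_len(nrow(cand))) {
      f <- .fit_once(struct, .par_pack(cand$kex[i], cand$p_b[i], dwc0, dwh0),
                     maxiter = if (i == 1) 150 else 60)
      if (is.null(best) || f$chi2 < best$chi2) best <- f
    }
    best <- .fit_once(struct, best$par, maxiter = 400)
    chi2_group <- .chi2_by_residue(struct, best)
    ratio <- chi2_group / chi2_indiv[struct$residues]
    over <- names(ratio)[ratio > prune_ratio]
    removed <- if (length(over) == 0) character(0)
               else if (prune_worst_only) names(which.max(ratio))
               else over
    log_rows[[iter]] <- tibble(iteration = iter, residue = struct$residues,
                               chi2_indiv = unname(chi2_indiv[struct$residues]),
                               chi2_group = unname(chi2_group),
                               ratio = unname(ratio),
                               removed = struct$residues %in% removed)
    if (length(removed) == 0) {
      return(.finish_fit(struct, best, pruning = bind_rows(log_rows),
                         chi2_indiv = chi2_indiv[struct$residues]))
    }
    active <- setdiff(active, removed)
    if (length(active) < 2) {
      abort("pruning removed (almost) all residues: no mutually consistent dynamic process")
    }
  }
  abort(sprintf("pruning did not converge within %d iterations", max_prune))
}

.chi2_by_residue <- function(struct, fit) {
  out <- tapply(fit$residuals^2, struct$residues[struct$residue_of_point], sum)
  setNames(as.numeric(out[struct$residues]), struct$residues)
}

# Assemble the disp_fit object: parameter table, covariance errors, chi2
# bookkeeping and identifiability flags.
.finish_fit <- function(struct, best, pruning, chi2_indiv) {
  n_res <- length(struct$residues)
  u <- .par_unpack(best$par, n_res)
  n_data <- length(struct$obs)
  n_params <- 2 + 2 * n_res + struct$n_curves
  se <- .covariance_errors(struct, best)
  sigma_bar <- median(1 / struct$w)
  identifiable <- .max_amplitude(struct) > 2 * sigma_bar
  res_tbl <- tibble(residue = struct$residues,
                    dw_c = u$dw_c, dw_h = u$dw_h,
                    se_dw_c = se$dw_c, se_dw_h = se$dw_h)
  if (!is.null(chi2_indiv)) {
    chi2_group <- .chi2_by_residue(struct, best)
    res_tbl$chi2_indiv <- unname(chi2_indiv[struct$residues])
    res_tbl$chi2_group <- unname(chi2_group)
    res_tbl$ratio <- res_tbl$chi2_group / res_tbl$chi2_indiv
  }
  curves_tbl <- struct$curves
  curves_tbl$r2_0 <- best$r2_0
  curves_tbl$se_r2_0 <- se$r2_0
  curves_tbl$n_points <- as.integer(table(struct$curve_of_point))
  out <- list(kex = u$kex, p_b = u$p_b, se_kex = se$kex, se_p_b = se$p_b,
              residues = res_tbl, curves = curves_tbl,
              chi2 = best$chi2, n_data = n_data, n_params = n_params,
              reduced_chi2 = best$chi2 / (n_data - n_params),
              pruning = pruning, identifiable = identifiable,
              singular = se$singular,
              data = struct$data[names(struct$data) != "curve_id"],
              optim_info = list(info = best$info, niter = best$niter))
  class(out) <- "disp_fit"
  out
}

# One-sigma errors from the covariance matrix (inverse curvature) at the
# optimum.  The Jacobian of the unprofiled residuals couples the nonlinear
# parameters (central differences on the batched model) with the per-curve
# r2_0 offsets (analytic indicator columns).
.covariance_errors <- function(struct, best) {
  n_res <- length(struct$residues)
  n_cur <- struct$n_curves
  u <- .par_unpack(best$par, n_res)
  w <- struct$w
  cid <- struct$curve_of_point
  n_nl <- 2 + 2 * n_res
  central <- function(f, h) (f(h) - f(-h)) / (2 * h)
  m_at <- function(kex = u$kex, p_b = u$p_b, dw_c = u$dw_c, dw_h = u$dw_h) {
    .model_vec(struct, kex, p_b, dw_c, dw_h)
  }
  jac <- matrix(0, length(w), n_nl + n_cur)
  h_kex <- max(abs(u$kex) * 1e-5, 1e-4)
  jac[, 1] <- -central(function(h) m_at(kex = u$kex + h), h_kex) * w
  h_pb <- max(abs(u$p_b) * 1e-5, 1e-9)
  jac[, 2] <- -central(function(h) m_at(p_b = u$p_b + h), h_pb) * w
  h_dw <- 1e-6
  dmc <- -central(function(h) m_at(dw_c = u$dw_c + h), h_dw) * w
  dmh <- -central(function(h) m_at(dw_h = u$dw_h + h), h_dw) * w
  for (r in seq_len(n_res)) {
    sel <- struct$residue_of_point == r
    jac[sel, 2 + r] <- dmc[sel]
    jac[sel, 2 + n_res + r] <- dmh[sel]
  }
  for (ci in seq_len(n_cur)) jac[cid == ci, n_nl + ci] <- -w[cid == ci]
  jtj <- crossprod(jac)
  # parameters differ by orders of magnitude in units; rescale to unit
  # diagonal before the (pseudo-)inverse to keep the conditioning honest
  dscale <- sqrt(pmax(diag(jtj), 0))
  zero_curv <- dscale <= 0
  dscale[zero_curv] <- 1
  a <- jtj / outer(dscale, dscale)
  sv <- svd(a)
  tol <- max(sv$d) * 1e-12
  ok <- sv$d > tol
  inv_d <- ifelse(ok, 1 / sv$d, 0)
  cov <- (sv$v %*% (inv_d * t(sv$u))) / outer(dscale, dscale)
  ses <- sqrt(pmax(diag(cov), 0))
  singular <- any(!ok) || any(zero_curv)
  if (singular) {
    null_vec <- sv$v[, !ok, drop = FALSE]
    flat <- zero_curv | rowSums(abs(null_vec) > 0.5) > 0
    ses[flat] <- Inf
  }
  list(kex = ses[1], p_b = ses[2],
       dw_c = ses[2 + seq_len(n_res)], dw_h = ses[2 + n_res + seq_len(n_res)],
       r2_0 = ses[n_nl + seq_len(n_cur)], singular = singular)
}

#' Parameter uncertainties of a dispersion fit
#'
#' Returns the one-sigma uncertainties derived from the covariance matrix
#' (inverse curvature) at the fit optimum, optionally cross-checked by a
#' parametric bootstrap: `bootstrap` synthetic datasets are generated from
#' the fitted model and the recorded per-point sigmas, refit, and the
#' empirical standard deviations reported alongside.
#'
#' @param fit A `"disp_fit"` object.
#' @param bootstrap Number of bootstrap replicates (0 to skip).
#' @param seed Seed for the bootstrap resimulation.
#' @return A tibble with `term`, `residue` (NA for global terms),
#'   `estimate`, `std.error` and, when bootstrapped, `boot.se`.
#' @export
estimate_errors <- function(fit, bootstrap = 0, seed = 20220324) {
  stopifnot(inherits(fit, "disp_fit"))
  out <- tidy(fit)
  if (bootstrap > 0) {
    sims <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
      lapply(seq_len(bootstrap), function(b) {
        d <- augment(fit)
        d$r2eff <- d$.fitted + rnorm(nrow(d), 0, d$sigma)
        cols <- c("residue", "experiment", "field_mhz", "t_relax_s",
                  "nu_cpmg_hz", "r2eff", "sigma")
        refit <- if (length(unique(d$residue)) == 1) {
          fit_single_residue(d[cols])
        } else {
          fit_global(d[cols], max_prune = 1, prune_ratio = Inf)
        }
        tidy(refit)[c("term", "residue", "estimate")]
      })
    })
    boots <- bind_rows(sims) %>%
      group_by(term, residue) %>%
      summarise(boot.se = sd(estimate), .groups = "drop")
    out <- left_join(out, boots, by = c("term", "residue"))
  }
  out
}

#' Identify residues with measurable dispersion
#'
#' A residue is classified dynamic when its dispersion amplitude
#' [delta_r2()] exceeds `threshold` (default 2 1/s) in any experiment;
#' the per-residue provenance records which experiments triggered the call.
#'
#' @param data Tidy R2eff table.
#' @param threshold Amplitude threshold in 1/s.
#' @return A tibble with one row per dynamic residue: `residue`,
#'   `max_delta_r2` and `triggered_by` (experiments over the threshold).
#'   The full per-curve amplitude table is attached as attribute
#'   `"delta_r2"`.
#' @examples
#' d <- simulate_dispersion(scenario_spec("ATP"), seed = 1)
#' classify_dynamic_residues(d)
#' @export
classify_dynamic_residues <- function(data, threshold = 2) {
  dr <- delta_r2(data)
  out <- dr %>%
    group_by(residue) %>%
    summarise(max_delta_r2 = max(delta_r2),
              triggered_by = paste(sort(unique(
                sprintf("%s@%g", experiment[delta_r2 > threshold],
                        field_mhz[delta_r2 > threshold]))), collapse = ","),
              .groups = "drop") %>%
    filter(max_delta_r2 > threshold) %>%
    arrange(residue)
  attr(out, "delta_r2") <- dr
  out
}
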