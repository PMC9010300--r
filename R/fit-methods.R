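# print / tidy / glance / augment / autoplot methods for fitted objects.

#' @export
print.disp_fit <- function(x, ...) {
  cat(sprintf("<disp_fit> %d residue(s), %d curves, %d points\n",
              nrow(x$residues), nrow(x$curves), x$n_data))
  cat(sprintf("  kex = %.1f +/- %.1f /s   p_b = %.4f +/- %.4f   reduced chi2 = %.3f\n",
              x$kex, x$se_kex, x$p_b, x$se_p_b, x$reduced_chi2))
  if (!is.null(x$pruning)) {
    removed <- unique(x$pruning$residue[x$pruning$removed])
    cat(sprintf("  pruning: %d iteration(s), removed: %s\n",
                max(x$pruning$iteration),
                if (length(removed)) paste(removed, collapse = ", ") else "none"))
  }
  if (!x$identifiable) cat("  WARNING: dispersion amplitude below noise; exchange parameters unidentifiable\n")
  invisible(x)
}

#' Tidy a dispersion fit into a parameter table
#'
#' @param x A `"disp_fit"` object.
#' @param ... Unused.
#' @return One row per parameter: `term` (`kex`, `p_b`, `dw_c`, `dw_h`,
#'   `r2_0`), `residue` (NA for shared terms), `curve` labels for `r2_0`
#'   terms, `estimate`, `std.error`.
#' @export
tidy.disp_fit <- function(x, ...) {
  bind_rows(
    tibble(term = c("kex", "p_b"), residue = NA_character_, curve = NA_character_,
           estimate = c(x$kex, x$p_b), std.error = c(x$se_kex, x$se_p_b)),
    tibble(term = "dw_c", residue = x$residues$residue, curve = NA_character_,
           estimate = x$residues$dw_c, std.error = x$residues$se_dw_c),
    tibble(term = "dw_h", residue = x$residues$residue, curve = NA_character_,
           estimate = x$residues$dw_h, std.error = x$residues$se_dw_h),
    tibble(term = "r2_0", residue = x$curves$residue,
           curve = sprintf("%s@%g", x$curves$experiment, x$curves$field_mhz),
           estimate = x$curves$r2_0, std.error = x$curves$se_r2_0))
}

#' One-line summary of a dispersion fit
#'
#' @param x A `"disp_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `kex`, `se_kex`, `p_b`, `se_p_b`, `chi2`,
#'   `reduced_chi2`, `n_data`, `n_params`, `n_residues`, `identifiable`.
#' @export
glance.disp_fit <- function(x, ...) {
  tibble(kex = x$kex, se_kex = x$se_kex, p_b = x$p_b, se_p_b = x$se_p_b,
         chi2 = x$chi2, reduced_chi2 = x$reduced_chi2,
         n_data = x$n_data, n_params = x$n_params,
         n_residues = nrow(x$residues), identifiable = x$identifiable)
}

#' Fitted values and residuals for every data point
#'
#' @param x A `"disp_fit"` object.
#' @param ... Unused.
#' @return The fitted data with `.fitted` and `.resid` (weighted) columns.
#' @export
augment.disp_fit <- function(x, ...) {
  d <- x$data
  key <- sprintf("%s|%s|%g|%g", d$residue, d$experiment, d$field_mhz, d$t_relax_s)
  ckey <- sprintf("%s|%s|%g|%g", x$curves$residue, x$curves$experiment,
                  x$curves$field_mhz, x$curves$t_relax_s)
  ci <- match(key, ckey)
  ri <- match(d$residue, x$residues$residue)
  fitted <- vapply(seq_len(nrow(d)), function(i) {
    n <- .snap_ncpmg(d$nu_cpmg_hz[i], d$t_relax_s[i], even = d$experiment[i] == "MQ")
    .r2eff_model(d$experiment[i], d$field_mhz[i], d$t_relax_s[i], n,
                 x$kex, x$p_b, x$residues$dw_h[ri[i]], x$residues$dw_c[ri[i]],
                 x$curves$r2_0[ci[i]])
  }, numeric(1))
  d$.fitted <- fitted
  d$.resid <- (d$r2eff - fitted) / d$sigma
  d
}

#' Plot dispersion profiles with fitted curves
#'
#' Draws the measured `R2eff` values (points with one-sigma error bars)
#' against CPMG frequency, faceted by residue, coloured by field, with the
#' fitted dispersion curves evaluated on a fine frequency grid.
#'
#' @param object A `"disp_fit"` object.
#' @param residues Optional subset of residues to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disp_fit <- function(object, residues = NULL, ...) {
  d <- object$data
  if (!is.null(residues)) d <- d[d$residue %in% residues, ]
  curves <- object$curves
  if (!is.null(residues)) curves <- curves[curves$residue %in% residues, ]
  lines <- purrr::pmap_dfr(curves, function(residue, experiment, field_mhz,
                                            t_relax_s, r2_0, ...) {
    nu_max <- max(d$nu_cpmg_hz[d$experiment == experiment & d$field_mhz == field_mhz])
    n <- suppressWarnings(unique(.snap_ncpmg(
      seq(min(d$nu_cpmg_hz), nu_max, length.out = 80),
      t_relax_s, even = experiment == "MQ")))
    ri <- match(residue, object$residues$residue)
    model <- .r2eff_model(experiment, field_mhz, t_relax_s, n,
                          object$kex, object$p_b,
                          object$residues$dw_h[ri], object$residues$dw_c[ri], r2_0)
    tibble(residue = residue, experiment = experiment, field_mhz = field_mhz,
           nu_cpmg_hz = n / t_relax_s, r2eff = model)
  })
  ggplot2::ggplot(d, ggplot2::aes(nu_cpmg_hz, r2eff, colour = factor(field_mhz))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = r2eff - sigma, ymax = r2eff + sigma),
                           width = 0, linewidth = 0.3) +
    ggplot2::geom_line(data = lines) +
    ggplot2::facet_wrap(~ residue + experiment, scales = "free_y") +
    ggplot2::labs(x = expression(nu[CPMG] ~ "(Hz)"),
                  y = expression(R[2 * eff] ~ (s^-1)), colour = "field (MHz)") +
    ggplot2::theme_bw()
}

#' Plot a simulated or measured dispersion table
#'
#' @param object A tidy R2eff table (e.g. from [simulate_dispersion()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disp_data <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(nu_cpmg_hz, r2eff, colour = factor(field_mhz))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ residue + experiment, scales = "free_y") +
    ggplot2::labs(x = expression(nu[CPMG] ~ "(Hz)"),
                  y = expression(R[2 * eff] ~ (s^-1)), colour = "field (MHz)") +
    ggplot2::theme_bw()
}

#' Pruning log of a global fit
#'
#' @param fit A `"disp_fit"` from [fit_global()].
#' @return Tibble with one row per residue per pruning iteration:
#'   `iteration`, `residue`, `chi2_indiv`, `chi2_group`, `ratio`, `removed`.
#' @export
pruning_log <- function(fit) {
  stopifnot(inherits(fit, "disp_fit"))
  if (is.null(fit$pruning)) abort("this fit has no pruning log (single-residue fit?)")
  fit$pruning
}
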