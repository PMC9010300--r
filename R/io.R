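# Plain-TSV file formats.  The analysis layer starts at peak intensities
# (upstream spectral processing is out of scope), so no spectrometer or
# processed-spectrum formats are read: dispersion tables, peak lists and
# reports are tab-separated text with a provenance comment header.

.tiny_hash <- function(x) {
  v <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (i in v) h <- (h * 33 + i) %% 2^28
  sprintf("%07x", h)
}

.provenance_header <- function(seed = NULL, config = NULL) {
  c(sprintf("# cpmgdisp %s", as.character(utils::packageVersion("cpmgdisp"))),
    if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed)),
    if (!is.null(config)) sprintf("# config_hash=%s", .tiny_hash(unlist(config))))
}

# Atomic write: assemble the full text, write to a sibling temp file, rename.
.write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) abort(paste0("could not write ", path))
  invisible(path)
}

.format_tsv <- function(df, digits_map = NULL) {
  df <- as_tibble(df)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.null(digits_map)) {
      dg <- digits_map[[nm]]
      if (!is.null(dg)) df[[nm]] <- formatC(df[[nm]], format = "f", digits = dg)
    }
  }
  header <- paste(names(df), collapse = "\t")
  rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  c(header, rows)
}

.DISP_DIGITS <- list(field_mhz = 1, t_relax_s = 4, nu_cpmg_hz = 3,
                     r2eff = 3, sigma = 3, intensity = 3, sigma_i = 3,
                     sigma_r2eff = 3)
.PEAK_DIGITS <- list(delta_h_ppm = 4, delta_c_ppm = 4, sigma_h = 4,
                     sigma_c = 4, intensity = 3)

#' Write / read a dispersion table
#'
#' Tab-separated text with a `#` provenance header (package version, seed,
#' configuration hash).  A table holds either intensity-level rows (column
#' `intensity`, reference points at `nu_cpmg_hz == 0`) or rate-level rows
#' (column `r2eff`), never both.  Unknown columns are preserved.  Writes are
#' atomic (a temporary sibling file is renamed into place).
#'
#' @param data Dispersion table (intensity- or R2eff-level).
#' @param path File path.
#' @param seed,config Optional provenance entries for the header.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_dispersion_table <- function(data, path, seed = NULL, config = NULL) {
  .check_disp_columns(data)
  .write_atomic(c(.provenance_header(seed, config),
                  .format_tsv(data, .DISP_DIGITS)), path)
}

#' @rdname write_dispersion_table
#' @export
read_dispersion_table <- function(path) {
  out <- .read_tsv_checked(path, required = c("residue", "experiment", "field_mhz",
                                              "t_relax_s", "nu_cpmg_hz"),
                           numeric_cols = c("field_mhz", "t_relax_s", "nu_cpmg_hz",
                                            "r2eff", "sigma", "intensity",
                                            "sigma_i", "sigma_r2eff", "replicate"))
  .check_disp_columns(out)
  out
}

.check_disp_columns <- function(data) {
  has_i <- "intensity" %in% names(data)
  has_r <- "r2eff" %in% names(data)
  if (has_i && has_r) abort("a dispersion table holds either `intensity` or `r2eff` rows, not both")
  if (!has_i && !has_r) abort("missing required column(s): intensity or r2eff")
  invisible(data)
}

#' Write / read a peak list
#'
#' Tab-separated peak list with columns `residue`, `delta_h_ppm`,
#' `delta_c_ppm` and optionally `intensity`, `sigma_h`, `sigma_c`.
#'
#' @param data Peak-list tibble.
#' @param path File path.
#' @param seed,config Optional provenance entries.
#' @param validate_labels Require residue labels of the form `[A-Z]<number>`.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_peak_list <- function(data, path, seed = NULL, config = NULL) {
  .validate_r2eff_table(data, need = c("residue", "delta_h_ppm", "delta_c_ppm"))
  .write_atomic(c(.provenance_header(seed, config),
                  .format_tsv(data, .PEAK_DIGITS)), path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path, validate_labels = TRUE) {
  out <- .read_tsv_checked(path, required = c("residue", "delta_h_ppm", "delta_c_ppm"),
                           numeric_cols = c("delta_h_ppm", "delta_c_ppm",
                                            "intensity", "sigma_h", "sigma_c"))
  if (validate_labels && !all(grepl("^[A-Z][0-9]+$", out$residue))) {
    bad <- out$residue[!grepl("^[A-Z][0-9]+$", out$residue)]
    abort(paste0("residue labels not of the form [A-Z]<number>: ",
                 paste(unique(bad), collapse = ", ")))
  }
  if (any(!is.finite(out$delta_h_ppm)) || any(!is.finite(out$delta_c_ppm))) {
    abort("non-finite ppm value in peak list")
  }
  out
}

#' Read an assignment-list peak file (`label w1 w2` dialect)
#'
#' Whitespace-separated columns `label`, `w1`, `w2` as written by common
#' assignment tools; by convention `w1` is the 13C (indirect) and `w2` the
#' 1H (direct) dimension, switchable via `w1`.
#'
#' @param path File path.
#' @param w1 Which nucleus the `w1` column holds: `"C"` (default) or `"H"`.
#' @return A peak-list tibble (`residue`, `delta_h_ppm`, `delta_c_ppm`).
#' @export
read_assignment_list <- function(path, w1 = c("C", "H")) {
  w1 <- match.arg(w1)
  raw <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("label", "w1", "w2")
  missing_cols <- setdiff(need, tolower(names(raw)))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  names(raw) <- tolower(names(raw))
  tibble(residue = sub("[A-Za-z0-9]*?([A-Z][0-9]+).*", "\\1", raw$label),
         delta_h_ppm = if (w1 == "C") as.numeric(raw$w2) else as.numeric(raw$w1),
         delta_c_ppm = if (w1 == "C") as.numeric(raw$w1) else as.numeric(raw$w2))
}

# Strict TSV reader: all cells read as text, numeric conversion checked
# cell by cell so errors can name the offending line.
.read_tsv_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  body <- lines[!is_comment]
  if (length(body) < 2) abort(paste0(path, ": no data rows"))
  line_no <- which(!is_comment)
  cells <- strsplit(body, "\t", fixed = TRUE)
  header <- cells[[1]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  n <- length(header)
  rows <- cells[-1]
  bad_len <- which(vapply(rows, length, integer(1)) != n)
  if (length(bad_len)) {
    abort(sprintf("%s: line %d has %d fields, expected %d", path,
                  line_no[bad_len[1] + 1], length(rows[[bad_len[1]]]), n))
  }
  df <- as_tibble(setNames(lapply(seq_len(n), function(j)
    vapply(rows, `[[`, character(1), j)), header))
  for (nm in intersect(numeric_cols, header)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !df[[nm]] %in% c("NA", ""))
    if (length(bad)) {
      abort(sprintf("%s: non-numeric value '%s' in column '%s' at line %d",
                    path, df[[nm]][bad[1]], nm, line_no[bad[1] + 1]))
    }
    df[[nm]] <- v
  }
  df
}

#' Write a fit report
#'
#' A flat key-value text block (global parameters, errors, chi-square
#' bookkeeping, pruning summary) plus, when `params_path` is given, the
#' machine-readable tidy parameter table as TSV.
#'
#' @param fit A `"disp_fit"` object.
#' @param path Report file path.
#' @param params_path Optional TSV path for the [tidy()] parameter table.
#' @param seed,config Optional provenance entries.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, params_path = NULL, seed = NULL, config = NULL) {
  stopifnot(inherits(fit, "disp_fit"))
  g <- glance(fit)
  kv <- c(sprintf("kex_s-1 = %.3f", g$kex), sprintf("kex_err = %.3f", g$se_kex),
          sprintf("p_b = %.6f", g$p_b), sprintf("p_b_err = %.6f", g$se_p_b),
          sprintf("chi2 = %.3f", g$chi2),
          sprintf("reduced_chi2 = %.4f", g$reduced_chi2),
          sprintf("n_data = %d", g$n_data), sprintf("n_params = %d", g$n_params),
          sprintf("n_residues = %d", g$n_residues),
          sprintf("identifiable = %s", g$identifiable))
  if (!is.null(fit$pruning)) {
    removed <- unique(fit$pruning$residue[fit$pruning$removed])
    kv <- c(kv, sprintf("pruning_iterations = %d", max(fit$pruning$iteration)),
            sprintf("pruned_residues = %s",
                    if (length(removed)) paste(removed, collapse = ",") else "none"))
  }
  .write_atomic(c(.provenance_header(seed, config), kv), path)
  if (!is.null(params_path)) {
    .write_atomic(c(.provenance_header(seed, config),
                    .format_tsv(tidy(fit), list(estimate = 6, std.error = 6))),
                  params_path)
  }
  invisible(path)
}
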