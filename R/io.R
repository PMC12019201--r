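# Plain-text export of spectra, center lines and solved fields.
#
# All outputs are CSV/JSON so runs can be diffed and archived; each file
# embeds the resolved run-configuration hash when written through
# run_experiment().

#' Write a spectrum to CSV
#'
#' One row per (detector, frequency) with columns `detector`,
#' `frequency_MHz`, `real`, `imag`, `magnitude`.
#'
#' @param spectrum A `pa_spectrum`.
#' @param path Output CSV path.
#' @param comment Optional comment line(s) written as a `#` header.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path, comment = NULL) {
  stopifnot(inherits(spectrum, "pa_spectrum"))
  nd <- nrow(spectrum$values)
  df <- data.frame(
    detector = rep(seq_len(nd), times = ncol(spectrum$values)),
    frequency_MHz = rep(spectrum$freqs$values, each = nd),
    real = as.vector(Re(spectrum$values)),
    imag = as.vector(Im(spectrum$values)))
  df$magnitude <- sqrt(df$real^2 + df$imag^2)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a solved field to plain-text files
#'
#' The complex lattice goes to `<path>.csv` (columns `row`, `col`,
#' `real`, `imag`; one line per pixel) and the solve metadata
#' (frequency, media, grid, epsilon, iterations, error trace,
#' convergence flag) to `<path>.json`.  For production lattices the CSV
#' is large; `rows` can restrict the export, e.g. to the centre row.
#'
#' @param solution A `field_solution`.
#' @param path Base path without extension.
#' @param rows Optional integer vector of rows to export (default: all).
#' @param comment Optional `#` comment line for the CSV.
#' @return Base `path`, invisibly.
#' @export
write_field <- function(solution, path, rows = NULL, comment = NULL) {
  stopifnot(inherits(solution, "field_solution"))
  n <- solution$grid$n
  rows <- if (is.null(rows)) seq_len(n) else as.integer(rows)
  sub <- solution$psi[rows, , drop = FALSE]
  df <- data.frame(row = rep(rows, times = n),
                   col = rep(seq_len(n), each = length(rows)),
                   real = as.vector(Re(sub)),
                   imag = as.vector(Im(sub)))
  con <- file(paste0(path, ".csv"), "w")
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  meta <- list(f_MHz = solution$f, method = solution$method,
               n = solution$grid$n, h_um = solution$grid$h,
               vf = solution$medium$vf, vs = solution$medium$vs,
               rho_f = solution$medium$rho_f, rho_s = solution$medium$rho_s,
               epsilon = solution$epsilon,
               iterations = solution$iterations,
               converged = solution$converged,
               error_trace = solution$error_trace)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
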