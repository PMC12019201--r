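# Experiment harnesses: detector read-out, frequency sweeps,
# CBS-vs-analytic comparison and ensemble statistics over phantoms.

#' Detector geometry
#'
#' Three read-out styles: the full `center_line` row of the lattice, a
#' `ring` of equally spaced point detectors (e.g. 200 detectors at
#' 51 um used for average spectra), or a `single_point`.
#'
#' @param kind `"center_line"`, `"ring"` or `"single_point"`.
#' @param row Center-line row index (1-based; default n/2 at read-out
#'   time when `NULL`).
#' @param center,radius,count Ring geometry: centre (um), radius (um)
#'   and number of detectors equally spaced in angle.
#' @param position Single-point position (um).
#' @return A `detector_set` object.
#' @export
#' @examples
#' detector_set("ring", center = c(0, 0), radius = 51, count = 200)
#' detector_set("single_point", position = c(51, 0))
detector_set <- function(kind = c("center_line", "ring", "single_point"),
                         row = NULL, center = c(0, 0), radius = NULL,
                         count = NULL, position = NULL) {
  kind <- match.arg(kind)
  if (kind == "ring") {
    stopifnot(is.numeric(radius), radius > 0, is.numeric(count), count >= 1)
    th <- 2 * pi * (seq_len(count) - 1) / count
    pts <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  } else if (kind == "single_point") {
    stopifnot(is.numeric(position), length(position) == 2)
    pts <- matrix(position, ncol = 2)
  } else {
    pts <- NULL
  }
  structure(list(kind = kind, row = row, center = center, radius = radius,
                 count = count, points = pts),
            class = "detector_set")
}

#' @export
print.detector_set <- function(x, ...) {
  cat(sprintf("<detector_set> %s%s\n", x$kind,
              if (x$kind == "ring")
                sprintf(" (%d detectors at r=%g um)", x$count, x$radius)
              else ""))
  invisible(x)
}

# Detector positions in um; center_line resolves to pixel centres of
# the centre row.
detector_positions <- function(detectors, grid) {
  if (detectors$kind == "center_line") {
    row <- if (is.null(detectors$row)) center_row_index(grid) else detectors$row
    ax <- grid_axis(grid)
    cbind(ax, ax[row])
  } else {
    detectors$points
  }
}

#' Read a solved field at detector positions
#'
#' The `center_line` kind returns the full centre row of the lattice;
#' point and ring detectors are read by bilinear interpolation of the
#' complex field between the four surrounding pixel centres.  Detectors
#' inside the absorbing layer trigger a warning (fields there are
#' deliberately damped).
#'
#' @param solution A `field_solution` from [solve_cbs()]/[solve_tbs()].
#' @param detectors A [detector_set()].
#' @param grid The [sim_grid()] of the solution (defaults to the one
#'   stored in it).
#' @return Complex vector, one value per detector.
#' @export
sample_field <- function(solution, detectors, grid = solution$grid) {
  psi <- solution$psi
  if (detectors$kind == "center_line") {
    row <- if (is.null(detectors$row)) center_row_index(grid) else detectors$row
    return(psi[row, ])
  }
  pts <- detectors$points
  half_int <- grid$extent / 2 - solution$config$abl_d * grid$h
  if (any(abs(pts) > half_int))
    warning("detector inside the absorbing boundary layer: values are damped")
  # Bilinear interpolation on pixel centres; fractional index along an
  # axis for coordinate u (um) is (u + extent/2)/h + 0.5.
  fi <- (pts[, 2] + grid$extent / 2) / grid$h + 0.5  # row (y)
  fj <- (pts[, 1] + grid$extent / 2) / grid$h + 0.5  # column (x)
  if (any(fi < 1 | fi > grid$n | fj < 1 | fj > grid$n))
    stop("detector outside the simulation grid")
  i0 <- pmin(pmax(floor(fi), 1), grid$n - 1); ti <- fi - i0
  j0 <- pmin(pmax(floor(fj), 1), grid$n - 1); tj <- fj - j0
  idx <- function(i, j) psi[cbind(i, j)]
  (1 - ti) * (1 - tj) * idx(i0, j0) + (1 - ti) * tj * idx(i0, j0 + 1) +
    ti * (1 - tj) * idx(i0 + 1, j0) + ti * tj * idx(i0 + 1, j0 + 1)
}

#' Frequency sweep of a scene at a detector set
#'
#' Runs independent per-frequency evaluations of a scene by the chosen
#' method: `"cbs"` solves the Helmholtz equation on the lattice at each
#' frequency, `"exact"`/`"dpa"` evaluate the closed-form solutions
#' (which require exterior detectors).  Per-frequency CBS
#' non-convergence is recorded in the result, not fatal.
#'
#' @param scene A list with elements `disks`, `medium`, `optical`, and
#'   for CBS sweeps `grid` and `config`.
#' @param freqs A [frequency_grid()].
#' @param method `"cbs"`, `"dpa"` or `"exact"`.
#' @param detectors A [detector_set()].
#' @return A `pa_spectrum` with one row per detector; CBS sweeps also
#'   carry a `convergence` data frame (f, iterations, converged).
#' @export
frequency_sweep <- function(scene, freqs, method = c("exact", "dpa", "cbs"),
                            detectors) {
  method <- match.arg(method)
  stopifnot(inherits(freqs, "frequency_grid"))
  disks <- as_disk_list(scene$disks)
  medium <- scene$medium %||% acoustic_medium()
  optical <- scene$optical %||% optical_params()

  if (method %in% c("exact", "dpa")) {
    grid <- scene$grid  # optional, only to resolve center_line positions
    if (is.null(grid) && detectors$kind == "center_line")
      stop("center_line detectors need scene$grid to resolve positions")
    pts <- detector_positions(detectors, grid)
    vals <- vapply(freqs$values, function(f) {
      if (method == "exact" && length(disks) == 1L)
        disk_field(pts, f, disks[[1]], medium, optical)
      else
        dpa_field(pts, disks, f, medium, optical)
    }, complex(nrow(pts)))
    vals <- matrix(vals, nrow = nrow(pts))
    return(new_spectrum(vals, freqs, method, detectors))
  }

  grid <- scene$grid
  config <- scene$config %||% cbs_config()
  stopifnot(inherits(grid, "sim_grid"))
  n_det <- if (detectors$kind == "center_line") grid$n
           else nrow(detectors$points)
  vals <- matrix(NA_complex_, n_det, freqs$n_points)
  conv <- data.frame(f = freqs$values, iterations = NA_integer_,
                     converged = NA)
  for (k in seq_along(freqs$values)) {
    sol <- withCallingHandlers(
      solve_cbs(disks, medium, optical, freqs$values[k], grid, config),
      warning = function(w) invokeRestart("muffleWarning"))
    vals[, k] <- sample_field(sol, detectors, grid)
    conv$iterations[k] <- sol$iterations
    conv$converged[k] <- sol$converged
  }
  new_spectrum(vals, freqs, "cbs", detectors, convergence = conv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detector-averaged amplitude spectrum
#'
#' Mean over detectors of the pressure magnitude at each frequency.
#' Magnitudes (not complex values) are averaged: for random scenes the
#' phase varies with detector angle and complex averaging would cancel.
#'
#' @param spectrum A `pa_spectrum`.
#' @return Numeric vector, one mean amplitude per frequency.
#' @export
average_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "pa_spectrum"), nrow(spectrum$values) >= 1)
  colMeans(Mod(spectrum$values))
}

# Center-line positions (um) outside the ABL, with masks for points
# interior/exterior to the disks; shared by the comparison helpers.
center_line_frame <- function(grid, config, disks) {
  ax <- grid_axis(grid)
  row <- center_row_index(grid)
  keep <- seq_len(grid$n) > config$abl_d & seq_len(grid$n) <= grid$n - config$abl_d
  pts <- cbind(ax, ax[row])
  inside <- rep(FALSE, grid$n)
  for (d in as_disk_list(disks)) {
    inside <- inside |
      ((pts[, 1] - d$center[1])^2 + (pts[, 2] - d$center[2])^2 <= d$radius^2)
  }
  list(pts = pts, keep = keep, inside = inside, row = row)
}

rel_l2 <- function(x, y) sqrt(sum(Mod(x - y)^2) / sum(Mod(y)^2))

#' Compare a CBS solution with its analytic counterpart on the center line
#'
#' Evaluates the exact single-disk solution (or the DPA superposition
#' for several disks) at the centre-row pixel centres outside the ABL
#' and reports relative L2 and maximum errors, separately for points
#' inside and outside the sources.  For multi-disk scenes only the
#' exterior comparison is available (the DPA has no interior solution).
#'
#' @param solution A `field_solution`.
#' @param scene List with `disks`, `medium`, `optical`.
#' @param grid The [sim_grid()] (defaults to the solution's).
#' @return A list: `outside` and (single disk only) `inside`, each with
#'   `rel_l2` and `max_abs` entries, plus the number of points used.
#' @export
compare_cbs_analytic <- function(solution, scene, grid = solution$grid) {
  disks <- as_disk_list(scene$disks)
  medium <- scene$medium %||% acoustic_medium()
  optical <- scene$optical %||% optical_params()
  cf <- center_line_frame(grid, solution$config, disks)
  num <- solution$psi[cf$row, ]

  out <- list()
  sel_out <- cf$keep & !cf$inside
  ana_out <- dpa_field(cf$pts[sel_out, , drop = FALSE], disks, solution$f,
                       medium, optical)
  out$outside <- list(
    rel_l2 = rel_l2(num[sel_out], ana_out),
    max_abs = max(Mod(num[sel_out] - ana_out)),
    n_points = sum(sel_out))
  if (length(disks) == 1L) {
    sel_in <- cf$keep & cf$inside
    if (any(sel_in)) {
      ana_in <- disk_field(cf$pts[sel_in, , drop = FALSE], solution$f,
                           disks[[1]], medium, optical)
      out$inside <- list(
        rel_l2 = rel_l2(num[sel_in], ana_in),
        max_abs = max(Mod(num[sel_in] - ana_in)),
        n_points = sum(sel_in))
    }
  }
  out
}

#' Ensemble statistics of the center-line pressure over tissue realizations
#'
#' For each realization (seed = `base_seed` + index) a phantom is packed
#' and, for every intracellular sound speed in `vs_list`, the CBS field
#' at frequency `f` is solved and \eqn{|\psi|} is averaged over the
#' centre-row points outside the ABL and exterior to every disk (so the
#' DPA counterpart, computed at the same points on the same phantom, is
#' directly comparable).  Means and standard deviations are then taken
#' across realizations.
#'
#' @param roi An [roi_spec()].
#' @param packing A [packing_config()] (its `seed` is overridden per
#'   realization).
#' @param f Frequency in MHz.
#' @param vs_list Intracellular sound speeds to scan (m/s).
#' @param n_realizations Number of phantoms (>= 2).
#' @param base_seed First seed; realization i uses `base_seed + i - 1`.
#' @param seeds Optional explicit seed vector (length `n_realizations`)
#'   overriding the `base_seed` rule.
#' @param grid A [sim_grid()].
#' @param medium Template [acoustic_medium()] supplying `vf` and the
#'   densities.
#' @param optical An [optical_params()].
#' @param config A [cbs_config()].
#' @return An `ensemble_stats` object: per-`vs` CBS and DPA means and
#'   standard deviations, per-realization values, iteration counts, and
#'   the effective number of realizations (failures are excluded with a
#'   logged reason).
#' @export
ensemble_center_line_stats <- function(roi, packing, f, vs_list,
                                       n_realizations, base_seed,
                                       grid, medium = acoustic_medium(),
                                       optical = optical_params(),
                                       config = cbs_config(),
                                       seeds = base_seed + seq_len(n_realizations) - 1) {
  stopifnot(n_realizations >= 2, length(seeds) == n_realizations)
  nv <- length(vs_list)
  cbs_vals <- matrix(NA_real_, n_realizations, nv)
  dpa_vals <- matrix(NA_real_, n_realizations, nv)
  iters <- matrix(NA_integer_, n_realizations, nv)
  failures <- character(0)

  for (i in seq_len(n_realizations)) {
    pk <- packing
    pk$seed <- as.integer(seeds[i])
    tr <- tryCatch(pack_disks(roi, pk), error = function(e) e)
    if (inherits(tr, "error")) {
      failures <- c(failures, sprintf("realization %d: %s", i, conditionMessage(tr)))
      next
    }
    cf <- center_line_frame(grid, config, tr$disks)
    sel <- cf$keep & !cf$inside
    for (j in seq_len(nv)) {
      med <- acoustic_medium(vf = medium$vf, vs = vs_list[j],
                             rho_f = medium$rho_f, rho_s = medium$rho_s)
      sol <- withCallingHandlers(
        solve_cbs(tr$disks, med, optical, f, grid, config),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!sol$converged) {
        failures <- c(failures,
                      sprintf("realization %d vs=%g: CBS not converged", i, vs_list[j]))
        next
      }
      cbs_vals[i, j] <- mean(Mod(sol$psi[cf$row, sel]))
      dpa <- dpa_field(cf$pts[sel, , drop = FALSE], tr$disks, f, med, optical)
      dpa_vals[i, j] <- mean(Mod(dpa))
      iters[i, j] <- sol$iterations
    }
  }

  ok <- stats::complete.cases(cbs_vals)
  structure(list(
    vs = vs_list, f = f,
    cbs_mean = colMeans(cbs_vals[ok, , drop = FALSE]),
    cbs_sd = apply(cbs_vals[ok, , drop = FALSE], 2, sd),
    dpa_mean = colMeans(dpa_vals[ok, , drop = FALSE]),
    dpa_sd = apply(dpa_vals[ok, , drop = FALSE], 2, sd),
    cbs_values = cbs_vals, dpa_values = dpa_vals, iterations = iters,
    n_effective = sum(ok), n_requested = n_realizations,
    failures = failures),
    class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("<ensemble_stats> f=%g MHz, %d/%d realizations\n",
              x$f, x$n_effective, x$n_requested))
  df <- data.frame(vs = x$vs, cbs_mean = x$cbs_mean, cbs_sd = x$cbs_sd,
                   dpa_mean = x$dpa_mean, dpa_sd = x$dpa_sd)
  print(df, row.names = FALSE)
  invisible(x)
}
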