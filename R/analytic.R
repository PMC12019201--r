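# Exact 2D solutions for the photoacoustic field of a fluid disk.
#
# A uniformly illuminated circular absorber radiates a cylindrical wave.
# Matching pressure and normal particle velocity at the rim r = a gives
# interior/exterior solutions built from Bessel J and outgoing Hankel
# H^(1) functions (e^{-i omega t} convention; the time factor is never
# materialised).  Both branches share the denominator
#   D = J1(ks a) H0(kf a) - rho_hat c_hat J0(ks a) H1(kf a).

# Hankel function of the first kind, order nu, real argument x > 0.
hankel1 <- function(nu, x) besselJ(x, nu) + 1i * besselY(x, nu)

# Shared boundary-matching denominator D at one frequency (SI inputs).
disk_denominator <- function(ks, kf, a_m, medium) {
  besselJ(ks * a_m, 1) * hankel1(0, kf * a_m) -
    medium$rho_hat * medium$c_hat * besselJ(ks * a_m, 0) * hankel1(1, kf * a_m)
}

# Interior / exterior radial solutions, vectorised over r_m (SI metres).
# Exposed through disk_field(); dpa_field() reuses the exterior branch.
disk_field_radial <- function(r_m, f, a_m, medium, optical) {
  k <- wavenumbers(medium, f)
  A <- pa_amplitude(optical, medium$vs)
  D <- disk_denominator(k$ks, k$kf, a_m, medium)
  if (!is.finite(D) || abs(D) < .Machine$double.xmin)
    stop("disk solution degenerate: boundary-matching denominator vanishes ",
         "at f = ", f, " MHz (resonance at machine precision)")
  rc <- medium$rho_hat * medium$c_hat
  out <- ifelse(
    r_m <= a_m,
    (A / k$ks) * (1 + rc * besselJ(k$ks * r_m, 0) * hankel1(1, k$kf * a_m) / D),
    (A / k$ks) * besselJ(k$ks * a_m, 1) * hankel1(0, k$kf * r_m) / D)
  if (any(!is.finite(out)))
    stop("non-finite analytic disk field at f = ", f, " MHz")
  out
}

#' Exact photoacoustic field of a single fluid disk
#'
#' Evaluates the closed-form interior (Bessel \eqn{J_0(k_s r)}) or
#' exterior (outgoing Hankel \eqn{H_0^{(1)}(k_f r)}) solution for a
#' uniformly illuminated circular absorber, depending on whether `point`
#' lies inside the disk.  Pressure and normal particle velocity are
#' continuous across the rim by construction.
#'
#' @param point Numeric length-2 position in micrometres (anywhere in the
#'   plane), or an n x 2 matrix of positions.
#' @param f Frequency in MHz (scalar, > 0).
#' @param disk A [disk()].
#' @param medium An [acoustic_medium()].
#' @param optical An [optical_params()].
#' @return Complex pressure (arbitrary units), one value per point.
#' @export
#' @examples
#' d <- disk()
#' disk_field(c(51, 0), f = 183, d, acoustic_medium(), optical_params())
disk_field <- function(point, f, disk, medium = acoustic_medium(),
                       optical = optical_params()) {
  stopifnot(length(f) == 1, f > 0, inherits(disk, "pa_disk"))
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  r_m <- um_to_m(sqrt((pts[, 1] - disk$center[1])^2 +
                      (pts[, 2] - disk$center[2])^2))
  disk_field_radial(r_m, f, um_to_m(disk$radius), medium, optical)
}

#' Discrete particle approach: linear superposition of disk fields
#'
#' Sums the exterior single-disk solution over every disk in the scene,
#' ignoring inter-particle acoustic scattering.  Valid only at points
#' exterior to all disks.
#'
#' @param point Numeric length-2 position (um) or an n x 2 matrix.
#' @param disks A [disk()] or list of disks.
#' @param f Frequency in MHz (scalar, > 0).
#' @param medium An [acoustic_medium()].
#' @param optical An [optical_params()].
#' @return Complex pressure, one value per point.
#' @export
dpa_field <- function(point, disks, f, medium = acoustic_medium(),
                      optical = optical_params()) {
  stopifnot(length(f) == 1, f > 0)
  disks <- as_disk_list(disks)
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  total <- complex(length.out = nrow(pts))
  for (d in disks) {
    r_m <- um_to_m(sqrt((pts[, 1] - d$center[1])^2 +
                        (pts[, 2] - d$center[2])^2))
    if (any(r_m <= um_to_m(d$radius)))
      stop("dpa_field is exterior-only: a field point lies inside a disk")
    total <- total +
      disk_field_radial(r_m, f, um_to_m(d$radius), medium, optical)
  }
  total
}

#' Analytic pressure spectrum at a detector
#'
#' Evaluates [disk_field()] (single disk) or [dpa_field()] (several
#' disks) at one detector position for every frequency of a grid.  No
#' smoothing is applied.
#'
#' @param detector Numeric length-2 detector position in micrometres,
#'   exterior to every source.
#' @param freqs A [frequency_grid()].
#' @param source A [disk()] or list of disks.
#' @param medium An [acoustic_medium()].
#' @param optical An [optical_params()].
#' @return A `pa_spectrum` object: complex `values` (1 x n_freq matrix),
#'   the frequency grid, and the evaluation method.
#' @export
#' @examples
#' sp <- analytic_spectrum(c(51, 0), frequency_grid(), disk())
#' sp$freqs$values[first_minimum_index(Mod(sp$values[1, ]))]  # ~432 MHz
analytic_spectrum <- function(detector, freqs, source,
                              medium = acoustic_medium(),
                              optical = optical_params()) {
  stopifnot(inherits(freqs, "frequency_grid"))
  disks <- as_disk_list(source)
  vals <- vapply(freqs$values, function(f) {
    if (length(disks) == 1L)
      disk_field(detector, f, disks[[1]], medium, optical)
    else
      dpa_field(detector, disks, f, medium, optical)
  }, complex(1))
  new_spectrum(matrix(vals, nrow = 1), freqs,
               method = if (length(disks) == 1L) "exact" else "dpa")
}

# Shared constructor for spectra (also used by frequency_sweep()).
new_spectrum <- function(values, freqs, method, detectors = NULL,
                         convergence = NULL) {
  structure(list(values = values, freqs = freqs, method = method,
                 detectors = detectors, convergence = convergence),
            class = "pa_spectrum")
}

#' @export
print.pa_spectrum <- function(x, ...) {
  cat(sprintf("<pa_spectrum> method=%s  %d detector(s) x %d frequencies\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Index of the first local minimum of a sampled curve
#'
#' Utility for reading the first spectral minimum off a sampled
#' amplitude spectrum: the first interior index whose value is smaller
#' than both neighbours.
#'
#' @param y Numeric vector (e.g. `Mod()` of a spectrum row).
#' @return Integer index of the first strict local minimum, or `NA` if
#'   none exists.
#' @export
first_minimum_index <- function(y) {
  stopifnot(is.numeric(y))
  if (length(y) < 3) return(NA_integer_)
  i <- which(diff(sign(diff(y))) == 2)
  if (length(i) == 0) NA_integer_ else i[1] + 1L
}
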