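#' Acoustic properties of the source and its surrounding fluid
#'
#' Bundles the sound speeds and mass densities of the absorbing source
#' region (subscript "s") and the ambient coupling fluid (subscript "f").
#' The derived density ratio \eqn{\hat\rho = \rho_s/\rho_f} and
#' sound-speed ratio \eqn{\hat c = v_s/v_f} control the boundary matching
#' of the disk solutions, while the wavenumbers \eqn{k_f = 2\pi f/v_f}
#' and \eqn{k_s = 2\pi f/v_s} set the scattering strength
#' \eqn{k_s^2 - k_f^2}.
#'
#' Defaults model a red blood cell in extracellular matrix: both
#' densities 1000 kg/m^3, ambient speed 1500 m/s, and an intracellular
#' speed of 1950 m/s (a +30\% contrast; values down to 1200 m/s, i.e.
#' -20\%, are typical study conditions).
#'
#' @param vf Sound speed of the ambient fluid (m/s, > 0).
#' @param vs Sound speed inside the source (m/s, > 0).
#' @param rho_f Density of the ambient fluid (kg/m^3, > 0).
#' @param rho_s Density of the source (kg/m^3, > 0).
#' @return An object of class `acoustic_medium` with fields `vf`, `vs`,
#'   `rho_f`, `rho_s` and the derived ratios `rho_hat`, `c_hat`.
#' @export
#' @examples
#' med <- acoustic_medium(vs = 1950)
#' wavenumbers(med, f = 183)  # rad/m at 183 MHz
acoustic_medium <- function(vf = 1500, vs = 1950, rho_f = 1000, rho_s = 1000) {
  stopifnot(is.numeric(vf), vf > 0, is.numeric(vs), vs > 0,
            is.numeric(rho_f), rho_f > 0, is.numeric(rho_s), rho_s > 0)
  structure(
    list(vf = vf, vs = vs, rho_f = rho_f, rho_s = rho_s,
         rho_hat = rho_s / rho_f, c_hat = vs / vf),
    class = "acoustic_medium")
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf("<acoustic_medium> vf=%g vs=%g m/s  rho_f=%g rho_s=%g kg/m^3\n",
              x$vf, x$vs, x$rho_f, x$rho_s))
  cat(sprintf("  rho_hat=%g  c_hat=%g  (sound-speed contrast %+.0f%%)\n",
              x$rho_hat, x$c_hat, 100 * (x$c_hat - 1)))
  invisible(x)
}

#' Wavenumbers of the source and ambient regions at a frequency
#'
#' @param medium An [acoustic_medium()].
#' @param f Modulation frequency in MHz (> 0).
#' @return A list with `kf` and `ks` in rad/m.
#' @export
wavenumbers <- function(medium, f) {
  stopifnot(inherits(medium, "acoustic_medium"), all(f > 0))
  omega <- 2 * pi * mhz_to_hz(f)
  list(kf = omega / medium$vf, ks = omega / medium$vs)
}

#' Optical and thermodynamic parameters of the absorber
#'
#' The photoacoustic amplitude of a disk is
#' \eqn{A = i \mu \beta I_0 v_s / C_p}: light of intensity \eqn{I_0} is
#' absorbed with coefficient \eqn{\mu} and converted to pressure through
#' the thermal expansion coefficient \eqn{\beta} and specific heat
#' \eqn{C_p}.  All four enter only through this product, so they default
#' to unity (reduced units) and simply scale the field linearly.
#'
#' @param I0 Incident light intensity (arbitrary units, >= 0).
#' @param mu Optical absorption coefficient (>= 0).
#' @param beta Isobaric thermal expansion coefficient (>= 0).
#' @param Cp Specific heat of the absorber (> 0).
#' @return An object of class `optical_params`.
#' @export
optical_params <- function(I0 = 1, mu = 1, beta = 1, Cp = 1) {
  stopifnot(I0 >= 0, mu >= 0, beta >= 0, Cp > 0)
  structure(list(I0 = I0, mu = mu, beta = beta, Cp = Cp),
            class = "optical_params")
}

#' @export
print.optical_params <- function(x, ...) {
  cat(sprintf("<optical_params> I0=%g mu=%g beta=%g Cp=%g\n",
              x$I0, x$mu, x$beta, x$Cp))
  invisible(x)
}

# PA amplitude A = i mu beta I0 vs / Cp (purely imaginary for real inputs).
pa_amplitude <- function(optical, vs) {
  1i * optical$mu * optical$beta * optical$I0 * vs / optical$Cp
}

#' A circular absorbing disk
#'
#' The elementary photoacoustic source: a fluid disk of radius `radius`
#' centred at `center`, approximating a red blood cell seen in cross
#' section.
#'
#' @param center Numeric length-2 vector, disk centre in micrometres.
#' @param radius Disk radius in micrometres (> 0); default 2.75 um, a
#'   typical erythrocyte radius.
#' @return An object of class `pa_disk`.
#' @export
#' @examples
#' disk()                      # RBC-sized disk at the origin
#' disk(c(10, -5), radius = 3)
disk <- function(center = c(0, 0), radius = 2.75) {
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)),
            is.numeric(radius), length(radius) == 1, radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "pa_disk")
}

#' @export
print.pa_disk <- function(x, ...) {
  cat(sprintf("<pa_disk> center=(%g, %g) um  radius=%g um\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

# Accept a single disk or a list of disks; always return a list.
as_disk_list <- function(disks) {
  if (inherits(disks, "pa_disk")) return(list(disks))
  stopifnot(is.list(disks), all(vapply(disks, inherits, logical(1), "pa_disk")))
  disks
}

#' Equally spaced frequency grid
#'
#' The default band runs from 7.3233 MHz to 2197 MHz in 300 equal steps
#' of \eqn{\Delta f = 2197/300} MHz, i.e. \eqn{f_k = k\,\Delta f} for
#' \eqn{k = 1, \dots, 300}.  Over this band the size parameter
#' \eqn{k_f a} of a 2.75-um disk in water-like fluid spans roughly 0.08
#' to 25, covering the long-wavelength through strongly phase-sensitive
#' scattering regimes.
#'
#' @param f_min,f_max Band edges in MHz.
#' @param n_points Number of equally spaced frequencies.
#' @return An object of class `frequency_grid` with a `values` vector
#'   (MHz, strictly increasing).
#' @export
#' @examples
#' fg <- frequency_grid()
#' length(fg$values)  # 300
frequency_grid <- function(f_min = 2197 / 300, f_max = 2197, n_points = 300) {
  stopifnot(n_points >= 1, f_min > 0, f_max >= f_min)
  values <- if (n_points == 1) f_min else seq(f_min, f_max, length.out = n_points)
  structure(list(f_min = f_min, f_max = f_max, n_points = as.integer(n_points),
                 values = values),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d points, %.4g to %.4g MHz (step %.4g MHz)\n",
              x$n_points, x$f_min, x$f_max,
              if (x$n_points > 1) x$values[2] - x$values[1] else NA_real_))
  invisible(x)
}

#' Dimensionless size parameter of a disk
#'
#' \eqn{k_f a = 2\pi f a / v_f}, the ratio of the disk circumference to
#' the acoustic wavelength in the ambient fluid.
#'
#' @param f Frequency in MHz (vectorised).
#' @param radius Disk radius in micrometres.
#' @param medium An [acoustic_medium()].
#' @return Numeric vector of \eqn{k_f a} values.
#' @export
#' @examples
#' size_parameter(c(7.3233, 2197), 2.75, acoustic_medium())
size_parameter <- function(f, radius = 2.75, medium = acoustic_medium()) {
  2 * pi * mhz_to_hz(f) * um_to_m(radius) / medium$vf
}
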