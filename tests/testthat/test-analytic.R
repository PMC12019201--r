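# Exact disk solutions and the discrete-particle superposition.

test_that("pressure is continuous across the disk rim for a range of contrasts", {
  d <- disk()
  for (vs in c(1950, 1500, 1200)) {
    for (rho_s in c(900, 1000, 1100)) {
      med <- acoustic_medium(vs = vs, rho_s = rho_s)
      for (f in c(51, 183, 732)) {
        a <- d$radius
        inner <- disk_field(c(a * (1 - 1e-9), 0), f, d, med)
        outer <- disk_field(c(a * (1 + 1e-9), 0), f, d, med)
        ref <- disk_field(c(a, 0), f, d, med)
        expect_lt(Mod(inner - outer) / Mod(ref), 1e-6)
      }
    }
  }
})

test_that("normal particle velocity is continuous across the rim", {
  # (1/rho_s) d(psi_s)/dr = (1/rho_f) d(psi_f)/dr at r = a, by central
  # differences on each side of the rim.
  d <- disk()
  a <- d$radius
  eps <- 1e-5  # um
  for (vs in c(1950, 1200)) {
    for (rho_s in c(900, 1100)) {
      med <- acoustic_medium(vs = vs, rho_s = rho_s)
      f <- 183
      dpsi_in <- (disk_field(c(a - eps, 0), f, d, med) -
                  disk_field(c(a - 3 * eps, 0), f, d, med)) / (2 * eps)
      dpsi_out <- (disk_field(c(a + 3 * eps, 0), f, d, med) -
                   disk_field(c(a + eps, 0), f, d, med)) / (2 * eps)
      lhs <- dpsi_in / med$rho_s
      rhs <- dpsi_out / med$rho_f
      expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-4)
    }
  }
})

test_that("zero-contrast denominator reduces to the Bessel Wronskian 2i/(pi x)", {
  med <- acoustic_medium(vs = 1500)  # vs = vf, rho_s = rho_f
  for (f in c(50, 200, 800)) {
    k <- wavenumbers(med, f)
    x <- k$kf * um_to_m(2.75)
    D <- pacbs:::disk_denominator(k$ks, k$kf, um_to_m(2.75), med)
    expect_lt(Mod(D - 2i / (pi * x)), 1e-12 * Mod(D))
  }
})

test_that("field scales linearly with light intensity and is finite at r = 0 and far away", {
  d <- disk()
  med <- acoustic_medium()
  base <- disk_field(c(10, 3), 183, d, med, optical_params(I0 = 1))
  scaled <- disk_field(c(10, 3), 183, d, med, optical_params(I0 = 3.5))
  expect_equal(scaled, 3.5 * base)
  expect_true(is.finite(Mod(disk_field(c(0, 0), 183, d, med))))
  far <- disk_field(c(1e5, 0), 183, d, med)
  expect_true(is.finite(Mod(far)))
  expect_lt(Mod(far), Mod(disk_field(c(51, 0), 183, d, med)))
})

test_that("spectral minima multiply and crowd together as vs decreases", {
  fg <- frequency_grid()
  n_minima <- sapply(c(1950, 1500, 1200), function(vs) {
    m <- Mod(analytic_spectrum(c(51, 0), fg, disk(),
                               acoustic_medium(vs = vs))$values[1, ])
    idx <- which(diff(sign(diff(m))) == 2) + 1
    list(count = length(idx), first_gap = diff(fg$values[idx[1:2]]))
  })
  counts <- unlist(n_minima["count", ])
  gaps <- unlist(n_minima["first_gap", ])
  expect_true(all(diff(counts) > 0))  # 1950 < 1500 < 1200 minima counts
  expect_true(all(diff(gaps) < 0))    # successive-minima spacing shrinks
})

test_that("DPA reduces to the single-disk field and superposes linearly", {
  med <- acoustic_medium()
  d0 <- disk()
  pt <- c(31, 7)
  expect_equal(dpa_field(pt, d0, 183, med), disk_field(pt, 183, d0, med))
  # two identical disks equidistant from the detector -> exactly double
  two <- list(disk(c(0, 10)), disk(c(0, -10)))
  expect_equal(dpa_field(c(40, 0), two, 183, med),
               2 * disk_field(c(40, 0), 183, two[[1]], med))
})

test_that("DPA matches an independent term-by-term summation oracle", {
  tr <- random_phantom(n_disks = 5, roi_size = 12, seed = 11)
  med <- acoustic_medium(vs = 1200)
  opt <- optical_params(I0 = 2)
  pt <- c(45, -13)
  oracle <- 0 + 0i
  for (d in tr$disks) {
    r <- sqrt(sum((pt - d$center)^2)) * 1e-6
    a <- d$radius * 1e-6
    f_hz <- 183e6
    ks <- 2 * pi * f_hz / med$vs
    kf <- 2 * pi * f_hz / med$vf
    h1 <- function(nu, x) besselJ(x, nu) + 1i * besselY(x, nu)
    A <- 1i * opt$mu * opt$beta * opt$I0 * med$vs / opt$Cp
    oracle <- oracle + A * besselJ(ks * a, 1) * h1(0, kf * r) /
      (ks * (besselJ(ks * a, 1) * h1(0, kf * a) -
             med$rho_hat * med$c_hat * besselJ(ks * a, 0) * h1(1, kf * a)))
  }
  expect_equal(dpa_field(pt, tr$disks, 183, med, opt), oracle,
               tolerance = 1e-13)
})

test_that("DPA refuses field points inside a disk", {
  expect_error(dpa_field(c(0.5, 0), disk(), 183), "exterior-only")
})

test_that("analytic_spectrum is the pointwise field on the default 300-point band", {
  fg <- frequency_grid()
  expect_identical(fg$n_points, 300L)
  expect_equal(fg$values[2] - fg$values[1], 2197 / 300)
  sp <- analytic_spectrum(c(51, 0), frequency_grid(n_points = 5), disk())
  for (k in 1:5)
    expect_equal(sp$values[1, k],
                 disk_field(c(51, 0), sp$freqs$values[k], disk()))
})
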