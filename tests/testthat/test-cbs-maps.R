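# Operator lattices: source term, scattering potential, Fourier Green's
# function, ABL window, and the scalar helpers.

test_that("source map is -i*omega inside disks, zero outside, fractional at the rim", {
  g <- test_grid(64)
  expect_equal(source_map(g, list(), f = 183), matrix(0 + 0i, 64, 64))
  S <- source_map(g, disk(radius = 1.5), f = 183)
  s0 <- -1i * 2 * pi * 183e6
  expect_true(any(S == s0))              # fully covered pixels
  expect_true(any(S == 0))               # exterior
  w <- Mod(S) / Mod(s0)
  expect_true(all(w >= 0 & w <= 1 + 1e-12))
  expect_true(any(w > 0 & w < 1))        # area-weighted rim pixels
})

test_that("rasterized disk area matches pi a^2 and the pixel count its h^2 quotient", {
  g <- test_grid(512)
  cov <- rasterize_disks(g, disk())
  # covered area within one part in 10^3 of the true disk area
  # (4x4 subsampling quantises boundary coverage in 1/16 steps)
  expect_equal(sum(cov) * g$h^2, pi * 2.75^2, tolerance = 1e-3)
  # majority-covered pixel count near pi a^2/h^2 = 2375.8
  count <- sum(cov >= 0.5)
  expect_gt(count, 2376 - 60)
  expect_lt(count, 2376 + 60)
})

test_that("disks reaching into the ABL frame trigger a warning", {
  g <- test_grid(64)
  expect_warning(source_map(g, disk(c(2, 0), radius = 1), f = 183, abl_d = 16),
                 "absorbing boundary")
})

test_that("scattering potential encodes the sound-speed contrast", {
  g <- test_grid(64)
  f <- 183
  kf <- wavenumbers(acoustic_medium(), f)$kf
  eps <- 0.8 * kf^2
  # zero contrast: uniform -i*eps
  V0 <- potential_map(g, disk(radius = 1.5), acoustic_medium(vs = 1500), f, eps)
  expect_equal(V0, matrix(complex(real = 0, imaginary = -eps), 64, 64))
  # vs = 1200: Re(V) inside = ((1500/1200)^2 - 1) kf^2 = 0.5625 kf^2
  V <- potential_map(g, disk(radius = 1.5), acoustic_medium(vs = 1200), f, eps)
  expect_equal(max(Re(V)), 0.5625 * kf^2, tolerance = 1e-12)
  expect_equal(unique(as.vector(Im(V))), -eps)
})

test_that("epsilon below the contrast bound is rejected; 0.8 kf^2 passes both extremes", {
  g <- test_grid(64)
  f <- 183
  kf <- wavenumbers(acoustic_medium(), f)$kf
  expect_error(
    potential_map(g, disk(radius = 1.5), acoustic_medium(vs = 1200), f,
                  0.5 * kf^2),
    "convergence guarantee")
  for (vs in c(1200, 1950))
    expect_silent(potential_map(g, disk(radius = 1.5),
                                acoustic_medium(vs = vs), f, 0.8 * kf^2))
})

test_that("Fourier Green's function has the exact analytic values and bound", {
  g <- test_grid(64)
  # choose kf on a lattice point so |p|^2 = kf^2 is hit exactly
  p <- grid_fourier(g) * 1e6
  kf <- abs(p[4])
  eps <- 0.3 * kf^2
  gt <- greens_ft(g, kf, eps)
  expect_equal(gt[1, 1], -1 / (kf^2 + 1i * eps))         # p = 0 bin
  expect_equal(gt[4, 1], 1i / eps)                        # |p|^2 = kf^2 bin
  expect_equal(max(Mod(gt)), 1 / eps, tolerance = 1e-12)  # global bound attained
})

test_that("ABL window is 1 in the interior and tiny at the outer edge", {
  # 1-um pitch so the 25-pixel layer is 25 um thick (physically
  # comparable to the production 50-um layer)
  n <- 64
  g <- sim_grid(n, h = 1)
  d <- 25  # odd so a pixel centre sits exactly at the sigmoid midpoint
  W <- abl_window(g, d = d, kappa = 61.36e2)
  interior <- W[(d + 1):(n - d), (d + 1):(n - d)]
  expect_true(all(interior == 1))
  # pixel at distance 0.5*d*h from the boundary: per-axis profile 0.5
  mid <- (d + 1) / 2
  expect_equal(W[mid, n / 2], 0.5, tolerance = 1e-12)
  # per-axis edge value 1/(1 + exp(kappa * 0.5 d h)) ~ 6.4e-4 at the
  # outermost pixel centre; the corner is its square
  edge_val <- 1 / (1 + exp(61.36e2 * 1e2 * (12.5e-6 - 0.5e-6)))
  expect_equal(W[1, n / 2], edge_val, tolerance = 1e-10)
  expect_equal(W[1, 1], edge_val^2, tolerance = 1e-10)
  expect_true(all(W > 0 & W <= 1))
})

test_that("center-row error formula matches hand-evaluated cases", {
  g <- test_grid(64)
  psi <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  expect_equal(total_error(psi, psi, g), 0)
  expect_equal(total_error(2 * psi, psi, g), 1)
  # center rows [1, i] vs [1 + 1e-4, i] -> 1e-4 / 2
  a <- matrix(0 + 0i, 64, 64); b <- a
  a[32, 1:2] <- c(1 + 0i, 1i)
  b[32, 1:2] <- c(1 + 1e-4 + 0i, 1i)
  expect_equal(total_error(b, a, g), 5e-5)
  expect_error(total_error(psi, matrix(0 + 0i, 64, 64), g), "zero")
})

test_that("attenuation coefficient is eps/(2 kf), linear in frequency under the 0.8 rule", {
  expect_equal(attenuation_coefficient(0, 100), 0)
  for (f in c(7.32, 183, 2197)) {
    kf <- wavenumbers(acoustic_medium(), f)$kf
    expect_equal(attenuation_coefficient(0.8 * kf^2, kf), 0.4 * kf)
  }
})
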