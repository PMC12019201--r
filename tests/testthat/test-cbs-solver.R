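# Born-series iteration: initial field, single steps vs the brute-force
# oracle, full solves vs convergence contracts, and the TBS fallback.

test_that("initial field is zero for an empty scene and uniform for constant S", {
  g <- sim_grid(64, h = 0.1)
  ws <- cbs_workspace(g, list(), acoustic_medium(), optical_params(), 183,
                      cbs_config(abl_d = 16))
  expect_equal(initial_field(ws), matrix(0 + 0i, 64, 64))
  # spatially constant S: only the zero-frequency Fourier bin survives,
  # so psi0 = gamma * s0 * gt(0) (before the window, uniform)
  s0 <- 3 - 2i
  ws$S <- matrix(s0, 64, 64)
  psi0 <- initial_field(ws)
  expected <- ws$window * ((1i / ws$epsilon) * ws$V * s0 * ws$greens[1, 1])
  expect_equal(psi0, expected, tolerance = 1e-12)
})

test_that("initial field of a point source decays away from the source pixel", {
  g <- sim_grid(64, h = 0.1)
  ws <- cbs_workspace(g, list(), acoustic_medium(), optical_params(), 183,
                      cbs_config(abl_d = 16))
  ws$S[32, 32] <- -1i * 2 * pi * 183e6
  amp <- Mod(initial_field(ws))
  along <- amp[32, 32:48]  # profile moving away from the source
  expect_equal(which.max(along), 1L)
  expect_true(all(diff(along) < 0))
})

test_that("cbs_step matches the direct-summation convolution oracle on 32x32", {
  g <- sim_grid(32, h = 0.1)
  cfg <- cbs_config(abl_d = 8)
  ws <- cbs_workspace(g, disk(radius = 0.6), acoustic_medium(vs = 1950),
                      optical_params(), 183, cfg)
  set.seed(4)
  psi <- matrix(complex(real = rnorm(32^2), imaginary = rnorm(32^2)), 32, 32)
  psi <- psi * 1e-7  # typical field scale

  kernel <- idft2_direct(ws$greens)      # real-space kernel, no fft()
  conv <- circ_conv_direct(kernel, ws$V * psi + ws$S)
  gamma <- (1i / ws$epsilon) * ws$V
  oracle <- ws$window * (psi - gamma * (psi - conv))

  step <- cbs_step(psi, ws)
  expect_lt(max(Mod(step - oracle)) / max(Mod(oracle)), 1e-12)
})

test_that("the compiled solver loop reproduces the R reference step exactly", {
  g <- sim_grid(64, h = 0.1)
  cfg1 <- cbs_config(abl_d = 16, max_iter = 1)
  d <- disk(radius = 1)
  med <- acoustic_medium(vs = 1200)
  ws <- cbs_workspace(g, d, med, optical_params(), 366, cfg1)
  # one compiled iteration == one R step from the initial field
  sol1 <- suppressWarnings(solve_cbs(d, med, optical_params(), 366, g, cfg1))
  ref <- cbs_step(initial_field(ws), ws)
  expect_lt(max(Mod(sol1$psi - ref)) / max(Mod(ref)), 1e-12)
  expect_equal(sol1$error_trace[1], total_error(ref, initial_field(ws), g),
               tolerance = 1e-12)
  # a few more iterations, compared against an explicit R loop
  cfg5 <- cbs_config(abl_d = 16, max_iter = 5)
  sol5 <- suppressWarnings(solve_cbs(d, med, optical_params(), 366, g, cfg5))
  psi <- initial_field(ws)
  for (l in 1:5) psi <- cbs_step(psi, ws)
  expect_lt(max(Mod(sol5$psi - psi)) / max(Mod(psi)), 1e-11)
})

test_that("single-disk solves converge and satisfy the convergence contract", {
  g <- test_grid(256)
  cfg <- test_config(256)
  for (vs in c(1950, 1200)) {
    sol <- solve_cbs(disk(radius = 1.5), rbc_medium(vs), optical_params(),
                     183, g, cfg)
    expect_true(sol$converged)
    expect_lt(utils::tail(sol$error_trace, 1), cfg$error_threshold)
    expect_equal(sol$iterations, length(sol$error_trace))
    expect_true(all(is.finite(Mod(sol$psi))))
    # definition of convergence: one further step moves the center row
    # by less than the threshold
    ws <- cbs_workspace(g, disk(radius = 1.5), rbc_medium(vs),
                        optical_params(), 183, cfg)
    expect_lt(total_error(cbs_step(sol$psi, ws), sol$psi, g),
              cfg$error_threshold)
  }
})

test_that("iteration count grows with frequency at fixed contrast", {
  g <- test_grid(256)
  cfg <- test_config(256)
  iters <- sapply(c(183, 366, 732), function(f)
    solve_cbs(disk(radius = 1.5), rbc_medium(1950), optical_params(),
              f, g, cfg)$iterations)
  expect_true(all(diff(iters) >= 0))
})

test_that("the ABL suppresses the field at the domain edge", {
  sol <- solve_test(disk(), vs = 1950, f = 366)
  n <- sol$grid$n
  ring <- c(Mod(sol$psi[1, ]), Mod(sol$psi[n, ]),
            Mod(sol$psi[, 1]), Mod(sol$psi[, n]))
  expect_lt(max(ring), 1e-3 * max(Mod(sol$psi)))
})

test_that("solves are deterministic and zero contrast equals vs = vf substitution", {
  a <- solve_test(disk(), vs = 1500, f = 183, n = 128)
  b <- solve_test(disk(), vs = 1500, f = 183, n = 128)
  expect_identical(a$psi, b$psi)
  med_sub <- acoustic_medium(vf = 1500, vs = 1500)
  c2 <- suppressWarnings(solve_cbs(disk(), med_sub, optical_params(), 183,
                                   test_grid(128), test_config(128)))
  expect_identical(a$psi, c2$psi)
})

test_that("non-convergence warns and flags, never errors", {
  g <- test_grid(128)
  cfg <- cbs_config(abl_d = 32, max_iter = 3)
  expect_warning(
    sol <- solve_cbs(disk(), rbc_medium(1950), optical_params(), 183, g, cfg),
    "did not converge")
  expect_false(sol$converged)
  expect_equal(sol$iterations, 3L)
})

test_that("TBS converges for weak scattering and agrees with CBS", {
  # zero contrast, small disk, low frequency: the unpreconditioned
  # series converges and both solvers approximate the same solution
  g <- test_grid(256)
  cfg <- test_config(256)
  d <- disk(radius = 1)
  tbs <- solve_tbs(d, rbc_medium(1500), optical_params(), 51, g, cfg)
  cbs <- solve_cbs(d, rbc_medium(1500), optical_params(), 51, g, cfg)
  expect_true(tbs$converged)
  cr <- pacbs:::center_row_index(g)
  keep <- (cfg$abl_d + 1):(g$n - cfg$abl_d)
  rel <- sqrt(sum(Mod(tbs$psi[cr, keep] - cbs$psi[cr, keep])^2) /
              sum(Mod(cbs$psi[cr, keep])^2))
  expect_lt(rel, 0.01)
})

test_that("TBS diverges for large contrast at high frequency and flags it", {
  g <- test_grid(256)
  cfg <- cbs_config(abl_d = 64, max_iter = 300)
  for (vs in c(1950, 1200)) {
    sol <- suppressWarnings(
      solve_tbs(disk(), rbc_medium(vs), optical_params(), 2197, g, cfg))
    expect_false(sol$converged)
    expect_true(sol$diverged)
  }
})

test_that("TBS with an all-zero source returns the zero field after one step", {
  g <- test_grid(64)
  sol <- solve_tbs(list(), rbc_medium(1950), optical_params(), 183, g,
                   cbs_config(abl_d = 16))
  expect_true(sol$converged)
  expect_equal(sol$iterations, 1L)
  expect_equal(sol$psi, matrix(0 + 0i, 64, 64))
})
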