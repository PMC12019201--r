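# Shared fixtures: a fast full-physics configuration (512-pixel lattice,
# 100 nm pitch, 128-pixel ABL with the production kappa so the physical
# taper profile is unchanged) and small scene builders.

test_grid <- function(n = 512) sim_grid(n, h = 0.1)

test_config <- function(n = 512) cbs_config(abl_d = n / 4)

rbc_medium <- function(vs = 1950) acoustic_medium(vf = 1500, vs = vs)

single_disk_scene <- function(vs = 1950, radius = 2.75) {
  list(disks = disk(radius = radius), medium = rbc_medium(vs),
       optical = optical_params())
}

# Quiet CBS solve on the test lattice.
solve_test <- function(disks, vs = 1950, f = 183, n = 512,
                       optical = optical_params()) {
  suppressWarnings(
    solve_cbs(disks, rbc_medium(vs), optical, f, test_grid(n),
              test_config(n)))
}

# Small random non-overlapping scenes for property loops.
random_phantom <- function(n_disks = 6, roi_size = 10, seed = 1,
                           radius = 2.75) {
  pack_disks(roi_spec("circle", roi_size),
             packing_config(n_disks, radius = radius, seed = seed))
}

# Independent brute-force oracles ------------------------------------

# Direct inverse 2D DFT via explicit DFT matrices (no fft() call).
idft2_direct <- function(G) {
  n <- nrow(G)
  w <- exp(2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  (w %*% G %*% w) / n^2
}

# Direct-summation circular convolution of a kernel with a lattice.
circ_conv_direct <- function(kernel, x) {
  n <- nrow(x)
  out <- matrix(0 + 0i, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      di <- ((i - seq_len(n)) %% n) + 1
      dj <- ((j - seq_len(n)) %% n) + 1
      out[i, j] <- sum(kernel[di, dj] * x)
    }
  }
  out
}
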