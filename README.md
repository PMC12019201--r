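# pacbs

Frequency-domain simulation of two-dimensional photoacoustic (PA)
pressure fields generated by optically absorbing disks that mimic red
blood cells, for researchers modelling PA microscopy/spectroscopy of
blood at the cellular scale.

When modulated light of frequency *f* is absorbed by a fluid disk of
radius *a*, the pressure field ψ obeys an inhomogeneous Helmholtz
equation: ∇²ψ + k²ψ = iωμβI₀/C_p inside the absorber (wavenumber
k_s = ω/v_s) and ∇²ψ + k_f²ψ = 0 outside (k_f = ω/v_f).  Because cell
and ambient sound speeds differ, each cell also scatters its
neighbours' waves; dense suspensions exhibit multiple scattering that
linear superposition cannot capture.  The package provides three routes
to the field and the machinery to compare them:

- **Exact disk solution** — closed-form interior/exterior solutions in
  Bessel/Hankel functions (`disk_field()`, `analytic_spectrum()`), with
  the boundary-matching denominator
  D = J₁(k_s a)H₀⁽¹⁾(k_f a) − ρ̂ĉ J₀(k_s a)H₁⁽¹⁾(k_f a).
- **Discrete particle approach (DPA)** — linear superposition of
  exterior disk fields (`dpa_field()`), exact only at zero contrast.
- **Convergent Born series (CBS)** — a preconditioned fixed-point
  iteration ψ ← ψ − γ{ψ − IFFT[g̃ · FFT(Vψ + S)]} with
  γ = (i/ε)V and g̃(p) = 1/(|p|² − k_f² − iε), which converges for
  arbitrary sound-speed contrast when ε ≥ max|k_s² − k_f²|
  (`solve_cbs()`; the divergence-prone traditional series is
  `solve_tbs()`).  A sigmoid absorbing boundary layer suppresses the
  FFT's periodic wrap-around.

Blood-smear phantoms — non-overlapping disk ensembles at a target
hematocrit — are generated by a Metropolis–Hastings chain
(`pack_disks()`), and experiment harnesses cover center-line
comparisons, frequency sweeps at ring detectors and ensemble statistics
over phantom realizations.

## Worked example

```r
library(pacbs)

med <- acoustic_medium(vf = 1500, vs = 1950)   # +30% contrast RBC
sol <- solve_cbs(disk(), med, optical_params(), f = 183,
                 grid = sim_grid(512), config = cbs_config(abl_d = 128))
sol
#> <field_solution> CBS  f=183 MHz  n=512  26 iterations  converged

cmp <- compare_cbs_analytic(sol, list(disks = disk(), medium = med))
sprintf("rel L2 vs analytic: outside %.4f, inside %.4f",
        cmp$outside$rel_l2, cmp$inside$rel_l2)
#> "rel L2 vs analytic: outside 0.0174, inside 0.0109"

fg <- frequency_grid()                          # 7.3233 to 2197 MHz, 300 points
sp <- analytic_spectrum(c(51, 0), fg, disk(), med)
fg$values[first_minimum_index(Mod(sp$values[1, ]))]
#> 432.0767

tr <- pack_disks(roi_spec("circle", 50), packing_config(133, seed = 1))
tr
#> <tissue_realization> 133 disks in circle ROI (size 50 um), area fraction 0.402
#>   seed 1, 6297 proposals (617 accepted), final energy 0
```

The solver converges in 26 iterations on the 512² demonstration
lattice and reproduces the exact solution on the center line to ~2%.
The first minimum of the amplitude spectrum at a detector 51 µm away
falls at 432 MHz for v_s = 1950 m/s (330 and 264 MHz for 1500 and
1200 m/s — the spectral fingerprint of the intracellular sound speed).
The phantom generator reaches exactly zero overlap energy for 133 cells
at 40% area coverage.

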