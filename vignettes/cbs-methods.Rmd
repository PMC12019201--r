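---
title: "Simulating photoacoustic fields from erythrocyte ensembles with a convergent Born series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating photoacoustic fields from erythrocyte ensembles with a convergent Born series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacbs)
```

## The physical problem

When blood is illuminated by an intensity-modulated light beam, red
blood cells (RBCs) absorb the light and radiate pressure waves -- the
photoacoustic (PA) effect.  In the monochromatic regime the pressure
field $\psi(\mathbf r)$ of an absorbing region obeys a Helmholtz
equation with a source term,

$$\nabla^2\psi + k_s^2\,\psi = \frac{i\omega\mu\beta I_0}{C_p}
\quad\text{(inside the absorber)},\qquad
\nabla^2\psi + k_f^2\,\psi = 0 \quad\text{(outside)},$$

where $k_s = \omega/v_s$ and $k_f = \omega/v_f$ are the wavenumbers of
the cell interior and the ambient fluid, $I_0$ is the light intensity,
$\mu$ the optical absorption coefficient, $\beta$ the isobaric thermal
expansion coefficient and $C_p$ the specific heat.  A cell is modelled
as a fluid disk in 2D (an RBC seen in cross-section, radius
$a = 2.75\ \mu\mathrm m$).  Because RBC sound speed differs from the
extracellular matrix (here $v_s$ between 1200 and 1950 m/s against
$v_f = 1500$ m/s), each cell also *scatters* the waves emitted by its
neighbours: in dense suspensions the field inside the tissue carries a
multiple-scattering signature that linear superposition misses.  The
package exists to compute that field and expose that signature.

Three routes to the field are implemented:

1. **Exact single-disk solution** (`disk_field()`): matching pressure
   and normal particle velocity at the rim gives interior/exterior
   solutions in Bessel $J$ and outgoing Hankel $H^{(1)}$ functions,
   sharing the denominator
   $D = J_1(k_s a)H_0^{(1)}(k_f a) - \hat\rho\hat c\,
   J_0(k_s a)H_1^{(1)}(k_f a)$ with $\hat\rho = \rho_s/\rho_f$,
   $\hat c = v_s/v_f$.  This is the oracle everything else is measured
   against.
2. **Discrete particle approach** (`dpa_field()`): the exterior
   solutions of all disks added linearly -- correct only when
   inter-particle scattering is negligible (zero sound-speed contrast).
3. **Convergent Born series** (`solve_cbs()`): a preconditioned
   fixed-point iteration for the full inhomogeneous problem on a pixel
   lattice, valid for arbitrary contrast and any number of sources.

## The convergent Born series

Adding an artificial loss $i\epsilon$ to both sides turns the governing
equation into
$(\nabla^2 + k_f^2 + i\epsilon)\psi = -S - V\psi$ with the source map
$S = -i\mu\beta I_0\omega/C_p$ inside sources (0 outside) and the
scattering potential $V = k_s^2 - k_f^2 - i\epsilon$ inside
($-i\epsilon$ outside).  The damped Green's operator is diagonal in the
Fourier domain, $\tilde g(\mathbf p) = 1/(|\mathbf p|^2 - k_f^2 -
i\epsilon)$, so one operator application is two FFTs.  The plain
(traditional) Born iteration $\psi \leftarrow G[V\psi + S]$ converges
only for weak potentials and small sources -- `solve_tbs()` implements
it and detects its divergence for demonstration.  Preconditioning with
$\gamma = (i/\epsilon)V$ yields the convergent update

$$\psi \leftarrow \psi - \gamma\left\{\psi -
\mathrm{IFFT}\!\left[\tilde g\,\mathrm{FFT}\,[V\psi + S]\right]\right\},$$

which converges for arbitrarily strong contrast provided
$\epsilon \ge \max|k_s^2 - k_f^2|$.  A note on the preconditioner: it
is sometimes typeset as $\gamma = i\epsilon V$, which is dimensionally
inconsistent with the update's leading correction term
$(i/\epsilon)V\psi$; the $(i/\epsilon)V$ form is the one that
reproduces published iteration-count behaviour, and is what the package
uses.  The default $\epsilon = 0.8k_f^2$ (`cbs_config(c_eps = 0.8)`)
satisfies the convergence bound for the whole $v_s$ range studied here:
the contrast factor $|(v_f/v_s)^2 - 1|$ is 0.5625 at 1200 m/s and 0.408
at 1950 m/s.  The loss makes the *iteration* medium attenuating, with
$\alpha \approx \epsilon/(2k_f) = 0.4\,k_f$ (about 122.7 Np/cm at
7.32 MHz), but the converged fixed point solves the original lossless
equation -- the $i\epsilon$ terms cancel identically at convergence.

### Lattice, boundary layer, stopping rule

The production lattice is $2048\times2048$ pixels at
$h = 100\ \mathrm{nm}$ (204.8 $\mu$m per side), with Fourier
coordinates $p = 2\pi m/(nh)$ in FFT-native order.  The forward/inverse
FFT pair is mutually inverse (the $1/n^2$ on the inverse), and
$\tilde g$ multiplies spectra of lattice samples directly -- with this
normalisation the discrete convolution approximates the continuum
integral with no extra pixel-area factor, which is why the computed
amplitudes match the analytic solution absolutely, not just in shape.

Because the FFT imposes periodic boundaries, an absorbing boundary
layer (ABL) of $d = 500$ pixels frames the domain.  Along each axis the
window is $1/(1 + e^{-\kappa(x - dh/2)})$ for distance $x$ from the
outer boundary (evaluated at pixel centres, in physical units against
$\kappa = 61.36\times10^2$ Np/cm), exactly 1 in the interior, and the
2D window is the product of the per-axis profiles -- separable, so
corners damp at least as strongly as edges.  The window multiplies the
field after the initial estimate and after every update; outgoing waves
die before wrapping (edge amplitude below $10^{-3}$ of the interior
maximum).  A residual of the separable window is a small anisotropic
artifact near the interior/frame seam: on a 512-pixel lattice whose
layer is only 12.8 $\mu$m thick, ring detectors around a centred disk
see a 1--2% angular ripple that thins with layer thickness.

Iterations stop when the relative center-row change
$\sum_m|\psi_{l+1}(c,m)-\psi_l(c,m)| \,/\, \sum_m|\psi_l(c,m)|$ (row
$c = n/2$, 1-based) drops below $10^{-4}$, with a hard cap of 2000.
The error is evaluated on the field actually carried forward, i.e.
after the window multiplication.  Non-convergence at the cap is a
warning plus `converged = FALSE`, never an error; any non-finite
intermediate aborts with a diagnostic naming the stage.

### Rasterisation of sources

Disks are laid onto the lattice by **area-weighted rasterisation**:
each pixel of $S$ and $V$ carries the fraction of its area covered by
the disk, estimated on a $4\times4$ subpixel lattice
(`rasterize_disks()`).  This choice was forced by the physics.  A
binary centre-in-disk rule perturbs the effective disk radius by
$O(h/2) \approx 0.9\%$; away from resonances that is harmless, but a
fluid disk with $v_s < v_f$ is a potential barrier with sharp interior
resonances, and at 732 MHz / $v_s = 1200$ m/s the analytic exterior
amplitude changes several-fold between $a = 2.70$ and $2.80\ \mu$m.
Under the binary rule the solved field differed from the analytic
solution by 19% in relative $L_2$ on the exterior center line --
independent of the convergence threshold, so a discretisation bias, not
an iteration residual.  Area weighting shrinks the covered-area error
to $\sim10^{-4}$ relative and the worst-case center-line error to
about 1%.

## Blood-smear phantoms

`pack_disks()` generates non-overlapping ensembles by a
Metropolis--Hastings chain: disks are thrown uniformly into the ROI
(overlaps allowed, continuous coordinates), each overlapping pair costs
$V_{ij} = 1000\,k_BT$, and single-disk teleport proposals (uniform
random new position) are accepted when $\Delta E < 0$ or with
probability $e^{-\Delta E}$ otherwise.  Energies are kept in $k_BT$
units since only $\Delta E/k_BT$ enters the rule; no physical
temperature is configurable.  The chain stops when the energy is
*exactly* zero (an integer pair count times $V_{ij}$, so no tolerance
is needed).  Overlap is strict -- tangent disks are legal -- and disks
must lie fully inside the ROI, which is what makes "133 disks of radius
2.75 $\mu$m at 40% of a 50-$\mu$m circle" the canonical smear phantom
(`n_disks_for_fraction()` returns the smallest $N$ with
$N\pi a^2 \ge$ fraction $\times$ ROI area).  Packing is fully
deterministic given the seed; ensembles use seed = base + index.
Fractions above 0.5 warn (random packing of hard disks becomes slow),
and an exhausted proposal budget errors with the remaining energy and
acceptance statistics.

What the generator emulates: spatial randomness of a smear at a given
hematocrit with hard-core exclusion.  What it does not: RBC
aggregation/rouleaux, polydisperse or non-circular cells, periodic
boundaries, 3D stacking.  Tests passing on these phantoms therefore
say nothing about aggregation-dominated blood or about out-of-plane
scattering.

## Frequencies, detectors, experiments

The study band is $f_k = k\,\Delta f$, $\Delta f = 2197/300$ MHz,
$k = 1..300$ (7.3233--2197 MHz), over which the size parameter $k_f a$
of an RBC disk runs from 0.08 to 25.  Spectra are evaluated at a point
detector 51 $\mu$m from the centre, or averaged in magnitude over 200
ring detectors (phase varies with angle for random scenes, so complex
averaging would cancel).  Off-lattice detectors use bilinear
interpolation of the complex field -- the lowest-order scheme
consistent with a pitch far below the wavelength.  "PA spectrum" plots
are magnitude spectra; ensemble statistics are means and standard
deviations of the center-row $|\psi|$ across phantom realizations,
taken over row points outside the ABL and exterior to every disk so
that the DPA (exterior-only) counterpart samples identical locations.

## Choices made where the design was open

- **Interior solution reading.**  The interior disk solution is
  $\psi_s = (A/k_s)[1 + \hat\rho\hat c\,J_0(k_s r)H_1^{(1)}(k_f a)/D]$,
  the unique form continuous with the exterior solution at $r = a$
  (verified numerically to $10^{-9}$ relative).
- **Center row.**  Row $n/2$ in 1-based indexing; for even $n$ its
  $y$-coordinate is $-h/2$, and analytic comparisons evaluate the
  oracle at the true pixel positions including that offset.
- **Frequency grid reconciliation.**  Band statements of "7.3", "7.32"
  and "2197 MHz in steps of 7.3" are reconciled as
  $\Delta f = 2197/300$ MHz exactly.
- **Minimum lattice.**  `sim_grid()` accepts $n \ge 32$ so that
  direct-summation oracle checks (which cost $O(n^4)$) stay feasible;
  physically meaningful runs use $n \ge 512$.
- **Units.**  User-facing lengths in $\mu$m, frequencies in MHz, speeds
  in m/s; converted to SI at operation entry.  $\kappa x$ is evaluated
  with both factors in consistent units (Np/cm against cm).

## Scale of the validation runs

Full-lattice checks in the test suite run on a $512\times512$ grid at
the production pitch with a 128-pixel ABL (same $\kappa$, hence the
same physical taper shape), where single-disk solves converge in
25--100 iterations and the center line matches the analytic oracle to
$\le2\%$ relative $L_2$ at 183/366/732 MHz for all three contrasts.
The convergence-bound check runs at the full production scale
($2048^2$, 2197 MHz, both contrast extremes).  Ensemble demonstrations
use 5 realizations of 4--6 disks; the production-scale ensembles (100
realizations of hundreds of cells) are run through the CLI presets
rather than the test suite.  On a $256^2$ lattice the 6.4-$\mu$m ABL is
too thin at 183 MHz (the artificial attenuation length is 3.3 $\mu$m,
so wrapped energy re-enters); tests at that size use 366 MHz and above.

## Known limitations

- 2D only: disks, not biconcave 3D erythrocytes; uniform illumination
  (per-cell intensities would move the amplitude $A$ inside the DPA
  sum and the source map builder).
- The ABL consumes 500 pixels per side of the production lattice,
  shrinking the usable ROI to 104.8 $\mu$m; detector radii beyond
  ~51 $\mu$m need a larger lattice.
- Interior media are lossless (real wavenumbers); no acoustic
  absorption inside cells, no detector bandwidth/directivity/noise.
- Iteration counts near sharp interior resonances depend on the
  residual $O((h/4)^2)$ area error of rasterised disks; exact
  per-frequency counts are reproducible only to a few iterations.

## A minimal session

```{r example, eval = FALSE}
med <- acoustic_medium(vf = 1500, vs = 1950)
sol <- solve_cbs(disk(), med, optical_params(), f = 183,
                 grid = sim_grid(512), config = cbs_config(abl_d = 128))
compare_cbs_analytic(sol, list(disks = disk(), medium = med))

tr <- pack_disks(roi_spec("circle", 50), packing_config(133, seed = 1))
spec <- frequency_sweep(list(disks = tr$disks, medium = med),
                        frequency_grid(), "dpa",
                        detector_set("ring", radius = 51, count = 200))
head(average_spectrum(spec))
```
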