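# nsphere

Analytical EEG forward solutions — potentials and lead fields of radial
current dipoles — in volume conductors made of an **arbitrary number of
concentric, homogeneous, isotropic spherical shells**.

## Who this is for

The concentric-spheres head model is the workhorse of cheap EEG forward
modeling: exact on spherical geometry, fast enough for iterative source
reconstruction, and the standard reference for validating numerical (BEM/FEM)
solvers. The literature, however, offers several superficially incompatible
formulations of its solution, historically hard-wired to three or four
shells. This package implements a single per-degree recursion that works for
any number of shells, plus the historical formulations as built-in
cross-validation oracles, so every number it produces can be checked against
independently derived paths.

## The model

For a radial dipole of moment $P$ (A·m) at radius $r_0$ inside shell 1, the
potential at radius $r$ and polar angle $\theta$ from the dipole axis, in
shell $s$, is the Legendre series

$$\Phi_s = \frac{P}{4\pi\sigma_1 r_0^2}\sum_{l=1}^{L}
\left(\frac{r_0}{R_1}\right)^{l+1}
\left[\tilde A_l^s \left(\frac{r}{R_s}\right)^{l}
    + \tilde B_l^s \left(\frac{R_s}{r}\right)^{l+1}\right] l\,P_l(\cos\theta),$$

with per-degree constants obtained from the boundary conditions by a
backward recursion in $X_l^s = \tilde B_l^s/\tilde A_l^s$:

$$X_l^n = \tfrac{l}{l+1},\qquad
X_l^s = \frac{X_l^n \sigma_r - F}{\sigma_r + F},\qquad
F = \frac{X_l^n t^{2l+1} - X_l^{s+1}}{t^{2l+1} + X_l^{s+1}},$$

$t = R_s/R_{s+1}$, $\sigma_r = \sigma_s/\sigma_{s+1}$, followed by a forward
pass $\tilde A_l^1 = 1/X_l^1,\ \tilde B_l^1 = 1,\ \tilde A_l^s = \tilde
A_l^{s-1}(1+X_l^{s-1})/(t^l + X_l^s t^{-(l+1)})$. The constants depend only
on the conductor, never on the dipole, so lead fields over thousands of
sources cost one constants computation plus cheap series sums. See the
methods vignette (`vignettes/concentric-spheres-methods.Rmd`) for the
numerical design: overflow-safe powers, homogeneous-coordinates handling of
the poles of $X$, truncation policy, and the validation strategy.

## Worked example

```r
library(nsphere)

model <- canonical_model("three-shell-classic")   # brain/skull/scalp
#> Concentric-sphere conductor: 3 shell(s)
#>   R (m):     0.087, 0.092, 0.100
#>   sigma (S/m): 0.333333333, 0.004166667, 0.333333333

hc  <- harmonic_constants(model, L = 100)          # once per head model
dip <- radial_dipole(c(0, 0, 0.07), moment = 1e-8) # 10 nA*m, eccentricity 0.80
surface_potential_profile(model, hc, dip, thetas = c(0, pi/6, pi/3, pi/2, pi))
#>    theta      value degree_used shell
#> 1 0.0000  1.523e-06         100     3
#> 2 0.5236  6.217e-07         100     3
#> 3 1.0470  8.533e-08         100     3
#> 4 1.5710 -1.288e-07         100     3
#> 5 3.1420 -2.695e-07         100     3
```

The scalp potential directly above a 10 nA·m radial source is ~1.5 µV,
decaying and changing sign with angular distance — the familiar dipolar
topography. `value` is in volts; `shell` confirms the evaluation points sit
in the scalp compartment.

```r
ang <- seq(0, 2*pi, length.out = 5)[-5]
arr <- electrode_array(c("Cz","C4","Oz","C3"),
                       0.1 * cbind(sin(c(0, .7, .7, .7)) * cos(ang),
                                   sin(c(0, .7, .7, .7)) * sin(ang),
                                   cos(c(0, .7, .7, .7))))
lf <- radial_leadfield(model, hc, list(src = radial_dipole(c(0, 0, 0.07))),
                       arr, reference = "average")
lf$values          # V per (A*m), average-referenced: columns sum to zero
#>       src
#> Cz  85.57
#> C4 -28.52
#> Oz -28.52
#> C3 -28.52
```

Cross-checking the recursion against the explicit four-sphere constants, the
spatial-filter form, and a first-principles linear-system solve (classic
model padded to 4 shells, 50 angles, eccentricities 0.2–0.95):

```r
cmp <- compare_formulations(split_shell(model, 3, 0.5),
                            eccentricities = c(0.2, 0.5, 0.8, 0.95),
                            thetas = seq(0, pi, length.out = 50), L = 100)
cmp$per_eccentricity
#>         0.20         0.50         0.80         0.95
#> 3.215979e-15 3.920045e-15 4.157283e-15 3.700505e-15
```

All four independent paths agree to ~4×10⁻¹⁵ — double-precision rounding.

## Command line

```sh
inst/exec/nsphere-leadfield \
  --model model.json --dipoles dipoles.csv --electrodes electrodes.csv \
  --degree 100 --reference average --out leadfield.tsv --log run.log
```

`model.json` holds `radii_m` and `conductivities_S_per_m`; the tables use
`x_m,y_m,z_m` columns (plus `moment_Am` for dipoles, `label` for
electrodes). The output TSV carries a `#` provenance header (model hash,
degree, reference) and one row per dipole. Failures exit nonzero and leave
no partial output.

## Scope

Radial dipoles and electric potentials only: tangential moments, MEG,
anisotropic or realistically shaped conductors, and inverse methods are out
of scope. The intended roles are fast spherical lead fields and an exact
reference for validating numerical forward solvers.
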