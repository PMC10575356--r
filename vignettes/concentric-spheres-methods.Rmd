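---
title: "Methods: analytical EEG lead fields in concentric n-sphere conductors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analytical EEG lead fields in concentric n-sphere conductors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`nsphere` computes the electric potential generated by a radial current
dipole inside a volume conductor made of `n` concentric, homogeneous,
isotropic spherical shells surrounded by vacuum — the classical spherical
head model of EEG forward modeling. Shell `s` is bounded outwardly by radius
$R_s$ ($R_1 < \dots < R_n$, meters) and has conductivity $\sigma_s$ (S/m);
the dipole sits at radius $r_0 < R_1$ with signed moment $P$ (A·m) along its
own radius. Because a radial dipole's field is rotationally symmetric about
its axis, the potential at a point $(r, \theta)$ — radius and polar angle
from the dipole axis — is a Legendre series. In shell $s$:

$$\Phi_s(r,\theta) \;=\; \frac{P}{4\pi\sigma_1 r_0^2} \sum_{l=1}^{L}
\left(\frac{r_0}{R_1}\right)^{l+1}
\left[\tilde A_l^s \left(\frac{r}{R_s}\right)^{l} +
      \tilde B_l^s \left(\frac{R_s}{r}\right)^{l+1}\right]
\, l \, P_l(\cos\theta),$$

where $P_l$ is the Legendre polynomial of degree $l$. The sum starts at
$l = 1$: a dipole has no monopole term. The coefficients
$\tilde A_l^s, \tilde B_l^s$ depend only on the geometry and conductivities
— never on the dipole position, which enters solely through the factored
$(r_0/R_1)^{l+1}$ — so they are computed once per head model
(`harmonic_constants()`) and reused for every source and sensor. That
factoring is what makes lead-field assembly cheap.

## The per-degree recursion

Imposing continuity of potential and of $\sigma$-weighted radial current at
every internal boundary, and zero radial current at $R_n$, yields for each
degree a backward recursion in the propagation constant
$X_l^s = \tilde B_l^s / \tilde A_l^s$, the ratio of inward- to
outward-propagating components in shell $s$:

$$X_l^n = \frac{l}{l+1}, \qquad
X_l^s = \frac{X_l^n\,\sigma_r - F}{\sigma_r + F}, \qquad
F = \frac{X_l^n\,t^{2l+1} - X_l^{s+1}}{t^{2l+1} + X_l^{s+1}},$$

with $t = R_s/R_{s+1} \le 1$ and $\sigma_r = \sigma_s/\sigma_{s+1}$. The
inner fraction is deliberately arranged so that only the bounded power
$t^{2l+1} \le 1$ appears; the textbook mixture of $t^l$ and $t^{-(l+1)}$ is
identical in exact arithmetic but overflows for large $l$. Forward over the
shells, with the primary-source normalization $\tilde B_l^1 = 1$:

$$\tilde A_l^1 = \frac{1}{X_l^1}, \qquad
\tilde A_l^s = \tilde A_l^{s-1}\,
\frac{1 + X_l^{s-1}}{t^l + X_l^s\, t^{-(l+1)}}, \qquad
\tilde B_l^s = X_l^s \tilde A_l^s .$$

This formulation works for *any* number of shells; the historical
closed-form solutions for three or four spheres are special cases, and the
package carries them as cross-validation oracles (see below).

### Poles of $X$ and the homogeneous-coordinates evaluation

$X_l^s$ is a ratio, and its denominator — the outward coefficient — crosses
zero for some degrees: below a deep boundary at high degree, $X$
legitimately spans hundreds of orders of magnitude (across a boundary with
*equal* conductivities it scales exactly by $t^{-(2l+1)}$). Evaluated
literally, the recursion then suffers exact catastrophic cancellation: at a
zero-contrast boundary ($\sigma_r = 1$), once $t^{2l+1}$ underflows relative
to $X_l^{s+1}$, $F$ rounds to $-1$ and $\sigma_r + F$ to exactly zero,
producing `Inf`/`NaN`. This is not hypothetical — it is triggered by the
fictitious-boundary invariance check the package itself performs.

The implementation therefore carries each $X_l^s$ as a renormalized
numerator/denominator pair $(p, q)$ and updates the pair with products
grouped by $t^{2l+1}q$ and $p$, so that $\sigma_r = 1$ reduces *exactly* to
$p_s = p_{s+1}(1 + X_l^n)$, $q_s = t^{2l+1} q_{s+1} (1 + X_l^n)$ — no
subtraction at all. $\tilde A$ and $\tilde B$ are then computed from the
same pair, which stays finite where $X$ itself passes through a pole. One
consequence, documented here deliberately: $\tilde B_l^s = X_l^s \tilde
A_l^s$ holds to rounding (tested at $10^{-14}$), not bitwise, because the
two are no longer literally computed as a product.

## Evaluation and numerical choices

* **Units** are SI throughout: meters, S/m, A·m, volts. Mixing mm and m is
  the classic failure mode of head-modeling code; the column names of the
  I/O formats (`x_m`, `moment_Am`, ...) carry the unit as a reminder.
* **Grouping.** The decaying factor $(r_0/R_1)^{l+1}$ is folded into the
  radial powers in the log domain before multiplying by the (growing)
  $\tilde A/\tilde B$, so per-degree summands can neither overflow nor form
  `Inf * 0`. Coefficients are finite in double precision for $L \le 300$ on
  models with $R_s/R_{s+1} \ge 0.5$; this guard is tested, not assumed.
* **Truncation** defaults to $L = 100$, the conventional benchmark degree
  for this model family; it leaves a relative truncation error below
  $10^{-6}$ on the classical model for eccentricities $r_0/R_1 \le 0.95$.
  An adaptive mode stops once the last 5 summands each contribute less than
  $10^{-12}$ relative to the running total; the fixed-$L$ mode remains the
  reproducible default. Where a validation check demands tails below
  $10^{-10}$ (the homogeneous-limit comparison), $L$ is chosen from the
  geometric tail bound beforehand: $L = 300$ at effective ratio $\le 0.79$,
  $L = 700$ at $0.95$.
* **Region of validity.** The series implemented is the $r > r_0$ expansion
  of the source field. Points with $r < r_0$ (only possible inside shell 1)
  are rejected with a classed error rather than silently evaluated wrong;
  EEG sensors always satisfy $r \ge r_0$.
* **Degenerate cases.** A dipole exactly at the center has no defined radial
  direction, so an explicit orientation is required; the potential is then
  the $r_0 \to 0$ limit, in which only the $l = 1$ term survives
  ($(r_0/R_1)^{l+1}/r_0^2$ is finite only there). A field point exactly on a
  boundary belongs to the inner shell; by continuity the value is identical
  either way (tested). $X_l^1 = 0$ would make $\tilde A_l^1$ undefined and
  raises a degenerate-model error.
* **$\theta$ convention.** $\theta$ is the polar angle from the dipole axis
  (the argument of $P_l(\cos\theta)$), computed as a dot product of unit
  vectors; no rotation matrices.

## Built-in cross-validation

Four independent solution paths coexist and are compared in the test suite
and in `compare_formulations()`:

1. the arbitrary-$n$ recursion above (`harmonic_constants()`);
2. the explicit four-sphere constants (`naess_constants()`), the historical
   closed-form chain $U_l, V_l, Y_l, Z_l$ with the dipole position inside
   the coefficients;
3. the spatial-filter form (`yao_filter()`), which pulls $(r_0/r)^{l+1}$
   out of the series and weights the harmonic spectrum by a per-degree
   filter $W_l^s$;
4. a first-principles boundary-condition solver
   (`boundary_system_constants()`): one dense LU solve per degree of the
   continuity equations, written in per-shell scaled bases
   ($u_s = (r/R_s)^l$, $v_s = (R_{s-1}/r)^{l+1}$) so every matrix entry is
   bounded by $l + 1$ and the solve stays well conditioned at $l = 100$
   even for extreme random geometries. This is the package's independent
   gold standard; the closed formula historically used in that role is not
   publicly available.

On the classical brain/skull/scalp model ($\sigma = 1/3, 1/240, 1/3$ S/m)
and on hundreds of randomized 4-shell models, all paths agree to
$\sim 10^{-14}$ in sup-norm relative difference — the software restatement
of the finding that the competing published formulations, once their
transcription errors are fixed, describe the same physics to
double-precision rounding.

**Disagreement metric.** Agreement is measured as
$\max_\theta |a - b| \,/\, \max_\theta |a|$ per eccentricity. A pointwise
relative difference is ill-posed wherever the potential profile crosses
zero; normalizing by the profile's own scale keeps the metric meaningful at
every angle while still demanding near machine-precision agreement.

## What the random-model generator emulates — and what it does not

`random_model()` draws boundary radii uniform-increasing on
$[0.05, 0.11]$ m (head-sized geometry) and conductivities log-uniform on
$[10^{-3}, 1]$ S/m, independently per shell. The conductivity range spans
realistic tissue values from compact bone to CSF and deliberately stresses
the recursion with up to $10^3$ contrast across one boundary. It does
**not** emulate realistic tissue *ordering* (no constraint that a
low-conductivity skull lies between conductive brain and scalp), anisotropy,
non-concentric geometry, or realistic head shape. A green cross-validation
test on these models therefore establishes numerical correctness of the
series solution on spherical conductors — not fidelity of any sphere model
to a real head, which is a modeling question outside this package's scope.

## Lead fields and referencing

`radial_leadfield()` assembles the electrodes × dipoles matrix of potential
per unit moment (V per A·m). Electrodes must lie within 1% of $R_n$ and are
projected radially onto the surface; anything farther off is refused as a
coregistration error rather than silently moved. The raw series is
referenced to zero at infinity (the default); the common EEG average
reference is available as a pure post-hoc linear map that makes every
column zero-mean. Only radial dipole moments are supported — that is the
scope of the axially symmetric expansion — and dipole tables carrying
orientation columns are refused with an explanation rather than projected.

## Known limitations

* Tangential dipole components (and hence full 3-D moment vectors and MEG)
  are out of scope; they require the order-1 associated Legendre machinery.
* Anisotropic or non-concentric conductors and realistic (BEM/FEM) geometry
  are out of scope; the package is intended as an exact reference on
  spherical geometry, e.g. for validating numerical solvers.
* The $r < r_0$ branch of the expansion is intentionally not implemented.
* Published wall-clock timing comparisons are hardware-dependent and are
  not reproduced.
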