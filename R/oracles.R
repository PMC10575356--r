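#' Explicit four-sphere expansion constants
#'
#' The historical explicit solution for a four-shell conductor: per-degree
#' constants `U_l`, `V_l`, `Y_l`, `Z_l` (and the cleaned-up variant
#' `Z._l`, written `Z_dot`), followed by the shell coefficients `A_l^s`,
#' `B_l^s` in the normalization of the factored series (the dipole position
#' enters through `(r0/R1)^(l+1)`). Used here as a cross-validation oracle
#' for the arbitrary-`n` recursion; it is only defined for exactly four
#' shells.
#'
#' @param model A 4-shell [sphere_model()].
#' @param r0 Dipole radial distance, `0 < r0 < R_1` (meters).
#' @param L Maximum Legendre degree.
#' @return A list with vectors `U`, `V`, `Y`, `Z`, `Z_dot` (length `L`) and
#'   matrices `A`, `B` (`L x 4`), plus `model`, `r0`, `L`.
#' @export
naess_constants <- function(model, r0, L) {
  validate_model(model)
  if (model$n != 4L) {
    nsph_error("nsphere_arity_error",
               sprintf("the explicit four-sphere constants need exactly 4 shells (got %d)",
                       model$n))
  }
  if (!is_finite_num(r0) || length(r0) != 1L || r0 <= 0 || r0 >= model$radii[1]) {
    nsph_error("nsphere_domain_error", "need 0 < r0 < R1")
  }
  L <- as.integer(L)
  l <- seq_len(L)
  R <- model$radii
  sg <- model$conductivities
  U <- l / (l + 1)

  # V_l, verbatim historical form (R3/R4 powers appear with both signs; fine
  # in double precision for the degrees this oracle is used at).
  t <- R[3] / R[4]
  fr <- (t^l - t^(-(l + 1))) / ((1 / U) * t^l + t^(-(l + 1)))
  V <- (U * sg[3] / sg[4] - fr) / (sg[3] / sg[4] + fr)

  # Y_l in the cleaned-up restatement (the raw form duplicates sub-expressions).
  t <- R[2] / R[3]
  fr <- (U * t^l - V * t^(-(l + 1))) / (t^l + V * t^(-(l + 1)))
  Y <- (U * sg[2] / sg[3] - fr) / (sg[2] / sg[3] + fr)

  t <- R[1] / R[2]
  Z <- (t^l - (1 / U) * Y * t^(-(l + 1))) / (t^l + Y * t^(-(l + 1)))
  fr <- (U * t^l - Y * t^(-(l + 1))) / (t^l + Y * t^(-(l + 1)))
  Z_dot <- (U * sg[1] / sg[2] - fr) / (sg[1] / sg[2] + fr)

  f <- (r0 / R[1])^(l + 1)
  A <- matrix(NA_real_, L, 4)
  B <- matrix(NA_real_, L, 4)
  # note: the (l+1)/l factor sits inside the numerator, not in front of the
  # whole ratio -- only this grouping is consistent with A~_l^1 = 1/Z._l
  A[, 1] <- ((1 / U) * sg[1] / sg[2] + Z) / (sg[1] / sg[2] - Z) * f
  B[, 1] <- f
  t <- R[1] / R[2]
  A[, 2] <- (A[, 1] + f) / (t^l + Y * t^(-(l + 1)))
  B[, 2] <- Y * A[, 2]
  t <- R[2] / R[3]
  A[, 3] <- (A[, 2] + B[, 2]) / (t^l + V * t^(-(l + 1)))
  B[, 3] <- V * A[, 3]
  t <- R[3] / R[4]
  A[, 4] <- (A[, 3] + B[, 3]) / (t^l + U * t^(-(l + 1)))
  B[, 4] <- U * A[, 4]

  list(U = U, V = V, Y = Y, Z = Z, Z_dot = Z_dot, A = A, B = B,
       model = model, r0 = r0, L = L)
}

#' Potential via the explicit four-sphere constants
#'
#' Independent evaluation path: sums the series directly from the
#' [naess_constants()] coefficients (which carry the dipole position),
#' without the factored `A~`/`B~` machinery.
#'
#' @param model A 4-shell [sphere_model()].
#' @param dipole A [radial_dipole()] with `r0 > 0`.
#' @param r Evaluation radii (meters), `r0 <= r <= R_4`.
#' @param costheta Cosines of the polar angle from the dipole axis, same
#'   length as `r`.
#' @param L Maximum Legendre degree.
#' @return Numeric vector of potentials (volts).
#' @export
naess_potential <- function(model, dipole, r, costheta, L = 100) {
  check_dipole_in_model(dipole, model)
  nc <- naess_constants(model, dipole$r0, L)
  l <- seq_len(L)
  shell <- locate_shell(model, r)
  r <- pmin(r, model$radii[model$n])
  Pl <- legendre_matrix(pmin(1, pmax(-1, costheta)), L)
  pref <- dipole$moment / (4 * pi * model$conductivities[1] * dipole$r0^2)
  vals <- numeric(length(r))
  for (s in unique(shell)) {
    idx <- which(shell == s)
    Rs <- model$radii[s]
    ra <- exp(outer(l, log(r[idx] / Rs)))
    rb <- exp(outer(l + 1, log(Rs / r[idx])))
    terms <- (nc$A[, s] * ra + nc$B[, s] * rb) * (l * Pl[, idx, drop = FALSE])
    vals[idx] <- pref * colSums(terms)
  }
  vals
}

#' Spatial-filter weight of the harmonic spectrum
#'
#' The per-degree spatial-filter weight `W_l^s` of the conductor: the factor
#' multiplying `(r0/r)^(l+1) l P_l(cos(theta))` in the potential when the
#' source-distance factor is pulled out of the series,
#' \deqn{W_l^s = \tilde A_l^s \frac{r^{2l+1}}{R_1^{l+1} R_s^l} +
#'               \tilde B_l^s \frac{R_s^{l+1}}{R_1^{l+1}}.}
#' Both groupings of the identity are available: `"coefficients"` uses
#' `A~` and `B~` separately, `"filter"` substitutes `B~ = X A~`. They are
#' algebraically identical; computing both is the numerical check that the
#' identity holds.
#'
#' @param constants A `harmonic_constants` object.
#' @param model The matching [sphere_model()].
#' @param r Evaluation radius (meters); must lie in shell `s`.
#' @param l Degree (scalar or vector).
#' @param s Shell index; defaults to `locate_shell(model, r)`.
#' @param form `"coefficients"` or `"filter"` (see above).
#' @return Numeric filter weight(s), one per degree in `l`.
#' @export
yao_filter <- function(constants, model, r, l, s = NULL,
                       form = c("coefficients", "filter")) {
  form <- match.arg(form)
  if (length(r) != 1L) {
    nsph_error("nsphere_argument_error", "r must be a single radius")
  }
  s_auto <- locate_shell(model, r)
  if (is.null(s)) {
    s <- s_auto
  } else if (s != s_auto &&
             !(s >= 2 && abs(r - model$radii[s - 1]) <= 1e-12 * model$radii[s - 1])) {
    nsph_error("nsphere_domain_error",
               sprintf("radius %g m lies in shell %d, not shell %d", r, s_auto, s))
  }
  R1 <- model$radii[1]
  Rs <- model$radii[s]
  A <- constants$A_tilde[l, s]
  # powers grouped as bounded ratios so the weight stays finite at large l
  pa <- (r / R1)^(l + 1) * (r / Rs)^l
  pb <- (Rs / R1)^(l + 1)
  if (form == "coefficients") {
    A * pa + constants$B_tilde[l, s] * pb
  } else {
    A * (pa + constants$X[l, s] * pb)
  }
}

#' Potential via the spatial-filter formulation
#'
#' Independent evaluation path: reconstructs the potential as
#' \deqn{\Phi = \frac{P}{4\pi\sigma_1 r_0^2}\sum_l
#'   \left(\frac{r_0}{r}\right)^{l+1} W_l^s\, l\, P_l(\cos\theta).}
#'
#' @inheritParams naess_potential
#' @param constants A `harmonic_constants` object for `model`.
#' @export
yao_potential <- function(model, constants, dipole, r, costheta) {
  check_dipole_in_model(dipole, model)
  L <- constants$L
  l <- seq_len(L)
  shell <- locate_shell(model, r)
  r <- pmin(r, model$radii[model$n])
  Pl <- legendre_matrix(pmin(1, pmax(-1, costheta)), L)
  pref <- dipole$moment / (4 * pi * model$conductivities[1] * dipole$r0^2)
  vals <- numeric(length(r))
  for (k in seq_along(r)) {
    W <- yao_filter(constants, model, r[k], l, s = shell[k])
    src <- exp((l + 1) * log(dipole$r0 / r[k]))
    vals[k] <- pref * sum(src * W * l * Pl[, k])
  }
  vals
}

#' Closed-form potential of a homogeneous sphere
#'
#' Analytic surface potential of a radial dipole inside a single homogeneous
#' sphere, obtained by summing the series with the generating function of the
#' Legendre polynomials:
#' \deqn{\Phi = \frac{P}{4\pi\sigma r_0 R}\left[
#'   \frac{1 - f^2}{(1 - 2 f\cos\theta + f^2)^{3/2}} - 1\right],\quad
#'   f = r_0 / R.}
#' (With surface weight `(2l+1)/l` per degree, the series is
#' `sum_l (2l+1) f^(l+1) P_l`; `sum f^l P_l = g = (1-2fx+f^2)^(-1/2)` and
#' `sum l f^(l-1) P_l = dg/df = (x-f) g^3` give `f[(1-f^2) g^3 - 1]`.)
#'
#' @param sigma Conductivity (S/m).
#' @param R Sphere radius (meters).
#' @param r0 Dipole radial distance, `0 < r0 < R`.
#' @param theta Polar angle(s) from the dipole axis (radians).
#' @param P Dipole moment (A*m). Default 1.
#' @return Potential(s) in volts, one per angle.
#' @export
homogeneous_closed_form <- function(sigma, R, r0, theta, P = 1) {
  if (!is_finite_num(r0) || r0 <= 0 || r0 >= R) {
    nsph_error("nsphere_domain_error", "need 0 < r0 < R")
  }
  f <- r0 / R
  x <- cos(theta)
  g2 <- 1 - 2 * f * x + f^2
  P / (4 * pi * sigma * r0 * R) * ((1 - f^2) / g2^1.5 - 1)
}

# --- first-principles boundary-condition solver (independent gold standard) --

# Per-degree dense solve in per-shell scaled bases: in shell s the potential
# is a1*(r/R1)^l + (r0/r)^(l+1) for s = 1 and a_s*(r/R_s)^l +
# b_s*(R_{s-1}/r)^(l+1) for s >= 2, so every matrix entry is bounded by
# (l+1) and the LU solve stays well-conditioned at large degrees even for
# extreme shell geometries. Solves with unit source scale ((r0/R1)^(l+1)
# factored out), i.e. directly in the A~/B~ normalization.
solve_degree_tilde <- function(model, l) {
  n <- model$n
  R <- model$radii
  sg <- model$conductivities
  idx_a <- function(s) if (s == 1) 1L else 2L * s - 2L
  idx_b <- function(s) 2L * s - 1L
  m <- 2L * n - 1L
  M <- matrix(0, m, m)
  rhs <- numeric(m)
  row <- 0L
  if (n > 1) {
    for (j in seq_len(n - 1)) {
      tin <- if (j >= 2) (R[j - 1] / R[j])^(l + 1) else NA_real_
      tout_l <- (R[j] / R[j + 1])^l
      row <- row + 1L  # potential continuity at R_j
      M[row, idx_a(j)] <- 1
      if (j >= 2) M[row, idx_b(j)] <- tin
      M[row, idx_a(j + 1)] <- -tout_l
      M[row, idx_b(j + 1)] <- -1
      if (j == 1) rhs[row] <- -1
      row <- row + 1L  # sigma-weighted current continuity at R_j
      M[row, idx_a(j)] <- sg[j] * l
      if (j >= 2) M[row, idx_b(j)] <- -sg[j] * (l + 1) * tin
      M[row, idx_a(j + 1)] <- -sg[j + 1] * l * tout_l
      M[row, idx_b(j + 1)] <- sg[j + 1] * (l + 1)
      if (j == 1) rhs[row] <- sg[1] * (l + 1)
    }
  }
  row <- row + 1L  # zero radial current at R_n
  M[row, idx_a(n)] <- l
  if (n >= 2) {
    M[row, idx_b(n)] <- -(l + 1) * (R[n - 1] / R[n])^(l + 1)
  } else {
    rhs[row] <- l + 1  # single shell: the primary term reaches the surface
  }
  x <- solve(M, rhs)
  A <- numeric(n)
  B <- numeric(n)
  A[1] <- x[1]
  B[1] <- 1
  if (n >= 2) {
    for (s in 2:n) {
      A[s] <- x[idx_a(s)]
      B[s] <- x[idx_b(s)] * (R[s - 1] / R[s])^(l + 1)
    }
  }
  list(A = A, B = B, residual = max(abs(M %*% x - rhs)))
}

#' Solve the per-degree boundary-condition linear system
#'
#' Brute-force oracle: for a single degree `l`, sets up and LU-solves the
#' dense linear system expressing continuity of potential and of
#' conductivity-weighted radial current at every internal boundary, plus zero
#' radial current at the outer surface, with the shell-1 inward coefficient
#' fixed by the primary-source expansion (`B_1 = (r0/R1)^(l+1)`). Entirely
#' independent of the iterative recursion.
#'
#' @param model A validated [sphere_model()].
#' @param r0 Dipole radial distance, `0 < r0 < R_1`.
#' @param l Degree, `>= 1`.
#' @return A list with vectors `A`, `B` (length `n`, in the normalization of
#'   the general series where shell `s` combines `(r/R_s)^l` and
#'   `(R_s/r)^(l+1)`) and `residual`, the maximum absolute residual of the
#'   solved system.
#' @export
boundary_system_solve <- function(model, r0, l) {
  validate_model(model)
  if (!is_finite_num(r0) || length(r0) != 1L || r0 <= 0 || r0 >= model$radii[1]) {
    nsph_error("nsphere_domain_error", "need 0 < r0 < R1")
  }
  if (!is.numeric(l) || length(l) != 1L || l < 1) {
    nsph_error("nsphere_argument_error", "l must be a single integer >= 1")
  }
  sol <- tryCatch(solve_degree_tilde(model, as.integer(l)),
                  error = function(e) {
                    nsph_error("nsphere_degenerate_model_error",
                               sprintf("boundary system singular at degree %d: %s",
                                       l, conditionMessage(e)))
                  })
  f <- (r0 / model$radii[1])^(l + 1)
  list(A = sol$A * f, B = sol$B * f, residual = sol$residual)
}

#' Harmonic constants from the boundary-condition solver
#'
#' Runs [boundary_system_solve()] (in its source-independent, tilde
#' normalization) for every degree `1..L` and packages the result as a
#' `harmonic_constants` object, so that the same evaluation front ends
#' ([potential()], [surface_potential_profile()]) can be driven by the
#' independent oracle coefficients.
#'
#' @inheritParams propagation_constants
#' @return A `harmonic_constants` object with attribute `method =
#'   "boundary-system"` and an extra field `residual` (max over degrees).
#' @export
boundary_system_constants <- function(model, L) {
  validate_model(model)
  L <- as.integer(L)
  n <- model$n
  A <- matrix(NA_real_, L, n)
  B <- matrix(NA_real_, L, n)
  resid <- 0
  for (l in seq_len(L)) {
    sol <- solve_degree_tilde(model, l)
    A[l, ] <- sol$A
    B[l, ] <- sol$B
    resid <- max(resid, sol$residual)
  }
  out <- structure(list(model = model, L = L, X = B / A, A_tilde = A,
                        B_tilde = B, residual = resid),
                   class = "harmonic_constants")
  attr(out, "method") <- "boundary-system"
  out
}
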