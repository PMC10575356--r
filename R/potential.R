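#' Legendre polynomial sequence
#'
#' Evaluates `P_0(x) ... P_L(x)` by the three-term (Bonnet) recurrence
#' `(l+1) P_{l+1} = (2l+1) x P_l - l P_{l-1}`, which is numerically stable on
#' the whole domain \[-1, 1\].
#'
#' @param x Abscissa(e) in \[-1, 1\].
#' @param L Maximum degree, `>= 0`.
#' @return For scalar `x`, a numeric vector of length `L + 1` in degree order;
#'   for vector `x`, an `(L + 1) x length(x)` matrix (row `l + 1` holds degree
#'   `l`).
#' @examples
#' legendre_sequence(0.5, 2)  # 1, 0.5, -0.125
#' @export
legendre_sequence <- function(x, L) {
  if (!is_finite_num(x) || any(abs(x) > 1)) {
    nsph_error("nsphere_domain_error", "Legendre abscissa must lie in [-1, 1]")
  }
  if (!is.numeric(L) || length(L) != 1L || L < 0) {
    nsph_error("nsphere_argument_error", "L must be a single integer >= 0")
  }
  L <- as.integer(L)
  scalar <- length(x) == 1L
  P <- matrix(0, nrow = L + 1, ncol = length(x))
  P[1, ] <- 1
  if (L >= 1) P[2, ] <- x
  if (L >= 2) {
    for (l in 1:(L - 1)) {
      P[l + 2, ] <- ((2 * l + 1) * x * P[l + 1, ] - l * P[l, ]) / (l + 1)
    }
  }
  if (scalar) drop(P) else P
}

# Degrees 1..L as an L x npts matrix (drops the monopole row).
legendre_matrix <- function(x, L) {
  P <- legendre_sequence(x, L)
  if (!is.matrix(P)) P <- matrix(P, ncol = 1)
  P[-1, , drop = FALSE]
}

#' Locate the shell containing a radius
#'
#' Returns the smallest shell index `s` with `r <= R_s`. A point exactly on a
#' boundary is assigned to the inner side; by continuity of the potential the
#' value is identical either way. A relative tolerance of `1e-9` absorbs
#' floating-point noise at the outer surface (projected electrodes).
#'
#' @param model A [sphere_model()].
#' @param r Radius or vector of radii (meters), `0 <= r <= R_n`.
#' @return Integer shell indices, same length as `r`.
#' @export
locate_shell <- function(model, r) {
  validate_model(model)
  Rn <- model$radii[model$n]
  if (!is_finite_num(r) || any(r < 0)) {
    nsph_error("nsphere_argument_error", "radii must be finite and >= 0")
  }
  if (any(r > Rn * (1 + 1e-9))) {
    nsph_error("nsphere_outside_conductor_error",
               sprintf("evaluation radius exceeds the outer radius R_n = %g m", Rn))
  }
  s <- rowSums(outer(pmin(r, Rn), model$radii, ">")) + 1L
  as.integer(s)
}

# Core series evaluator on (r, cos(theta)) pairs; all public evaluation paths
# funnel through here. The decaying dipole factor (r0/R1)^(l+1) is folded into
# the radial powers in the log domain before multiplying by the (growing)
# A~/B~ coefficients, so intermediate products can neither overflow nor hit
# Inf * 0.
series_eval <- function(constants, dipole, r, costheta, adaptive = FALSE) {
  model <- constants$model
  check_dipole_in_model(dipole, model)
  L <- constants$L
  l <- seq_len(L)
  if (length(costheta) != length(r)) {
    nsph_error("nsphere_argument_error", "r and costheta lengths differ")
  }
  costheta <- pmin(1, pmax(-1, costheta))
  shell <- locate_shell(model, r)
  r <- pmin(r, model$radii[model$n])
  sigma1 <- model$conductivities[1]
  r0 <- dipole$r0
  P <- dipole$moment
  R1 <- model$radii[1]

  if (any(r < r0 * (1 - 1e-12)) || any(r == 0)) {
    nsph_error("nsphere_unsupported_region_error",
               "evaluation points must satisfy r >= r0 > 0 (the series is the r > r0 expansion of the source field)")
  }

  if (r0 == 0) {
    # r0 -> 0 limit: (r0/R1)^(l+1) / r0^2 is finite only for l = 1.
    Rs <- model$radii[shell]
    val <- P / (4 * pi * sigma1 * R1^2) *
      (constants$A_tilde[1, shell] * (r / Rs) +
         constants$B_tilde[1, shell] * (Rs / r)^2) * costheta
    return(data.frame(value = val, degree_used = 1L, shell = shell))
  }

  pref <- P / (4 * pi * sigma1 * r0^2)
  lf1 <- log(r0 / R1)
  Pl <- legendre_matrix(costheta, L)
  vals <- numeric(length(r))
  deg <- rep.int(L, length(r))
  for (s in unique(shell)) {
    idx <- which(shell == s)
    Rs <- model$radii[s]
    # (r0/R1)^(l+1) * (r/Rs)^l   and   (r0/R1)^(l+1) * (Rs/r)^(l+1)
    MA <- exp(outer(l, log(r[idx] / Rs)) + (l + 1) * lf1)
    MB <- exp(outer(l + 1, log(Rs / r[idx]) + lf1))
    terms <- (constants$A_tilde[, s] * MA + constants$B_tilde[, s] * MB) *
      (l * Pl[, idx, drop = FALSE])
    if (!adaptive) {
      vals[idx] <- pref * colSums(terms)
    } else {
      for (k in seq_along(idx)) {
        tk <- terms[, k]
        tot <- sum(tk)
        scale <- max(abs(tot), max(abs(tk)), .Machine$double.xmin)
        rel <- abs(tk) / scale
        m <- L
        if (L >= 5) {
          ok <- rel < 1e-12
          run <- which(vapply(5:L, function(j) all(ok[(j - 4):j]), logical(1)))
          if (length(run) > 0) m <- (5:L)[run[1]]
        }
        vals[idx[k]] <- pref * sum(tk[seq_len(m)])
        deg[idx[k]] <- m
      }
    }
  }
  data.frame(value = vals, degree_used = deg, shell = shell)
}

#' Electric potential of a radial dipole in an n-sphere conductor
#'
#' Evaluates the Legendre-series potential
#' \deqn{\Phi = \frac{P}{4\pi\sigma_1 r_0^2}\sum_{l=1}^{L}
#'   \left(\frac{r_0}{R_1}\right)^{l+1}
#'   \left[\tilde A_l^s \left(\frac{r}{R_s}\right)^l +
#'         \tilde B_l^s \left(\frac{R_s}{r}\right)^{l+1}\right]
#'   l\, P_l(\cos\theta)}
#' at Cartesian points inside the conductor, where `s` is the shell containing
#' the point and `theta` the polar angle between the point and the dipole
#' axis. Points with `r < r0` (below the source radius, inside shell 1) are
#' rejected: the series implemented is the `r > r0` expansion of the source
#' field, which covers all EEG use cases.
#'
#' @param model A [sphere_model()].
#' @param constants Matching `harmonic_constants` (from [harmonic_constants()]
#'   or [boundary_system_constants()]).
#' @param dipole A [radial_dipole()] strictly inside shell 1.
#' @param points Length-3 vector or `npts x 3` matrix of Cartesian positions
#'   (meters), all with `r0 <= r <= R_n`.
#' @param adaptive If `TRUE`, per point the summation stops once the last 5
#'   summands each contribute less than `1e-12` relative to the total;
#'   `degree_used` records the degree actually used. Default `FALSE`
#'   (reproducible fixed truncation at `L`).
#' @return A data frame with one row per point: `value` (volts),
#'   `degree_used`, `shell`.
#' @export
potential <- function(model, constants, dipole, points, adaptive = FALSE) {
  if (!inherits(constants, "harmonic_constants")) {
    nsph_error("nsphere_argument_error", "constants must be 'harmonic_constants'")
  }
  if (!identical(constants$model$radii, model$radii) ||
      !identical(constants$model$conductivities, model$conductivities)) {
    nsph_error("nsphere_argument_error", "constants were computed for a different model")
  }
  if (is.null(dim(points))) {
    if (length(points) != 3L) {
      nsph_error("nsphere_argument_error", "a point must have 3 Cartesian coordinates")
    }
    points <- matrix(points, ncol = 3)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L || !is_finite_num(points)) {
    nsph_error("nsphere_argument_error", "points must be a finite npts x 3 matrix (m)")
  }
  r <- sqrt(rowSums(points^2))
  costheta <- as.vector(points %*% dipole$axis) / ifelse(r > 0, r, 1)
  series_eval(constants, dipole, r, costheta, adaptive = adaptive)
}

#' Surface potential profile over polar angles
#'
#' Potential on the outer surface `r = R_n` at polar angles `thetas` measured
#' from the dipole axis. Because the radial-dipole field is rotationally
#' symmetric about that axis, `(R_n, theta)` determines the potential
#' completely.
#'
#' @inheritParams potential
#' @param thetas Vector of polar angles in radians.
#' @return A data frame with `theta`, `value` (volts), `degree_used`, `shell`.
#' @export
surface_potential_profile <- function(model, constants, dipole, thetas,
                                      adaptive = FALSE) {
  Rn <- model$radii[model$n]
  res <- series_eval(constants, dipole, rep(Rn, length(thetas)), cos(thetas),
                     adaptive = adaptive)
  cbind(data.frame(theta = as.numeric(thetas)), res)
}
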