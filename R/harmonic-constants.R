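#' Per-degree propagation constants for an n-shell conductor
#'
#' For each Legendre degree `l`, the constant `X_l^s` is the proportionality
#' between the inward- and outward-propagating components of the degree-`l`
#' harmonic in shell `s` (in the per-shell normalization where the potential
#' in shell `s` is a combination of `(r/R_s)^l` and `(R_s/r)^(l+1)`).
#'
#' The outermost shell has the closed value `X_l^n = l/(l+1)` (zero radial
#' current at `R_n`); inner shells follow by a backward recursion over the
#' boundaries. The recursion is evaluated in an overflow-safe arrangement
#' using only the bounded power `(R_s/R_{s+1})^(2l+1) <= 1`:
#' \deqn{F = \frac{X_l^n t^{2l+1} - X_l^{s+1}}{t^{2l+1} + X_l^{s+1}}, \qquad
#'       X_l^s = \frac{X_l^n \sigma_s/\sigma_{s+1} - F}
#'                    {\sigma_s/\sigma_{s+1} + F}}
#' with \eqn{t = R_s/R_{s+1}}. In exact arithmetic this is identical to the
#' textbook form mixing \eqn{t^l} and \eqn{t^{-(l+1)}}, but it stays finite
#' for large `l`.
#'
#' Below a deep boundary at high degree, `X_l^s` legitimately spans many
#' orders of magnitude (across a zero-contrast boundary it scales exactly by
#' `t^-(2l+1)`), and the plain ratio update can suffer catastrophic
#' cancellation in `sigma_s/sigma_{s+1} + F`. The recursion is therefore
#' carried in homogeneous coordinates: `X_l^s = p/q` with
#' \deqn{p_s = t^{2l+1} q_{s+1} X_l^n (\sigma_r - 1)
#'             + p_{s+1} (X_l^n \sigma_r + 1), \quad
#'       q_s = t^{2l+1} q_{s+1} (\sigma_r + X_l^n)
#'             + p_{s+1} (\sigma_r - 1),}
#' (\eqn{\sigma_r = \sigma_s/\sigma_{s+1}}), renormalized per step. For equal
#' conductivities this reduces exactly to
#' `p_s = p_{s+1}(1 + X_l^n)`, `q_s = t^{2l+1} q_{s+1} (1 + X_l^n)` — no
#' cancellation at fictitious boundaries. The pair is attached to the
#' returned matrix as attributes `num` and `den` (consumed by
#' [expansion_coefficients()]; the plain ratio is what the matrix holds).
#'
#' @param model A validated [sphere_model()].
#' @param L Maximum Legendre degree, `>= 1`. Degrees are indexed `1..L` (the
#'   `l = 0` monopole term is absent for a dipole source).
#' @return A numeric `L x n` matrix; row `l`, column `s` holds `X_l^s`
#'   (possibly very large below deep boundaries at high degree), with
#'   attributes `num` and `den` holding the homogeneous pair.
#' @export
propagation_constants <- function(model, L) {
  validate_model(model)
  if (!is.numeric(L) || length(L) != 1L || L < 1) {
    nsph_error("nsphere_argument_error", "L must be a single integer >= 1")
  }
  L <- as.integer(L)
  l <- seq_len(L)
  U <- l / (l + 1)
  n <- model$n
  P <- matrix(NA_real_, nrow = L, ncol = n)
  Q <- matrix(NA_real_, nrow = L, ncol = n)
  P[, n] <- l / (l + 1)
  Q[, n] <- 1
  if (n > 1) {
    for (s in (n - 1):1) {
      t2 <- (model$radii[s] / model$radii[s + 1])^(2 * l + 1)
      sr <- model$conductivities[s] / model$conductivities[s + 1]
      # grouped by t2*Q and P so that a zero-contrast boundary (sr == 1)
      # reduces exactly to p = P (1 + U), q = t2 Q (1 + U): naively forming
      # the continuity/current combinations first absorbs the tiny t2 term
      # and cancels q to 0 at high degree
      tQ <- t2 * Q[, s + 1]
      d <- sr - 1
      p <- tQ * (U * d) + P[, s + 1] * (U * sr + 1)
      q <- tQ * (sr + U) + P[, s + 1] * d
      nrm <- pmax(abs(p), abs(q))
      P[, s] <- p / nrm
      Q[, s] <- q / nrm
    }
  }
  structure(P / Q, num = P, den = Q)
}

#' Expansion coefficients from the propagation constants
#'
#' Builds the dipole-position-independent coefficients `A~_l^s` and `B~_l^s`
#' of the factored Legendre series. `A~_l^1 = 1/X_l^1` (the primary-source
#' normalization fixes `B~_l^1 = 1`), outward shells follow the forward
#' recursion
#' \deqn{\tilde A_l^s = \tilde A_l^{s-1}
#'       \frac{1 + X_l^{s-1}}{t^l + X_l^s\, t^{-(l+1)}}, \qquad
#'       t = R_{s-1}/R_s,}
#' and `B~_l^s = X_l^s A~_l^s` by definition. The coefficients grow with `l`
#' (they are compensated by the decaying dipole factor `(r0/R1)^(l+1)` at
#' evaluation time); they are finite in double precision for `L <= 300` on
#' models with radius ratios `R_s/R_{s+1} >= 0.5`.
#'
#' When `X` carries the homogeneous `num`/`den` attributes from
#' [propagation_constants()], the update is evaluated as
#' `A~_s = q S / (q t^l + p t^-(l+1))`, `B~_s = p S / (q t^l + p t^-(l+1))`
#' with `S = A~_{s-1} + B~_{s-1}`, which stays finite where `X` itself passes
#' through a pole (a legitimate zero of the outward coefficient). The
#' proportionality `B~ = X A~` then holds to rounding rather than bitwise.
#'
#' @param model The [sphere_model()] the constants belong to.
#' @param X `L x n` matrix from [propagation_constants()] for the same model
#'   (a plain matrix is also accepted).
#' @param L Maximum degree; must match `nrow(X)`.
#' @return An object of class `harmonic_constants`: a list with `model`, `L`,
#'   `X`, `A_tilde`, `B_tilde` (all matrices `L x n`).
#' @export
expansion_coefficients <- function(model, X, L) {
  validate_model(model)
  L <- as.integer(L)
  if (!is.matrix(X) || nrow(X) != L || ncol(X) != model$n) {
    nsph_error("nsphere_argument_error", "X must be an L x n matrix for this model")
  }
  P <- attr(X, "num")
  Q <- attr(X, "den")
  if (is.null(P) || is.null(Q)) {
    P <- unclass(X)
    attributes(P) <- list(dim = dim(X))
    Q <- matrix(1, L, model$n)
  }
  # X_l^1 = 0 (p = 0) makes A~^1 = 1/X^1 undefined; a pole of X_l^1 (q = 0)
  # is fine in the homogeneous form (A~^1 = 0, B~^1 = 1)
  if (any(P[, 1] == 0) || any(!is.finite(P[, 1])) || any(!is.finite(Q[, 1]))) {
    nsph_error("nsphere_degenerate_model_error",
               "X_l^1 is zero or undefined for some degree: expansion coefficients are undefined")
  }
  l <- seq_len(L)
  n <- model$n
  A <- matrix(NA_real_, nrow = L, ncol = n)
  B <- matrix(NA_real_, nrow = L, ncol = n)
  A[, 1] <- Q[, 1] / P[, 1]
  B[, 1] <- 1  # primary-source normalization
  if (n > 1) {
    for (s in 2:n) {
      t <- model$radii[s - 1] / model$radii[s]
      S <- A[, s - 1] + B[, s - 1]
      d <- Q[, s] * t^l + P[, s] * t^(-(l + 1))
      A[, s] <- Q[, s] * S / d
      B[, s] <- P[, s] * S / d
    }
  }
  structure(list(model = model, L = L, X = X, A_tilde = A, B_tilde = B),
            class = "harmonic_constants")
}

#' Harmonic constants for a model
#'
#' Convenience wrapper computing [propagation_constants()] and
#' [expansion_coefficients()] in one call. The result depends only on the
#' model and `L` — never on the dipole position — so it can be computed once
#' per head model and reused for every source and evaluation point.
#'
#' @inheritParams propagation_constants
#' @return A `harmonic_constants` object.
#' @examples
#' hc <- harmonic_constants(canonical_model("three-shell-classic"), L = 100)
#' hc$X[1, ]  # degree-1 propagation constants per shell
#' @export
harmonic_constants <- function(model, L = 100) {
  expansion_coefficients(model, propagation_constants(model, L), L)
}

#' @export
print.harmonic_constants <- function(x, ...) {
  cat(sprintf("Harmonic constants: L = %d, n = %d shell(s)\n", x$L, x$model$n))
  cat(sprintf("  X[1, ] = %s\n", paste(format(x$X[1, ], digits = 6), collapse = ", ")))
  invisible(x)
}

#' Per-degree boundary-condition residuals
#'
#' For every degree and every internal boundary, measures the relative
#' discontinuity of the degree-`l` potential term and of the
#' conductivity-weighted radial current across the boundary, plus the
#' outward current at the outer surface (which must vanish). All residuals
#' are relative to the magnitude of the quantities involved; they quantify
#' how well the computed coefficients satisfy the physics they encode.
#'
#' @param constants A `harmonic_constants` object.
#' @return A list with matrices `potential` and `current`
#'   (`L x (n-1)`, zero-column when `n = 1`) and vector `outer` (length `L`).
#' @export
boundary_residuals <- function(constants) {
  model <- constants$model
  L <- constants$L
  l <- seq_len(L)
  n <- model$n
  A <- constants$A_tilde
  B <- constants$B_tilde
  pot <- matrix(0, L, max(n - 1, 0))
  cur <- matrix(0, L, max(n - 1, 0))
  if (n > 1) {
    for (s in seq_len(n - 1)) {
      t <- model$radii[s] / model$radii[s + 1]
      # value and r * d/dr of the degree-l term, evaluated at r = R_s,
      # from the shell-s side (its own normalization radius is R_s) ...
      in_val <- A[, s] + B[, s]
      in_cur <- model$conductivities[s] * (l * A[, s] - (l + 1) * B[, s])
      # ... and from the shell-(s+1) side (normalization radius R_{s+1})
      out_val <- A[, s + 1] * t^l + B[, s + 1] * t^(-(l + 1))
      out_cur <- model$conductivities[s + 1] *
        (l * A[, s + 1] * t^l - (l + 1) * B[, s + 1] * t^(-(l + 1)))
      pot[, s] <- abs(in_val - out_val) / pmax(abs(in_val), abs(out_val))
      cur[, s] <- abs(in_cur - out_cur) /
        pmax(abs(in_cur), abs(out_cur),
             model$conductivities[s] * (l * abs(A[, s]) + (l + 1) * abs(B[, s])))
    }
  }
  outer_res <- abs(l * A[, n] - (l + 1) * B[, n]) /
    pmax(l * abs(A[, n]), (l + 1) * abs(B[, n]))
  list(potential = pot, current = cur, outer = outer_res)
}

#' Dump harmonic constants as TSV (debugging aid)
#'
#' Writes one row per (degree, shell) pair with columns
#' `l`, `s`, `X`, `A_tilde`, `B_tilde`.
#'
#' @param constants A `harmonic_constants` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_constants_tsv <- function(constants, path) {
  L <- constants$L
  n <- constants$model$n
  tab <- data.frame(
    l = rep(seq_len(L), times = n),
    s = rep(seq_len(n), each = L),
    X = as.vector(constants$X),
    A_tilde = as.vector(constants$A_tilde),
    B_tilde = as.vector(constants$B_tilde)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
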