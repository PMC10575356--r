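#' Cross-validate the solution paths on surface potentials
#'
#' Evaluates surface potential profiles for dipoles at the given
#' eccentricities with up to four independent formulations — the arbitrary-n
#' recursion (`"recursion"`), the explicit four-sphere constants (`"naess"`,
#' 4-shell models only), the spatial-filter path (`"yao"`), and the
#' boundary-condition linear-system solver (`"solver"`) — and reports their
#' worst disagreement.
#'
#' The disagreement metric is the sup-norm ratio per eccentricity:
#' `max over angles and method pairs |a - b| / max over angles |a|`. A
#' pointwise relative difference is ill-posed wherever the potential profile
#' crosses zero; normalizing by the profile's own scale keeps the metric
#' meaningful at every angle while still demanding near machine-precision
#' agreement.
#'
#' @param model A [sphere_model()].
#' @param eccentricities Dipole radial positions as fractions of `R_1`, each
#'   in `[0, 1)` (0 excluded here since the explicit oracle needs `r0 > 0`).
#' @param thetas Polar angles (radians) for the surface grid.
#' @param L Truncation degree (default 100).
#' @param methods Subset of `c("recursion", "naess", "yao", "solver")`.
#' @return A list with `values` (named list of angle x eccentricity
#'   matrices, one per method), `max_rel_diff` (worst sup-norm disagreement
#'   over all pairs and eccentricities) and `per_eccentricity` (vector of
#'   the same metric per eccentricity).
#' @export
compare_formulations <- function(model, eccentricities, thetas, L = 100,
                                 methods = c("recursion", "naess", "yao", "solver")) {
  validate_model(model)
  methods <- match.arg(methods, several.ok = TRUE)
  if ("naess" %in% methods && model$n != 4L) {
    nsph_error("nsphere_arity_error",
               "the 'naess' path needs a 4-shell model; pad with split_shell()")
  }
  if (any(eccentricities <= 0) || any(eccentricities >= 1)) {
    nsph_error("nsphere_argument_error", "eccentricities must lie in (0, 1)")
  }
  Rn <- model$radii[model$n]
  ct <- cos(thetas)
  hc <- if (any(c("recursion", "yao") %in% methods)) harmonic_constants(model, L)
  bc <- if ("solver" %in% methods) boundary_system_constants(model, L)

  values <- lapply(stats::setNames(methods, methods), function(m) {
    matrix(NA_real_, nrow = length(thetas), ncol = length(eccentricities))
  })
  for (j in seq_along(eccentricities)) {
    dip <- radial_dipole(c(0, 0, eccentricities[j] * model$radii[1]))
    rr <- rep(Rn, length(thetas))
    for (m in methods) {
      values[[m]][, j] <- switch(
        m,
        recursion = series_eval(hc, dip, rr, ct)$value,
        solver = series_eval(bc, dip, rr, ct)$value,
        naess = naess_potential(model, dip, rr, ct, L = L),
        yao = yao_potential(model, hc, dip, rr, ct)
      )
    }
  }
  per_ecc <- vapply(seq_along(eccentricities), function(j) {
    cols <- vapply(methods, function(m) values[[m]][, j], numeric(length(thetas)))
    scale <- max(abs(cols))
    worst <- 0
    for (a in seq_along(methods)) {
      for (b in seq_len(a - 1)) {
        worst <- max(worst, max(abs(cols[, a] - cols[, b])))
      }
    }
    worst / scale
  }, numeric(1))
  list(values = values,
       per_eccentricity = stats::setNames(per_ecc, format(eccentricities)),
       max_rel_diff = max(per_ecc))
}
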