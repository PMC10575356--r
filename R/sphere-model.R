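#' Concentric-sphere volume-conductor model
#'
#' A head (or generic volume-conductor) model made of `n` concentric,
#' homogeneous, isotropic spherical shells. Shell `s` is bounded outwardly by
#' radius `R_s`; radii are strictly increasing. The conductivity of shell `s`
#' is `sigma_s` (S/m). The exterior beyond `R_n` is vacuum (zero conductivity)
#' and is never stored.
#'
#' @param radii Numeric vector of boundary radii in meters, strictly
#'   increasing, all positive. `radii[1]` bounds the innermost shell, where
#'   sources live.
#' @param conductivities Numeric vector of shell conductivities in S/m, same
#'   length as `radii`, all positive and finite.
#' @return An object of class `sphere_model` with fields `radii`,
#'   `conductivities` and `n`.
#' @examples
#' sphere_model(c(0.087, 0.092, 0.100), c(1/3, 1/240, 1/3))
#' @seealso [canonical_model()], [random_model()], [split_shell()]
#' @export
sphere_model <- function(radii, conductivities) {
  model <- structure(
    list(
      radii = as.numeric(radii),
      conductivities = as.numeric(conductivities),
      n = length(radii)
    ),
    class = "sphere_model"
  )
  validate_model(model)
}

#' Validate a sphere model
#'
#' Checks the `sphere_model` invariants: at least one shell, strictly
#' increasing positive radii, positive finite conductivities, matching
#' lengths. Idempotent; returns its input unchanged when valid.
#'
#' @param model A candidate [sphere_model()].
#' @return The validated model, invisibly unchanged.
#' @export
validate_model <- function(model) {
  if (!inherits(model, "sphere_model")) {
    nsph_error("nsphere_argument_error", "not a 'sphere_model' object")
  }
  r <- model$radii
  s <- model$conductivities
  if (length(r) < 1L || length(s) < 1L) {
    nsph_error("nsphere_empty_model_error", "model must have at least one shell")
  }
  if (length(r) != length(s) || model$n != length(r)) {
    nsph_error("nsphere_argument_error",
               "radii and conductivities must have the same length")
  }
  if (!is_finite_num(r) || any(r <= 0) || any(diff(r) <= 0)) {
    nsph_error("nsphere_geometry_error",
               "radii must be finite, positive and strictly increasing (meters)")
  }
  if (!is_finite_num(s) || any(s <= 0)) {
    nsph_error("nsphere_conductivity_error",
               "conductivities must be finite and strictly positive (S/m)")
  }
  model
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("Concentric-sphere conductor: %d shell(s)\n", x$n))
  cat(sprintf("  R (m):     %s\n", paste(format(x$radii), collapse = ", ")))
  cat(sprintf("  sigma (S/m): %s\n", paste(format(x$conductivities), collapse = ", ")))
  invisible(x)
}

# Registry of named models. The classical brain/skull/scalp conductivities are
# 1/3, 1/(3*80), 1/3 S/m; radii follow the common scalp-model convention (the
# choice of radii is a package default, not a literature-prescribed value).
.model_registry <- list(
  "three-shell-classic" = list(radii = c(0.087, 0.092, 0.100),
                               conductivities = c(1/3, 1/(3 * 80), 1/3)),
  "single-shell" = list(radii = 0.100, conductivities = 1/3)
)

#' Canonical named sphere models
#'
#' Fixed registry of conventional models. `"three-shell-classic"` is the
#' classical brain/skull/scalp model with conductivities 1/3, 1/240 and 1/3
#' S/m and radii 0.087, 0.092 and 0.100 m; `"single-shell"` is a homogeneous
#' sphere of radius 0.1 m and conductivity 1/3 S/m.
#'
#' @param name Model name; one of `names(nsphere:::.model_registry)`.
#' @return A validated [sphere_model()].
#' @examples
#' canonical_model("three-shell-classic")
#' @export
canonical_model <- function(name = "three-shell-classic") {
  entry <- .model_registry[[name]]
  if (is.null(entry)) {
    nsph_error("nsphere_registry_error",
               sprintf("unknown canonical model '%s' (available: %s)",
                       name, paste(names(.model_registry), collapse = ", ")))
  }
  sphere_model(entry$radii, entry$conductivities)
}

#' Seeded random sphere models
#'
#' Draws a reproducible random conductor for stress testing: `n_shells`
#' boundary radii uniform on \[0.05, 0.11\] m (sorted increasing) and shell
#' conductivities log-uniform on \[1e-3, 1\] S/m, independently per shell.
#' The global RNG state is restored on exit.
#'
#' @param n_shells Number of shells, at least 1.
#' @param seed Integer seed; the same seed always yields the same model.
#' @return A validated [sphere_model()].
#' @export
random_model <- function(n_shells, seed) {
  if (!is.numeric(n_shells) || length(n_shells) != 1L || n_shells < 1) {
    nsph_error("nsphere_argument_error", "n_shells must be a single integer >= 1")
  }
  n_shells <- as.integer(n_shells)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  radii <- sort(stats::runif(n_shells, 0.05, 0.11))
  conductivities <- 10^stats::runif(n_shells, -3, 0)
  sphere_model(radii, conductivities)
}

#' Split a shell at a fictitious boundary
#'
#' Inserts an extra boundary inside shell `shell`, duplicating its
#' conductivity. Because the new boundary has zero conductivity contrast,
#' all potentials must be unchanged: this is the zero-contrast invariance
#' used to exercise the arbitrary-`n` recursion.
#'
#' @param model A [sphere_model()].
#' @param shell Index of the shell to split (1-based).
#' @param fraction Where to place the new boundary between the shell's inner
#'   and outer radius, in (0, 1). Default 0.5.
#' @return A model with `n + 1` shells.
#' @export
split_shell <- function(model, shell, fraction = 0.5) {
  validate_model(model)
  if (shell < 1 || shell > model$n) {
    nsph_error("nsphere_argument_error", "shell index out of range")
  }
  if (fraction <= 0 || fraction >= 1) {
    nsph_error("nsphere_argument_error", "fraction must be in (0, 1)")
  }
  inner <- if (shell == 1) 0 else model$radii[shell - 1]
  new_r <- inner + fraction * (model$radii[shell] - inner)
  sphere_model(append(model$radii, new_r, after = shell - 1),
               append(model$conductivities, model$conductivities[shell],
                      after = shell - 1))
}

#' Read / write a sphere model as JSON
#'
#' The on-disk format is a JSON object with keys `radii_m` (ascending list of
#' boundary radii, meters) and `conductivities_S_per_m` (same length, S/m).
#'
#' @param path File path.
#' @return `read_model_json()` returns a validated [sphere_model()];
#'   `write_model_json()` returns `path` invisibly.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) {
    nsph_error("nsphere_io_error", sprintf("model file not found: %s", path))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$radii_m) || is.null(x$conductivities_S_per_m)) {
    nsph_error("nsphere_io_error",
               sprintf("model JSON %s must contain 'radii_m' and 'conductivities_S_per_m'",
                       path))
  }
  sphere_model(x$radii_m, x$conductivities_S_per_m)
}

#' @rdname read_model_json
#' @param model A [sphere_model()] to serialize.
#' @export
write_model_json <- function(model, path) {
  validate_model(model)
  jsonlite::write_json(
    list(radii_m = model$radii, conductivities_S_per_m = model$conductivities),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

# Short content hash of a model, for output provenance headers.
model_hash <- function(model) {
  s <- paste(format(c(model$radii, model$conductivities), digits = 17),
             collapse = ",")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
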