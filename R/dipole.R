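#' Radial current dipole
#'
#' An elemental current dipole oriented radially, i.e. along the line from the
#' sphere center through its position. For a dipole exactly at the center
#' (`|position| == 0`) the radial direction is undefined and an explicit unit
#' `orientation` must be supplied; the potential is then evaluated in the
#' r0 -> 0 limit, in which only the degree-1 term of the series survives.
#'
#' @param position Numeric length-3 Cartesian position in meters. Must lie
#'   strictly inside the innermost shell of the model it is used with (checked
#'   at evaluation time).
#' @param moment Signed dipole moment magnitude in A*m; positive points
#'   outward along the radial axis. Default 1 (unit moment).
#' @param orientation Optional length-3 vector; required (and only allowed)
#'   when `position` is the origin. Normalized internally.
#' @return An object of class `radial_dipole` with fields `position`,
#'   `moment`, `r0` (radial distance, m) and `axis` (unit vector).
#' @examples
#' radial_dipole(c(0, 0, 0.05))
#' radial_dipole(c(0, 0, 0), orientation = c(0, 0, 1))
#' @export
radial_dipole <- function(position, moment = 1, orientation = NULL) {
  position <- as.numeric(position)
  if (length(position) != 3L || !is_finite_num(position)) {
    nsph_error("nsphere_argument_error", "position must be a finite length-3 vector (m)")
  }
  if (!is_finite_num(moment) || length(moment) != 1L) {
    nsph_error("nsphere_argument_error", "moment must be a single finite number (A*m)")
  }
  r0 <- sqrt(sum(position^2))
  if (r0 == 0) {
    if (is.null(orientation)) {
      nsph_error("nsphere_argument_error",
                 "a dipole at the origin needs an explicit 'orientation'")
    }
    orientation <- as.numeric(orientation)
    nrm <- sqrt(sum(orientation^2))
    if (length(orientation) != 3L || !is_finite_num(orientation) || nrm == 0) {
      nsph_error("nsphere_argument_error", "orientation must be a nonzero length-3 vector")
    }
    axis <- orientation / nrm
  } else {
    if (!is.null(orientation)) {
      nsph_error("nsphere_argument_error",
                 "orientation is only accepted for a dipole at the origin; off-center dipoles are radial by definition")
    }
    axis <- position / r0
  }
  structure(list(position = position, moment = as.numeric(moment),
                 r0 = r0, axis = axis),
            class = "radial_dipole")
}

#' @export
print.radial_dipole <- function(x, ...) {
  cat(sprintf("Radial dipole: r0 = %g m, moment = %g A*m, axis = (%s)\n",
              x$r0, x$moment, paste(format(x$axis, digits = 4), collapse = ", ")))
  invisible(x)
}

# Check that a dipole fits inside shell 1 of a model.
check_dipole_in_model <- function(dipole, model) {
  if (!inherits(dipole, "radial_dipole")) {
    nsph_error("nsphere_argument_error", "not a 'radial_dipole' object")
  }
  if (dipole$r0 >= model$radii[1]) {
    nsph_error("nsphere_geometry_error",
               sprintf("dipole radius r0 = %g m must be < innermost radius R1 = %g m",
                       dipole$r0, model$radii[1]))
  }
  invisible(dipole)
}

#' Read a dipole table from CSV/TSV
#'
#' Expected columns: `x_m`, `y_m`, `z_m` (Cartesian position, meters) and
#' optionally `moment_Am` (default 1). Tables carrying orientation columns
#' (e.g. `qx`, `oy_m`, `orientation_z`) are refused: only radial dipole
#' moments are supported by the spherical-harmonic expansion implemented
#' here, and silently projecting arbitrary moments onto the radial direction
#' would misrepresent the model.
#'
#' @param path CSV (comma) or TSV (tab, by `.tsv` extension) file path.
#' @return A list of [radial_dipole()] objects, named `d001`, `d002`, ...
#' @export
read_dipoles_csv <- function(path) {
  tab <- read_xyz_table(path)
  bad <- grep("^(q[xyz]$|o[xyz](_m)?$|orient)", names(tab), value = TRUE)
  if (length(bad) > 0) {
    nsph_error("nsphere_argument_error",
               sprintf(paste("dipole table %s carries orientation column(s) %s;",
                             "only radial dipoles are supported: drop the columns",
                             "or use a tool that handles arbitrary orientations"),
                       path, paste(bad, collapse = ", ")))
  }
  moments <- if ("moment_Am" %in% names(tab)) tab$moment_Am else rep(1, nrow(tab))
  dip <- lapply(seq_len(nrow(tab)), function(i) {
    radial_dipole(c(tab$x_m[i], tab$y_m[i], tab$z_m[i]), moment = moments[i])
  })
  names(dip) <- sprintf("d%03d", seq_along(dip))
  dip
}

# Shared CSV/TSV reader requiring x_m, y_m, z_m columns.
read_xyz_table <- function(path) {
  if (!file.exists(path)) {
    nsph_error("nsphere_io_error", sprintf("table not found: %s", path))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("x_m", "y_m", "z_m")
  if (!all(need %in% names(tab))) {
    nsph_error("nsphere_io_error",
               sprintf("%s must have columns %s (found: %s)",
                       path, paste(need, collapse = ","),
                       paste(names(tab), collapse = ",")))
  }
  if (nrow(tab) == 0) {
    nsph_error("nsphere_io_error", sprintf("%s contains no rows", path))
  }
  tab
}
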