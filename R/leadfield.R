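#' Scalp electrode array
#'
#' A labelled set of electrode positions. Labels must be unique; positions
#' are Cartesian meters and are expected to sit on (or within 1% of) the
#' outer surface of the conductor — see [project_electrodes()].
#'
#' @param labels Character vector of unique channel names.
#' @param positions `nchan x 3` numeric matrix of positions (meters).
#' @return An object of class `electrode_array`.
#' @export
electrode_array <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (anyDuplicated(labels)) {
    nsph_error("nsphere_argument_error", "electrode labels must be unique")
  }
  if (ncol(positions) != 3L || nrow(positions) != length(labels) ||
      !is_finite_num(positions)) {
    nsph_error("nsphere_argument_error",
               "positions must be a finite nchan x 3 matrix matching the labels")
  }
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("Electrode array: %d channel(s)\n", length(x$labels)))
  invisible(x)
}

#' Read an electrode table from CSV/TSV
#'
#' Expected columns: `x_m`, `y_m`, `z_m` and optionally `label` (channels are
#' named `E001`, `E002`, ... when absent).
#'
#' @param path CSV (comma) or TSV (tab, by `.tsv` extension) file path.
#' @return An [electrode_array()].
#' @export
read_electrodes_csv <- function(path) {
  tab <- read_xyz_table(path)
  labels <- if ("label" %in% names(tab)) as.character(tab$label) else
    sprintf("E%03d", seq_len(nrow(tab)))
  electrode_array(labels, as.matrix(tab[, c("x_m", "y_m", "z_m")]))
}

#' Project electrodes radially onto the outer surface
#'
#' Rescales each electrode position radially to exactly `R_n`. Positions more
#' than 1% off the surface are refused rather than silently projected: a
#' sensor that far from the scalp is a coregistration error, not noise.
#'
#' @param array An [electrode_array()].
#' @param model A [sphere_model()].
#' @return The array with all positions at radius exactly `R_n`.
#' @export
project_electrodes <- function(array, model) {
  if (!inherits(array, "electrode_array")) {
    nsph_error("nsphere_argument_error", "not an 'electrode_array'")
  }
  validate_model(model)
  Rn <- model$radii[model$n]
  r <- sqrt(rowSums(array$positions^2))
  off <- abs(r - Rn) / Rn
  if (any(off > 0.01)) {
    bad <- array$labels[which.max(off)]
    nsph_error("nsphere_placement_error",
               sprintf("electrode '%s' is %.1f%% off the outer surface (tolerance 1%%)",
                       bad, 100 * max(off)))
  }
  pos <- array$positions * (Rn / r)
  electrode_array(array$labels, pos)
}

#' Radial-dipole lead-field matrix
#'
#' Potential per unit dipole moment (V per A*m) at each electrode for each
#' radial dipole: entry `(i, j)` is the potential at electrode `i` generated
#' by dipole `j` with a 1 A*m radial moment. With `reference = "average"`
#' the mean over electrodes is subtracted from each column (each dipole's
#' topography becomes zero-mean); `"infinity"` keeps the raw series values,
#' which are referenced to a zero potential at infinity.
#'
#' @param model A [sphere_model()].
#' @param constants Matching `harmonic_constants`.
#' @param dipoles A [radial_dipole()] or list of them (all inside shell 1).
#' @param array A projected [electrode_array()] (see [project_electrodes()]).
#' @param reference `"infinity"` (default) or `"average"`.
#' @return An object of class `leadfield_matrix`: list with `values`
#'   (`nchan x ndip` matrix, dimnames channel x dipole), `reference`, `L`.
#' @export
radial_leadfield <- function(model, constants, dipoles, array,
                             reference = c("infinity", "average")) {
  reference <- match.arg(reference)
  if (inherits(dipoles, "radial_dipole")) dipoles <- list(dipoles)
  if (length(dipoles) == 0) {
    nsph_error("nsphere_argument_error", "need at least one dipole")
  }
  arr <- project_electrodes(array, model)
  ids <- names(dipoles)
  if (is.null(ids)) ids <- sprintf("d%03d", seq_along(dipoles))
  values <- matrix(NA_real_, nrow = length(arr$labels), ncol = length(dipoles),
                   dimnames = list(arr$labels, ids))
  for (j in seq_along(dipoles)) {
    d <- dipoles[[j]]
    unit <- radial_dipole(d$position, moment = 1,
                          orientation = if (d$r0 == 0) d$axis else NULL)
    values[, j] <- potential(model, constants, unit, arr$positions)$value
  }
  if (reference == "average") {
    values <- sweep(values, 2, colMeans(values))
  }
  structure(list(values = values, reference = reference, L = constants$L),
            class = "leadfield_matrix")
}

#' @export
print.leadfield_matrix <- function(x, ...) {
  cat(sprintf("Lead field: %d electrode(s) x %d dipole(s), reference = %s, L = %d\n",
              nrow(x$values), ncol(x$values), x$reference, x$L))
  invisible(x)
}

# Lead-field TSV writer: '#' provenance header, then channel-labelled columns,
# one row per dipole. Written to a temp file first so failures leave no
# partial output.
write_leadfield_tsv <- function(lf, model, path) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wt")
  ok <- FALSE
  tryCatch({
    writeLines(c(
      "# nsphere lead field",
      sprintf("# model_hash: %s", model_hash(model)),
      sprintf("# degree: %d", lf$L),
      sprintf("# reference: %s", lf$reference),
      "# units: V per (A*m); rows = dipoles, columns = electrodes"
    ), con)
    vals <- t(lf$values)  # dipoles x electrodes
    writeLines(paste(c("dipole", colnames(vals)), collapse = "\t"), con)
    for (i in seq_len(nrow(vals))) {
      writeLines(paste(c(rownames(vals)[i], sprintf("%.17g", vals[i, ])),
                       collapse = "\t"), con)
    }
    ok <- TRUE
  }, finally = close(con))
  if (ok) file.rename(tmp, path)
  invisible(path)
}

#' Read back a lead-field TSV
#'
#' @param path File written by the CLI / [write_leadfield_tsv()].
#' @return A `nchan x ndip` matrix (electrodes x dipoles).
#' @export
read_leadfield_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  t(m)
}
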