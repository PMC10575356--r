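# Shared fixtures, all generated in code.

classic3 <- function() canonical_model("three-shell-classic")

# classic model padded to 4 shells by splitting the scalp shell (R1 unchanged,
# so dipole eccentricities are comparable with the 3-shell model)
classic4 <- function() split_shell(classic3(), 3, 0.5)

theta_grid <- function(n = 50) seq(0, pi, length.out = n)

# Explicit low-degree Legendre polynomials, written out independently of the
# package recurrence.
legendre_explicit <- function(l, x) {
  switch(as.character(l),
         "0" = x^0,
         "1" = x,
         "2" = (3 * x^2 - 1) / 2,
         "3" = (5 * x^3 - 3 * x) / 2,
         "4" = (35 * x^4 - 30 * x^2 + 3) / 8,
         "5" = (63 * x^5 - 70 * x^3 + 15 * x) / 8,
         stop("no explicit form coded for l = ", l))
}

# sup-norm relative difference between two equally shaped profiles
rel_sup <- function(a, b) max(abs(a - b)) / max(abs(a), abs(b))

write_fixture_inputs <- function(dir, radii = classic3()$radii,
                                 cond = classic3()$conductivities) {
  model <- file.path(dir, "model.json")
  jsonlite::write_json(list(radii_m = radii, conductivities_S_per_m = cond),
                       model, digits = NA)
  dip <- file.path(dir, "dipoles.csv")
  # second dipole shallow (eccentricity ~0.93) so that L = 100 vs 200
  # truncation differences are representable in the output
  utils::write.csv(data.frame(x_m = c(0, 0.02), y_m = c(0, 0.01),
                              z_m = c(0.05, 0.078), moment_Am = c(1, 1)),
                   dip, row.names = FALSE)
  Rn <- max(radii)
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ele <- file.path(dir, "electrodes.csv")
  utils::write.csv(data.frame(label = sprintf("E%02d", seq_along(ang)),
                              x_m = Rn * sin(ang) * 0.999,
                              y_m = Rn * 0, z_m = Rn * cos(ang) * 0.999),
                   ele, row.names = FALSE)
  list(model = model, dipoles = dip, electrodes = ele)
}
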