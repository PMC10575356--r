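test_that("sphere_model enforces its invariants with classed errors", {
  expect_s3_class(sphere_model(0.1, 1/3), "sphere_model")

  expect_error(sphere_model(c(0.09, 0.08), c(1/3, 1/3)),
               class = "nsphere_geometry_error")
  expect_error(sphere_model(c(0.08, 0.08), c(1/3, 1/3)),
               class = "nsphere_geometry_error")
  expect_error(sphere_model(c(-0.05, 0.08), c(1/3, 1/3)),
               class = "nsphere_geometry_error")
  expect_error(sphere_model(c(0.08, 0.09), c(1/3, 0)),
               class = "nsphere_conductivity_error")
  expect_error(sphere_model(c(0.08, 0.09), c(1/3, -1)),
               class = "nsphere_conductivity_error")
  expect_error(sphere_model(c(0.08, 0.09), c(1/3, Inf)),
               class = "nsphere_conductivity_error")
  expect_error(sphere_model(numeric(0), numeric(0)),
               class = "nsphere_empty_model_error")
  expect_error(sphere_model(c(0.08, 0.09), 1/3),
               class = "nsphere_argument_error")

  # validate_model is idempotent
  m <- classic3()
  expect_identical(validate_model(validate_model(m)), m)
})

test_that("canonical_model registry holds the classical conductivities", {
  m <- canonical_model("three-shell-classic")
  expect_equal(m$conductivities, c(1/3, 1/(3 * 80), 1/3))
  expect_equal(m$radii, c(0.087, 0.092, 0.100))
  expect_equal(canonical_model("single-shell")$n, 1L)
  expect_error(canonical_model("foo"), class = "nsphere_registry_error")
})

test_that("random_model is seeded, valid, and leaves the global RNG alone", {
  expect_identical(random_model(4, 1), random_model(4, 1))
  expect_false(identical(random_model(4, 1)$conductivities,
                         random_model(4, 2)$conductivities))
  expect_s3_class(random_model(1, 99), "sphere_model")
  expect_error(random_model(0, 1), class = "nsphere_argument_error")

  # property: every seeded model passes validation, for several shell counts
  for (seed in 1:25) {
    for (n in c(1, 2, 4, 6)) {
      m <- random_model(n, seed + 7 * n)
      expect_identical(validate_model(m), m)
      expect_true(all(m$radii >= 0.05 & m$radii <= 0.11))
      expect_true(all(m$conductivities >= 1e-3 & m$conductivities <= 1))
    }
  }

  set.seed(123)
  before <- .Random.seed
  random_model(3, 42)
  expect_identical(before, .Random.seed)
})

test_that("split_shell inserts a zero-contrast boundary", {
  m <- classic3()
  sp <- split_shell(m, 2, 0.25)
  expect_equal(sp$n, 4L)
  expect_equal(sp$conductivities[2:3], rep(m$conductivities[2], 2))
  expect_equal(sp$radii[2], 0.087 + 0.25 * (0.092 - 0.087))
  expect_error(split_shell(m, 5), class = "nsphere_argument_error")
  expect_error(split_shell(m, 1, 1.5), class = "nsphere_argument_error")
})

test_that("radial_dipole geometry rules", {
  d <- radial_dipole(c(0, 0, 0.05), moment = 2)
  expect_equal(d$r0, 0.05)
  expect_equal(d$axis, c(0, 0, 1))

  # origin dipole needs (and accepts only then) an explicit orientation
  expect_error(radial_dipole(c(0, 0, 0)), class = "nsphere_argument_error")
  d0 <- radial_dipole(c(0, 0, 0), orientation = c(0, 0, 2))
  expect_equal(d0$axis, c(0, 0, 1))
  expect_error(radial_dipole(c(0, 0, 0.05), orientation = c(1, 0, 0)),
               class = "nsphere_argument_error")

  # eccentricity of any accepted dipole is in [0, 1)
  m <- classic3()
  for (z in c(0, 0.02, 0.086)) {
    d <- radial_dipole(c(0, 0, z), orientation = if (z == 0) c(1, 0, 0))
    expect_silent(nsphere:::check_dipole_in_model(d, m))
    expect_lt(d$r0 / m$radii[1], 1)
  }
  expect_error(
    nsphere:::check_dipole_in_model(radial_dipole(c(0, 0, 0.087)), m),
    class = "nsphere_geometry_error"
  )
})

test_that("model JSON and dipole/electrode tables round-trip", {
  dir <- withr::local_tempdir()
  m <- random_model(3, 11)
  path <- file.path(dir, "m.json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$radii, m$radii)
  expect_equal(m2$conductivities, m$conductivities)
  expect_error(read_model_json(file.path(dir, "nope.json")),
               class = "nsphere_io_error")

  files <- write_fixture_inputs(dir)
  dip <- read_dipoles_csv(files$dipoles)
  expect_length(dip, 2)
  expect_equal(dip[[1]]$position, c(0, 0, 0.05))
  arr <- read_electrodes_csv(files$electrodes)
  expect_equal(arr$labels[1], "E01")

  # orientation columns are refused, with the scope explained
  bad <- file.path(dir, "bad.csv")
  utils::write.csv(data.frame(x_m = 0, y_m = 0, z_m = 0.05, qx = 1, qy = 0, qz = 0),
                   bad, row.names = FALSE)
  expect_error(read_dipoles_csv(bad), "radial",
               class = "nsphere_argument_error")

  # missing coordinate column
  mangled <- file.path(dir, "mangled.csv")
  utils::write.csv(data.frame(x_m = 0, y_m = 0), mangled, row.names = FALSE)
  expect_error(read_dipoles_csv(mangled), class = "nsphere_io_error")
})
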