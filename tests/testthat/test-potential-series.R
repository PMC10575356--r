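test_that("legendre_sequence matches explicit polynomials and endpoint identities", {
  expect_equal(legendre_sequence(1, 10), rep(1, 11))
  expect_equal(legendre_sequence(-1, 10), (-1)^(0:10))
  expect_equal(legendre_sequence(0.3, 1)[2], 0.3)
  expect_equal(legendre_sequence(0.5, 2)[3], -0.125)

  xs <- seq(-1, 1, by = 0.25)
  P <- legendre_sequence(xs, 5)
  for (l in 0:5) {
    expect_equal(P[l + 1, ], legendre_explicit(l, xs), tolerance = 1e-14)
  }
  expect_true(all(abs(legendre_sequence(seq(-1, 1, 0.01), 200)) <= 1 + 1e-12))
  expect_error(legendre_sequence(1.2, 5), class = "nsphere_domain_error")
})

test_that("locate_shell uses the inner-side boundary convention", {
  m <- classic3()
  expect_equal(locate_shell(m, 0.05), 1L)
  expect_equal(locate_shell(m, 0.087), 1L)
  expect_equal(locate_shell(m, 0.092), 2L)
  expect_equal(locate_shell(m, c(0.09, 0.1)), c(2L, 3L))
  expect_error(locate_shell(m, 0.2), class = "nsphere_outside_conductor_error")
})

test_that("series matches the homogeneous closed form to 1e-10", {
  m1 <- canonical_model("single-shell")
  th <- theta_grid(60)
  for (f in c(0.1, 0.5, 0.8, 0.95)) {
    L <- if (f > 0.9) 700 else 300
    hc <- harmonic_constants(m1, L)
    d <- radial_dipole(c(0, 0, f * 0.1), moment = 2.5)
    prof <- surface_potential_profile(m1, hc, d, th)
    cf <- homogeneous_closed_form(1/3, 0.1, f * 0.1, th, P = 2.5)
    expect_lt(rel_sup(prof$value, cf), 1e-10)
  }
})

test_that("series matches the explicit four-sphere oracle to 1e-10", {
  m <- classic4()
  hc <- harmonic_constants(m, 100)
  th <- theta_grid(40)
  Rn <- m$radii[4]
  for (ecc in c(0.3, 0.9)) {
    d <- radial_dipole(c(0, 0, ecc * m$radii[1]))
    core <- surface_potential_profile(m, hc, d, th)$value
    oracle <- naess_potential(m, d, rep(Rn, length(th)), cos(th), L = 100)
    expect_lt(rel_sup(core, oracle), 1e-10)
  }
  # interior points too (all shells)
  d <- radial_dipole(c(0, 0, 0.04))
  for (r in c(0.06, 0.09, 0.094, 0.098)) {
    core <- nsphere:::series_eval(hc, d, rep(r, length(th)), cos(th))$value
    oracle <- naess_potential(m, d, rep(r, length(th)), cos(th), L = 100)
    expect_lt(rel_sup(core, oracle), 1e-10)
  }
})

test_that("potential is rotationally symmetric, linear in P, zero for P = 0", {
  m <- classic3()
  hc <- harmonic_constants(m, 100)
  d <- radial_dipole(c(0.01, 0.02, 0.03), moment = 3)

  # points with the same (r, cos theta) but different azimuth about the axis
  axis <- d$axis
  seed_pt <- c(0.05, -0.02, 0.07)
  r <- sqrt(sum(seed_pt^2))
  ct <- sum(seed_pt * axis) / r
  # rotate seed_pt about the dipole axis by a few angles (Rodrigues)
  rot <- function(v, k, ang) {
    v * cos(ang) + pracma_cross(k, v) * sin(ang) + k * sum(k * v) * (1 - cos(ang))
  }
  pracma_cross <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  }
  pts <- t(vapply(c(0, 0.7, 2.1, 4.4), function(ang) rot(seed_pt, axis, ang),
                  numeric(3)))
  vals <- potential(m, hc, d, pts)$value
  # rotation introduces ~eps noise in cos(theta), amplified ~l^2 by P_l'
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-10 * abs(vals[1]))

  # linearity in the moment
  d1 <- radial_dipole(d$position, moment = 1)
  expect_equal(vals, 3 * potential(m, hc, d1, pts)$value, tolerance = 1e-14)
  d0 <- radial_dipole(d$position, moment = 0)
  expect_equal(potential(m, hc, d0, pts)$value, rep(0, 4))
})

test_that("region-of-validity and argument errors", {
  m <- classic3()
  hc <- harmonic_constants(m, 50)
  d <- radial_dipole(c(0, 0, 0.05))
  expect_error(potential(m, hc, d, c(0, 0, 0.01)),
               class = "nsphere_unsupported_region_error")
  expect_error(potential(m, hc, d, c(0, 0, 0)),
               class = "nsphere_unsupported_region_error")
  expect_error(potential(m, hc, d, c(0, 0, 0.15)),
               class = "nsphere_outside_conductor_error")
  expect_error(potential(m, harmonic_constants(classic4(), 50), d, c(0, 0, 0.09)),
               class = "nsphere_argument_error")
  # r = r0 itself is fine (series converges, slowly)
  expect_silent(potential(m, hc, d, c(0, 0, 0.05)))
})

test_that("centered dipole: only the degree-1 term survives", {
  m1 <- canonical_model("single-shell")
  hc <- harmonic_constants(m1, 100)
  d0 <- radial_dipole(c(0, 0, 0), orientation = c(0, 0, 1))
  prof <- surface_potential_profile(m1, hc, d0, c(0, pi / 2, pi / 3))
  expect_equal(prof$degree_used, rep(1L, 3))
  amp <- 3 / (4 * pi * (1 / 3) * 0.1^2)
  expect_equal(prof$value, amp * cos(c(0, pi / 2, pi / 3)), tolerance = 1e-14)
  # theta = pi/2 exactly zero by symmetry
  expect_equal(prof$value[2], 0, tolerance = 1e-16 * amp)
})

test_that("surface_potential_profile is a faithful batch wrapper", {
  m <- classic3()
  hc <- harmonic_constants(m, 100)
  d <- radial_dipole(c(0, 0, 0.06))
  pr <- surface_potential_profile(m, hc, d, c(0.4, 0.4))
  expect_equal(pr$value[1], pr$value[2])
  one <- potential(m, hc, d, 0.1 * c(sin(0.4), 0, cos(0.4)))
  expect_equal(pr$value[1], one$value, tolerance = 1e-12)
  expect_equal(pr$shell, rep(3L, 2))
})

test_that("truncation: L = 100 vs 200 and the adaptive stopping rule", {
  m <- classic3()
  h100 <- harmonic_constants(m, 100)
  h200 <- harmonic_constants(m, 200)
  th <- theta_grid(30)
  for (ecc in c(0.5, 0.95)) {
    d <- radial_dipole(c(0, 0, ecc * m$radii[1]))
    a <- surface_potential_profile(m, h100, d, th)$value
    b <- surface_potential_profile(m, h200, d, th)$value
    expect_lt(rel_sup(a, b), 1e-6)
  }
  # adaptive mode stops early for a deep source and agrees with fixed L
  d <- radial_dipole(c(0, 0, 0.02))
  fixed <- surface_potential_profile(m, h200, d, th)
  adapt <- surface_potential_profile(m, h200, d, th, adaptive = TRUE)
  expect_true(all(adapt$degree_used < 200))
  expect_equal(adapt$value, fixed$value, tolerance = 1e-10)
})
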