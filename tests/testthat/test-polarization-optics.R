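# Stokes / Mueller / Jones algebra for linear-birefringence elements

test_that("lb_mueller reproduces the closed-form element structure", {
  # zero retardance is a null element
  expect_equal(unclass(lb_mueller(0.7, 0)), diag(4), ignore_attr = TRUE)

  # rho = pi/4 collapses the linear block
  M <- lb_mueller(pi / 4, 1.1)
  expect_equal(M[2, 2], cos(1.1))
  expect_equal(M[2, 3], 0)
  expect_equal(M[2, 4], sin(1.1))
  expect_equal(M[3, 3], 1)
  expect_equal(M[4, 4], cos(1.1))

  # stated elements for arbitrary (rho, delta)
  for (i in 1:20) {
    rho <- runif(1, 0, pi); delta <- runif(1, 0, 2 * pi)
    M <- lb_mueller(rho, delta)
    expect_equal(M[4, 4], cos(delta))
    expect_equal(M[2, 4], sin(2 * rho) * sin(delta))
    expect_equal(M[3, 4], cos(2 * rho) * sin(delta))
    expect_equal(M[1, ], c(1, 0, 0, 0))
    expect_equal(M[, 1], c(1, 0, 0, 0))
  }
})

test_that("lb_mueller equals a rotation-retarder-rotation composition", {
  # independent oracle: conjugate the axis-aligned retarder block by the
  # Poincare rotation of the (s2, s3) plane
  oracle <- function(rho, delta) {
    rot <- function(t) {
      matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3,
             byrow = TRUE)
    }
    base <- lb_mueller(0, delta)[2:4, 2:4]
    out <- diag(4)
    out[2:4, 2:4] <- rot(-2 * rho) %*% base %*% rot(2 * rho)
    out
  }
  set.seed(42)
  for (i in 1:50) {
    rho <- runif(1, 0, pi); delta <- runif(1, 0, 2 * pi)
    m <- lb_mueller(rho, delta)
    expect_lt(max(abs(matrix(as.numeric(m), 4, 4) - oracle(rho, delta))),
              1e-12)
  }
})

test_that("lb_mueller invariants: rotation block, determinant, additivity", {
  set.seed(7)
  for (i in 1:50) {
    rho <- runif(1, 0, pi)
    d1 <- runif(1, 0, pi); d2 <- runif(1, 0, pi)
    M <- lb_mueller(rho, d1)
    B <- M[2:4, 2:4]
    expect_equal(B %*% t(B), diag(3), tolerance = 1e-12)
    expect_equal(det(M), 1, tolerance = 1e-12)
    # retardance additivity at shared axis
    expect_equal(
      unclass(lb_mueller(rho, d1) %*% lb_mueller(rho, d2)),
      unclass(lb_mueller(rho, d1 + d2)),
      tolerance = 1e-12, ignore_attr = TRUE
    )
  }
  expect_error(lb_mueller(NA, 1), "finite")
  expect_error(lb_mueller(1, -0.1), ">= 0")
})

test_that("apply_mueller reproduces the circular-probe response", {
  S0 <- stokes_circular()
  expect_equal(as.numeric(apply_mueller(diag(4), S0)), as.numeric(S0))
  set.seed(3)
  for (i in 1:25) {
    rho <- runif(1, 0, pi); delta <- runif(1, 0, 2 * pi)
    S <- apply_mueller(lb_mueller(rho, delta), S0)
    expect_equal(
      as.numeric(S),
      c(1, sin(2 * rho) * sin(delta), cos(2 * rho) * sin(delta), cos(delta)),
      tolerance = 1e-12
    )
  }
  # frozen numeric case: rho = pi/6, delta = pi/2
  S <- apply_mueller(lb_mueller(pi / 6, pi / 2), S0)
  expect_equal(as.numeric(S), c(1, sqrt(3) / 2, 1 / 2, 0), tolerance = 1e-12)
})

test_that("Jones to Mueller conversion matches lb_mueller", {
  set.seed(11)
  for (i in 1:1000) {
    rho <- runif(1, 0, pi); delta <- runif(1, 0, 2 * pi)
    expect_lt(
      max(abs(jones_to_mueller(lb_jones(rho, delta)) -
                lb_mueller(rho, delta))),
      1e-10
    )
  }
  # unitarity
  J <- lb_jones(0.3, 1.7)
  expect_equal(Conj(t(J)) %*% J, diag(2) + 0i, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("stokes_to_polarization recovers azimuth and ellipticity", {
  p <- stokes_to_polarization(c(1, 1, 0, 0))
  expect_equal(p$alpha, 0)
  expect_equal(p$beta, 0)
  expect_true(p$alpha_defined)

  # circular: azimuth undefined, flagged, beta still returned
  p <- stokes_to_polarization(c(1, 0, 0, 1))
  expect_false(p$alpha_defined)
  expect_equal(p$alpha, 0)
  expect_equal(p$beta, pi / 4)

  # closed form through the probe response: alpha = 0.5 atan(cot 2 rho),
  # beta = 0.5 asin(cos delta)
  S <- apply_mueller(lb_mueller(pi / 6, pi / 2), stokes_circular())
  p <- stokes_to_polarization(S)
  expect_equal(p$alpha, pi / 12, tolerance = 1e-12)
  expect_equal(p$beta, 0, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:200) {
    rho <- runif(1, 0.05, pi / 2 - 0.05); delta <- runif(1, 0.1, pi - 0.1)
    S <- apply_mueller(lb_mueller(rho, delta), stokes_circular())
    p <- stokes_to_polarization(S)
    expect_equal(azimuth_diff(p$alpha, 0.5 * atan(cos(2 * rho) /
                                                    sin(2 * rho))), 0,
                 tolerance = 1e-10)
    expect_equal(p$beta, 0.5 * asin(cos(delta)), tolerance = 1e-10)
  }
})

test_that("amplitude and Stokes polarization paths agree", {
  expect_equal(amplitudes_to_polarization(1, 0)$alpha, 0)
  expect_equal(amplitudes_to_polarization(1, 0)$beta, 0)
  p <- amplitudes_to_polarization(1, 1i)
  expect_false(p$alpha_defined)
  expect_equal(p$beta, pi / 4)
  expect_error(amplitudes_to_polarization(0, 0), "zero")

  set.seed(9)
  for (i in 1:200) {
    ux <- complex(real = rnorm(1), imaginary = rnorm(1))
    uy <- complex(real = rnorm(1), imaginary = rnorm(1))
    a <- amplitudes_to_polarization(ux, uy)
    s1 <- Mod(ux)^2 + Mod(uy)^2
    s2 <- Mod(ux)^2 - Mod(uy)^2
    cr <- Conj(ux) * uy
    b <- stokes_to_polarization(c(s1, s2, 2 * Re(cr), 2 * Im(cr)))
    if (a$alpha_defined) {
      expect_equal(a$alpha, b$alpha, tolerance = 1e-10)
    }
    expect_equal(a$beta, b$beta, tolerance = 1e-10)
  }
})

test_that("amplitudes_to_polarization matches a time-domain ellipse fit", {
  # oracle: sample the real field E(t) = Re((ux, uy) e^{-i t}), fit the
  # ellipse axes and orientation from the trace
  ellipse_fit <- function(ux, uy) {
    t <- seq(0, 2 * pi, length.out = 4096)
    ex <- Re(ux * exp(-1i * t))
    ey <- Re(uy * exp(-1i * t))
    r2 <- ex^2 + ey^2
    imax <- which.max(r2)
    alpha <- atan2(ey[imax], ex[imax])
    alpha <- ((alpha + pi / 2) %% pi) - pi / 2
    ratio <- sqrt(min(r2) / max(r2))
    # handedness from the cross product near the major axis
    i2 <- imax %% length(t) + 1
    handed <- sign(ex[imax] * ey[i2] - ey[imax] * ex[i2])
    list(alpha = alpha, beta = handed * atan(ratio))
  }
  cases <- list(
    c(1 + 0i, 0.5 * exp(1i * pi / 3)),
    c(2 + 0i, exp(1i * pi / 3)),
    c(1 + 0.3i, -0.7 + 0.2i)
  )
  for (cs in cases) {
    p <- amplitudes_to_polarization(cs[1], cs[2])
    o <- ellipse_fit(cs[1], cs[2])
    expect_equal(azimuth_diff(p$alpha, o$alpha), 0, tolerance = 1e-3)
    expect_equal(p$beta, o$beta, tolerance = 1e-3)
  }
})

test_that("interference_polarization is the canonical amplitude path", {
  p <- interference_polarization(1, 1, 0)
  expect_equal(p$alpha, pi / 4, tolerance = 1e-12)
  expect_equal(p$beta, 0, tolerance = 1e-12)
  expect_equal(interference_polarization(1, 1, pi / 2)$beta, pi / 4,
               tolerance = 1e-12)
  # equivalence oracle on arbitrary magnitudes and phase shifts
  set.seed(13)
  for (i in 1:50) {
    mx <- runif(1, 0.1, 2); my <- runif(1, 0.1, 2); ph <- runif(1, 0, 2 * pi)
    a <- interference_polarization(mx, my, ph)
    b <- amplitudes_to_polarization(mx + 0i, my * exp(1i * ph))
    expect_equal(a$alpha, b$alpha)
    expect_equal(a$beta, b$beta)
  }
  expect_error(interference_polarization(-1, 1, 0), ">= 0")
})
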