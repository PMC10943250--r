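# Phase-section scanning, moments and the single-scattering plane

test_that("inter_component_phase is the literal relative phase", {
  n <- 16
  ux <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  f_same <- complex_field(ux, ux)
  expect_lt(max(inter_component_phase(f_same)), 1e-12)
  f_quad <- complex_field(ux, 1i * ux)
  expect_equal(max(abs(inter_component_phase(f_quad) - pi / 2)), 0,
               tolerance = 1e-12)
  # direct oracle on a random field
  uy <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  f <- complex_field(ux, uy)
  expect_equal(inter_component_phase(f),
               Arg(uy * Conj(ux)) %% (2 * pi), tolerance = 1e-12)
  # near-zero amplitude pixels flagged
  ux2 <- ux; ux2[1, 1] <- 0; uy2 <- uy; uy2[1, 1] <- 0
  ph <- inter_component_phase(complex_field(ux2, uy2))
  expect_true(is.na(ph[1, 1]))
  expect_error(
    inter_component_phase(complex_field(matrix(0i, 2, 2), matrix(0i, 2, 2))),
    "all-zero"
  )
})

test_that("phase deviation is zero for the unscattered probe", {
  n <- 24
  lay0 <- fibril_layer(matrix(0.4, n, n), matrix(0, n, n))
  f <- cascade_field(scattering_stack(list(lay0)))
  expect_lt(max(phase_deviation(f)), 1e-12)
  # single scattering: deviation = |atan2(cos 2rho sin delta, cos delta)|
  set.seed(2)
  rho <- matrix(runif(n * n, 0, pi), n, n)
  delta <- matrix(runif(n * n, 0, 1), n, n)
  f1 <- cascade_field(scattering_stack(list(fibril_layer(rho, delta))))
  expect_equal(phase_deviation(f1),
               abs(atan2(cos(2 * rho) * sin(delta), cos(delta))),
               tolerance = 1e-10)
})

test_that("section masks are cumulative and obey the retardance bound", {
  n <- 64
  # fibrils at rho = 0 with delta = pi/4 sit at deviation pi/4; the
  # background floor (delta = 0.05) stays below pi/8, so a pi/8 section
  # masks background only
  delta <- matrix(0.05, n, n)
  delta[20:40, ] <- pi / 4
  f <- cascade_field(scattering_stack(list(
    fibril_layer(matrix(0, n, n), delta)
  )))
  m1 <- section_map(f, pi / 8)
  expect_true(all(!m1$mask[20:40, ]))
  expect_true(all(m1$mask[1:19, ]))
  # full-circle section covers everything
  m2 <- section_map(f, 2 * pi)
  expect_true(all(m2$mask))
  # monotone nesting over a ladder of bounds
  bounds <- c(pi / 16, pi / 8, pi / 4, pi / 2, 2 * pi)
  prev <- section_map(f, bounds[1])$mask
  for (b in bounds[-1]) {
    cur <- section_map(f, b)$mask
    expect_true(all(cur[prev]))
    prev <- cur
  }
  expect_error(section_map(f, 0), "delta_t")
})

test_that("beta reference conventions are consistent", {
  n <- 32
  set.seed(5)
  rho <- matrix(runif(n * n, 0, pi), n, n)
  delta <- matrix(runif(n * n, 0.1, 0.6), n, n)
  f <- cascade_field(scattering_stack(list(fibril_layer(rho, delta))))
  mc <- section_map(f, 2 * pi, beta_reference = "circular")
  ma <- section_map(f, 2 * pi, beta_reference = "absolute")
  expect_equal(mc$beta_map, pi / 4 - ma$beta_map, tolerance = 1e-12)
  # absolute ellipticity stays in [-pi/4, pi/4]; probe-referenced equals
  # half the retardance for single scattering
  expect_true(all(abs(ma$beta_map) <= pi / 4 + 1e-12))
  expect_equal(mc$beta_map, delta / 2, tolerance = 1e-10)
})

test_that("moments implement both conventions", {
  m <- moments(c(0, 0, 0, 0), mode = "standard")
  expect_equal(m$z1, 0)
  expect_equal(m$z2, 0)
  expect_true(is.na(m$z3) && is.na(m$z4))

  m <- moments(c(1, 2, 3, 4), mode = "paper")
  expect_equal(m$z1, 2.5)
  expect_equal(m$z2, 7.5)
  expect_equal(m$z3, mean(c(1, 8, 27, 64)) / 7.5^3)
  expect_equal(m$z4, mean(c(1, 16, 81, 256)) / 7.5^4)

  # standard mode against a textbook two-pass oracle
  set.seed(6)
  x <- rnorm(500, 2, 3)
  m <- moments(x, mode = "standard")
  mu <- sum(x) / length(x)
  cm <- function(k) sum((x - mu)^k) / length(x)
  expect_equal(m$z1, mu, tolerance = 1e-12)
  expect_equal(m$z2, cm(2), tolerance = 1e-12)
  expect_equal(m$z3, cm(3) / cm(2)^1.5, tolerance = 1e-12)
  expect_equal(m$z4, cm(4) / cm(2)^2, tolerance = 1e-12)
  expect_error(moments(1), "at least 2")
})

test_that("phase_scan moments match direct per-section computation", {
  n <- 48
  set.seed(3)
  rho <- matrix(runif(n * n, 0, pi), n, n)
  delta <- matrix(runif(n * n, 0.05, 1.2), n, n)
  f <- cascade_field(scattering_stack(list(fibril_layer(rho, delta))))
  sc <- phase_scan(f, d_step = pi / 20, min_pixels = 2)
  ph <- phase_deviation(f)
  pol <- holopolar:::stokes_maps_to_polarization(field_stokes(f))
  beta_c <- pi / 4 - pol$beta
  for (k in c(3, 6, 10)) {
    sel <- ph <= sc$delta_t_grid[k]
    if (sum(sel) < 2) next
    ma <- moments(pol$alpha[sel], mode = "paper")
    mb <- moments(beta_c[sel], mode = "paper")
    expect_equal(unname(sc$moments_alpha[k, ]),
                 c(ma$z1, ma$z2, ma$z3, ma$z4), tolerance = 1e-10)
    expect_equal(unname(sc$moments_beta[k, ]),
                 c(mb$z1, mb$z2, mb$z3, mb$z4), tolerance = 1e-10)
  }
  # masked-pixel count is non-decreasing in delta_t
  expect_true(all(diff(sc$n_pixels) >= 0))
})

test_that("find_single_scatter_plane handles flat, plateau and drift", {
  grid <- seq(pi / 40, 2 * pi, by = pi / 40)
  flat <- matrix(1, length(grid), 4,
                 dimnames = list(NULL, c("z1", "z2", "z3", "z4")))
  sc <- structure(
    list(delta_t_grid = grid, n_pixels = seq_along(grid) + 100,
         moments_alpha = flat, moments_beta = flat, mode = "paper"),
    class = "phase_scan"
  )
  # constant moments: plateau extends to the grid maximum
  expect_equal(as.numeric(find_single_scatter_plane(sc)), max(grid))

  # strict drift everywhere: not found
  drift <- flat * (1.2^(seq_along(grid)))
  sc$moments_alpha <- drift
  expect_error(find_single_scatter_plane(sc),
               class = "holopolar_no_plateau")

  # plateau then jump: bound at the last consistent step
  stepm <- flat
  stepm[11:length(grid), ] <- 3
  sc$moments_alpha <- stepm
  got <- find_single_scatter_plane(sc)
  expect_equal(as.numeric(got), grid[10])
  # cap clips the returned plane
  expect_equal(as.numeric(find_single_scatter_plane(sc, cap = grid[4])),
               grid[4])
})

test_that("plateau maps recover ground truth under heavy depolarization", {
  # smooth single-scatter phantom, 50% depolarized background: masked
  # azimuth and ellipticity recovered within 0.02 rad median
  n <- 128
  lay <- smooth_layer(n, seed = 21, delta_range = c(0.8, 1.2), sigma = 14)
  f1 <- cascade_field(scattering_stack(list(lay)))
  ens <- add_depolarized_background(f1, 0.5, seed = 4, n_speckle = 32)
  rec <- holographic_roundtrip(ens)
  truth <- holopolar:::single_scatter_truth(lay$rho_map, lay$delta_map)
  m <- section_map(rec, 2 * pi, window = 5, beta_reference = "absolute")
  da <- azimuth_diff(m$alpha_map, truth$alpha)
  db <- abs(m$beta_map - truth$beta)
  expect_lt(median(da[m$mask]), 0.02)
  expect_lt(median(db[m$mask]), 0.02)
})
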