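# Phantom generation: layers, cascades, depolarization

test_that("generate_fibril_layer renders strokes with the drawn widths", {
  preset <- phantom_preset("aci")
  lay <- generate_fibril_layer(preset, seed = 7, size = 256,
                               pixel_pitch = 1.16)
  expect_equal(dim(lay$delta_map), c(256, 256))
  expect_true(all(lay$delta_map >= 0))
  expect_true(all(lay$rho_map >= 0 & lay$rho_map < pi))

  # determinism: same seed, same preset -> bit-identical rasters
  lay2 <- generate_fibril_layer(preset, seed = 7, size = 256,
                                pixel_pitch = 1.16)
  expect_identical(lay$delta_map, lay2$delta_map)
  expect_identical(lay$rho_map, lay2$rho_map)

  # no fibrils -> background floor everywhere
  lay0 <- generate_fibril_layer(phantom_preset("ba"), seed = 3, size = 128)
  expect_lt(max(lay0$delta_map), 0.15)

  # median stroke width from minimum chords: for each above-half-peak
  # pixel, the shortest run over four directions estimates the transverse
  # width regardless of orientation (worst-case widening sec(22.5 deg)
  # ~ 1.08).  Measured on a sparse render, where strokes do not merge
  # (at tissue density neighbouring strokes fuse into larger domains).
  # 15-20 um at 1.16 um/px means FWHM in [13, 17] px.
  sparse <- generate_fibril_layer(phantom_preset("aci", n_fibrils = 25),
                                  seed = 7, size = 256)
  half <- sparse$delta_map > phantom_preset("aci")$delta_peak / 2
  fwhm <- median(min_chords(half))
  expect_gte(fwhm, 13)
  expect_lte(fwhm, 17 * 1.1)
  expect_error(generate_fibril_layer(preset, 1, size = -4), "positive")
})

test_that("stroke width and order separate the aci and chd presets", {
  # blind estimates on generated rasters recover the programmed ordering
  est <- function(name, seed) {
    lay <- generate_fibril_layer(phantom_preset(name, n_fibrils = 40),
                                 seed, size = 256)
    peak <- phantom_preset(name)$delta_peak
    mask <- lay$delta_map > peak / 2
    # orientation order: resultant length of the doubled stroke angles
    th <- lay$rho_map[mask]
    list(width = median(min_chords(mask)),
         order = Mod(mean(exp(2i * th))))
  }
  ok <- 0L
  for (seed in 1:12) {
    aci <- est("aci", seed)
    chd <- est("chd", seed + 100)
    if (aci$width > chd$width && aci$order > chd$order) ok <- ok + 1L
  }
  expect_gte(ok, 11L) # >= 95% of seeds at cohort scale
})

test_that("cascade_field reproduces single scattering and additivity", {
  n <- 32
  # null layer keeps the circular probe circular
  lay0 <- fibril_layer(matrix(0.3, n, n), matrix(0, n, n))
  f <- cascade_field(scattering_stack(list(lay0)))
  st <- field_stokes(f)
  expect_equal(max(abs(st$s4 / st$s1 - 1)), 0, tolerance = 1e-12)

  # per-pixel closed form for a single layer
  set.seed(4)
  rho <- matrix(runif(n * n, 0, pi), n, n)
  delta <- matrix(runif(n * n, 0, 2), n, n)
  lay <- fibril_layer(rho, delta)
  f1 <- cascade_field(scattering_stack(list(lay)))
  st1 <- field_stokes(f1)
  truth <- holopolar:::single_scatter_truth(rho, delta)
  pol <- holopolar:::stokes_maps_to_polarization(st1)
  expect_lt(max(azimuth_diff(pol$alpha, truth$alpha)), 1e-10)
  expect_lt(max(abs(pol$beta - truth$beta)), 1e-10)

  # p same-axis layers with delta/p each equal one layer with delta
  lay3 <- fibril_layer(rho, delta / 3)
  f3 <- cascade_field(scattering_stack(list(lay3, lay3, lay3),
                                       layer_shift = 0))
  expect_lt(max(Mod(f3$ux - f1$ux)), 1e-12)
  expect_lt(max(Mod(f3$uy - f1$uy)), 1e-12)
})

test_that("coherent cascade agrees with the Mueller cascade", {
  # random stacks up to p = 5: per-pixel Jones product vs Mueller product
  set.seed(12)
  for (p in 1:5) {
    rhos <- runif(p, 0, pi)
    deltas <- runif(p, 0, 1.5)
    layers <- lapply(seq_len(p), function(j) {
      fibril_layer(matrix(rhos[j], 2, 2), matrix(deltas[j], 2, 2))
    })
    f <- cascade_field(scattering_stack(layers, layer_shift = 0))
    st <- field_stokes(f)
    S <- as.numeric(stokes_circular())
    for (j in seq_len(p)) S <- as.numeric(lb_mueller(rhos[j], deltas[j]) %*% S)
    jointly <- c(st$s1[1, 1], st$s2[1, 1], st$s3[1, 1], st$s4[1, 1])
    expect_lt(max(abs(jointly / jointly[1] - S / S[1])), 1e-10)
  }
})

test_that("add_depolarized_background reaches the target degree", {
  f <- smooth_complex_field(96, sigma = 8, seed = 5)
  expect_identical(add_depolarized_background(f, 0, seed = 1), f)
  ens <- add_depolarized_background(f, 0.5, seed = 1)
  expect_s3_class(ens, "field_ensemble")
  expect_equal(measure_depolarization(ens), 0.5, tolerance = 0.03)

  # monotone in the requested degree on a fixed seed
  got <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(d) {
    measure_depolarization(add_depolarized_background(f, d, seed = 9))
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_lt(max(abs(got - c(0.1, 0.3, 0.5, 0.7, 0.9))), 0.03)
  expect_error(add_depolarized_background(f, 1, seed = 1), "\\[0, 1\\)")
})

test_that("measure_depolarization spatial mode matches mixtures", {
  n <- 96
  # fully coherent uniform field: zero depolarization
  f <- complex_field(matrix(0.8 + 0.1i, n, n), matrix(0.2 - 0.4i, n, n))
  expect_lt(measure_depolarization(f, window = 8), 1e-10)

  # two equal-power orthogonally polarized independent speckles: ~1
  set.seed(77)
  sp <- function() matrix(complex(real = rnorm(n * n), imaginary =
                                    rnorm(n * n)), n, n) / sqrt(2)
  f2 <- complex_field(sp(), sp())
  expect_equal(measure_depolarization(f2, window = 12), 1, tolerance = 0.05)

  # intermediate mixtures match the mixing fraction
  for (frac in c(0.25, 0.5, 0.75)) {
    pol <- complex_field(
      matrix(sqrt(1 - frac) + 0i, n, n), matrix(0i, n, n)
    )
    mix <- complex_field(
      pol$ux + sqrt(frac) * sp() / sqrt(2),
      pol$uy + sqrt(frac) * sp() / sqrt(2)
    )
    expect_equal(measure_depolarization(mix, window = 12), frac,
                 tolerance = 0.03)
  }
  expect_error(measure_depolarization(f, window = 1), ">= 2")
})

test_that("phantom bundles export matching ground truth", {
  ph <- phantom_field("chd", seed = 11, size = 96, n_speckle = 8)
  expect_s3_class(ph$field, "field_ensemble")
  # exported truth equals the closed form of the first layer
  tr <- holopolar:::single_scatter_truth(ph$layer$rho_map,
                                         ph$layer$delta_map)
  expect_identical(ph$truth$alpha, tr$alpha)
  expect_identical(ph$truth$beta, tr$beta)
  expect_equal(ph$truth$beta_circular, pi / 4 - tr$beta)
  # determinism of the full bundle
  ph2 <- phantom_field("chd", seed = 11, size = 96, n_speckle = 8)
  expect_identical(ph$field$members[[3]]$ux, ph2$field$members[[3]]$ux)
})
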