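# ---------------------------------------------------------------------------
# Synthetic birefringent-tissue phantoms and coherent object fields
# ---------------------------------------------------------------------------

#' Phantom presets for the four specimen groups
#'
#' Returns the generator parameters emulating the morphology of the four
#' histological groups: myocardium with coronary heart disease (`chd`,
#' thin ~10 um disordered myosin fibrils), myocardium with acute coronary
#' insufficiency (`aci`, 15-20 um well-ordered fibrils), lung tissue with
#' bronchial asthma (`ba`, weakly structured parenchyma, no fibrils beyond
#' the birefringence floor) and with pulmonary fibrosis (`pf`, 5-10 um
#' collagen fibers).  Depolarization degrees default to the mid-range of the
#' measured values for the two tissue types (0.50 myocardium, 0.57 lung).
#'
#' @param name one of `"myocardium_chd"`, `"myocardium_aci"`, `"lung_ba"`,
#'   `"lung_pf"` (short forms `"chd"`, `"aci"`, `"ba"`, `"pf"` accepted).
#' @param ... named overrides for any preset field.
#' @return list of class `"phantom_preset"` with fields `name`,
#'   `fibril_width_um` (range), `orientation_kappa` (von Mises
#'   concentration), `delta_peak` (peak retardance, rad), `n_fibrils`,
#'   `n_layers`, `depol_degree`, `delta_floor` (parenchymal background
#'   retardance, rad).
#' @export
phantom_preset <- function(name, ...) {
  key <- sub("^(myocardium|lung)_", "", tolower(name))
  base <- switch(key,
    chd = list(
      name = "myocardium_chd", fibril_width_um = c(9, 11),
      orientation_kappa = 1, delta_peak = 0.30, n_fibrils = 160,
      n_layers = 3, depol_degree = 0.50, delta_floor = 0.1
    ),
    aci = list(
      name = "myocardium_aci", fibril_width_um = c(15, 20),
      orientation_kappa = 6, delta_peak = 0.35, n_fibrils = 120,
      n_layers = 3, depol_degree = 0.50, delta_floor = 0.1
    ),
    ba = list(
      name = "lung_ba", fibril_width_um = c(5, 10),
      orientation_kappa = 0, delta_peak = 0, n_fibrils = 0,
      n_layers = 3, depol_degree = 0.57, delta_floor = 0.1
    ),
    pf = list(
      name = "lung_pf", fibril_width_um = c(5, 10),
      orientation_kappa = 3, delta_peak = 0.36, n_fibrils = 180,
      n_layers = 3, depol_degree = 0.57, delta_floor = 0.1
    ),
    stop("unknown preset: ", name)
  )
  p <- modifyList(base, list(...))
  if (any(p$fibril_width_um <= 0)) stop("fibril widths must be positive")
  if (p$depol_degree < 0 || p$depol_degree >= 1) {
    stop("depol_degree must be in [0, 1)")
  }
  structure(p, class = "phantom_preset")
}

#' Construct a fibril layer
#'
#' @param rho_map m x n raster of optical-axis orientations, radians,
#'   reduced to `[0, pi)`.
#' @param delta_map m x n raster of retardances, radians, `>= 0`.
#' @param pixel_pitch object-plane sampling, micrometres per pixel.
#' @return list of class `"fibril_layer"`.
#' @export
fibril_layer <- function(rho_map, delta_map, pixel_pitch = 1.16) {
  if (!all(dim(rho_map) == dim(delta_map))) stop("map shapes must match")
  if (any(!is.finite(delta_map)) || any(delta_map < 0)) {
    stop("delta_map must be finite and >= 0")
  }
  structure(
    list(
      rho_map = rho_map %% pi, delta_map = delta_map,
      pixel_pitch = pixel_pitch
    ),
    class = "fibril_layer"
  )
}

#' Ordered stack of scattering layers
#'
#' @param layers list of [fibril_layer()] objects (length `p >= 1`), applied
#'   in order to the propagating field.
#' @param layer_shift lateral decorrelation offset between consecutive
#'   layers, pixels.
#' @return list of class `"scattering_stack"`.
#' @export
scattering_stack <- function(layers, layer_shift = 7) {
  if (length(layers) < 1) stop("need at least one layer")
  d <- dim(layers[[1]]$rho_map)
  for (l in layers) {
    if (!all(dim(l$rho_map) == d)) stop("all layers must share one shape")
  }
  structure(
    list(layers = layers, layer_shift = layer_shift),
    class = "scattering_stack"
  )
}

#' Construct a complex field
#'
#' Two co-registered rasters of complex amplitudes (x and y components) on a
#' common grid.
#'
#' @param ux,uy complex matrices of equal shape.
#' @param pixel_pitch micrometres per pixel.
#' @return list of class `"complex_field"`.
#' @export
complex_field <- function(ux, uy, pixel_pitch = 1.16) {
  if (!all(dim(ux) == dim(uy))) stop("ux and uy shapes must match")
  if (any(!is.finite(Mod(ux))) || any(!is.finite(Mod(uy)))) {
    stop("field must be finite")
  }
  structure(
    list(ux = ux, uy = uy, pixel_pitch = pixel_pitch),
    class = "complex_field"
  )
}

# von Mises sampler (Best & Fisher 1979); kappa = 0 falls back to uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) {
    return(runif(n, -pi, pi) + mu)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# smooth random surface: white noise blurred by a separable Gaussian
# kernel, rescaled to unit variance (so pnorm() of it is ~Uniform(0,1))
smooth_noise <- function(nr, nc, sigma) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  # circular convolution along both axes via FFT of the padded kernel
  kr <- numeric(nr); kr[(seq_along(k) - half - 1) %% nr + 1] <- k
  kc <- numeric(nc); kc[(seq_along(k) - half - 1) %% nc + 1] <- k
  zf <- fft(z) * outer(fft(kr), fft(kc))
  out <- Re(fft(zf, inverse = TRUE)) / (nr * nc)
  out / max(sd(out), .Machine$double.eps)
}

#' Generate one fibrillar birefringent layer
#'
#' Draws `n_fibrils` elongated strokes on an `size x size` raster.  Stroke
#' orientations follow a von Mises law (concentration `orientation_kappa`)
#' halved to `[0, pi)` about a seeded specimen orientation; within a stroke
#' the retardance tapers transversally as a Gaussian whose FWHM equals the
#' drawn fibril width (`fibril_width_um / pixel_pitch` pixels).  The
#' background carries a small parenchymal retardance floor with smoothly
#' varying axis orientation.
#'
#' @param preset a [phantom_preset()].
#' @param seed integer seed; identical seeds give bit-identical layers.
#' @param size raster side, pixels.
#' @param pixel_pitch micrometres per pixel (default 1.16: a 4.65 um camera
#'   pixel behind a 4x objective).
#' @return a [fibril_layer()] with attribute `mean_orientation`.
#' @export
generate_fibril_layer <- function(preset, seed, size = 256,
                                  pixel_pitch = 1.16) {
  if (size <= 0) stop("size must be positive")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- as.integer(size)
  # parenchymal background: smooth axis field, retardance floor
  rho_bg <- (smooth_noise(n, n, 8) * 3) %% pi
  delta <- matrix(preset$delta_floor, n, n) *
    (0.8 + 0.4 * pnorm(smooth_noise(n, n, 6) * 4))
  rho <- rho_bg
  mu <- runif(1, 0, pi) # specimen orientation
  nf <- preset$n_fibrils
  if (nf > 0) {
    widths_px <- runif(nf, preset$fibril_width_um[1],
                       preset$fibril_width_um[2]) / pixel_pitch
    thetas <- (rvonmises(nf, 2 * mu, preset$orientation_kappa) / 2) %% pi
    lens <- runif(nf, 0.15 * n, 0.5 * n)
    cx <- runif(nf, 1, n); cy <- runif(nf, 1, n)
    col_idx <- matrix(rep(seq_len(n), each = n), n, n)
    row_idx <- matrix(rep(seq_len(n), times = n), n, n)
    for (f in seq_len(nf)) {
      w <- widths_px[f]
      sigma <- w / (2 * sqrt(2 * log(2))) # FWHM = drawn width
      th <- thetas[f]
      dxv <- cos(th); dyv <- -sin(th) # image rows grow downward
      half <- lens[f] / 2
      reach <- half + 3 * w
      r0 <- max(1L, floor(cy[f] - reach)); r1 <- min(n, ceiling(cy[f] + reach))
      c0 <- max(1L, floor(cx[f] - reach)); c1 <- min(n, ceiling(cx[f] + reach))
      if (r0 > r1 || c0 > c1) next
      rr <- row_idx[r0:r1, c0:c1] - cy[f]
      cc <- col_idx[r0:r1, c0:c1] - cx[f]
      along <- cc * dxv + rr * dyv
      across <- -cc * dyv + rr * dxv
      endf <- pmin(1, pmax(0, (half + w / 2 - abs(along)) / w)) # end taper
      prof <- preset$delta_peak * exp(-across^2 / (2 * sigma^2)) * endf
      sub <- delta[r0:r1, c0:c1]
      take <- prof > sub
      sub[take] <- prof[take]
      delta[r0:r1, c0:c1] <- sub
      rsub <- rho[r0:r1, c0:c1]
      rsub[take & prof > 0.25 * preset$delta_peak] <- th
      rho[r0:r1, c0:c1] <- rsub
    }
  }
  out <- fibril_layer(rho, delta, pixel_pitch)
  attr(out, "mean_orientation") <- mu
  out
}

# vectorized application of the per-pixel LB Jones operator to a field
apply_jones_maps <- function(rho, delta, ux, uy) {
  c <- cos(rho); s <- sin(rho)
  ep <- exp(1i * delta / 2); em <- Conj(ep)
  j11 <- c^2 * ep + s^2 * em
  j12 <- c * s * (em - ep)
  j22 <- s^2 * ep + c^2 * em
  list(ux = j11 * ux + j12 * uy, uy = j12 * ux + j22 * uy)
}

#' Cascade a scattering stack over circular illumination
#'
#' Per pixel, the ordered product of layer Jones operators (layer `j`
#' laterally shifted by `(j-1) * layer_shift` pixels along both axes to
#' decorrelate the cascade) is applied to the right-circular unit Jones
#' vector `(1, i)/sqrt(2)`.  For a single layer this reproduces the
#' single-scattering field exactly.
#'
#' @param stack a [scattering_stack()].
#' @return a [complex_field()].
#' @export
cascade_field <- function(stack) {
  l1 <- stack$layers[[1]]
  d <- dim(l1$rho_map)
  ux <- matrix(complex(real = 1 / sqrt(2)), d[1], d[2])
  uy <- matrix(complex(imaginary = 1 / sqrt(2)), d[1], d[2])
  for (j in seq_along(stack$layers)) {
    l <- stack$layers[[j]]
    sh <- round((j - 1) * stack$layer_shift)
    rho <- shift_matrix(l$rho_map, sh)
    del <- shift_matrix(l$delta_map, sh)
    f <- apply_jones_maps(rho, del, ux, uy)
    ux <- f$ux; uy <- f$uy
  }
  complex_field(ux, uy, l1$pixel_pitch)
}

# circular (toroidal) shift of a matrix by s pixels along both axes
shift_matrix <- function(m, s) {
  if (s == 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  i <- ((seq_len(n1) - 1 + s) %% n1) + 1
  j <- ((seq_len(n2) - 1 + s) %% n2) + 1
  m[i, j, drop = FALSE]
}

#' Full phantom object field with ground truth
#'
#' Builds the coherent object field of one synthetic specimen: the
#' single-scattering field of the first layer, plus (for `n_layers > 1`) a
#' multiply scattered component obtained by cascading laterally shifted
#' copies of the layer, weighted by a smooth spatial envelope so that some
#' regions are single-scatter dominated and others diffuse.  The two
#' components add coherently (producing the interference-formed polarization
#' states), and a depolarized speckle background of the preset's degree is
#' attached as an incoherent ensemble.  The exact single-scatter azimuth and
#' ellipticity maps (closed form for circular probing) are exported as
#' ground truth.
#'
#' @param preset a [phantom_preset()] or preset name.
#' @param seed integer seed.
#' @param size raster side, pixels.
#' @param pixel_pitch micrometres per pixel.
#' @param multi_amplitude amplitude weight of the multiple-scattering
#'   component relative to the single-scattering one (0 disables it).
#' @param layer_shift lateral decorrelation shift between cascade layers,
#'   pixels.
#' @param n_speckle ensemble size for the depolarized background.
#' @return list of class `"phantom"` with elements `field` (a
#'   [complex_field()] or ensemble), `single` (the pure single-scatter
#'   field), `layer`, `truth` (list `alpha`, `beta`), `preset`, `seed`.
#' @export
phantom_field <- function(preset, seed, size = 256, pixel_pitch = 1.16,
                          multi_amplitude = 0.35, layer_shift = 7,
                          n_speckle = 32) {
  if (is.character(preset)) preset <- phantom_preset(preset)
  layer <- generate_fibril_layer(preset, seed, size, pixel_pitch)
  single <- cascade_field(scattering_stack(list(layer)))
  truth <- single_scatter_truth(layer$rho_map, layer$delta_map)
  field <- single
  if (preset$n_layers > 1 && multi_amplitude > 0) {
    set.seed((as.integer(seed) + 104729L) %% .Machine$integer.max)
    stack <- scattering_stack(
      rep(list(layer), preset$n_layers), layer_shift = layer_shift
    )
    multi <- cascade_field(stack)
    env <- pnorm(smooth_noise(size, size, 12) * 3) # 0..1 smooth envelope
    w <- multi_amplitude * env
    field <- complex_field(
      single$ux + w * multi$ux, single$uy + w * multi$uy, pixel_pitch
    )
  }
  if (preset$depol_degree > 0) {
    field <- add_depolarized_background(
      field, preset$depol_degree,
      seed = (as.integer(seed) + 15485863L) %% .Machine$integer.max,
      n_speckle = n_speckle
    )
  }
  truth$beta_circular <- pi / 4 - truth$beta # probe-referenced ellipticity
  structure(
    list(
      field = field, single = single, layer = layer, truth = truth,
      preset = preset, seed = seed
    ),
    class = "phantom"
  )
}

#' Bimodal-phase validation phantom
#'
#' Synthetic field for validating the single-scattering plane detector: a
#' smooth region field whose "single-scatter" portion (about half the
#' raster) carries phase deviations drawn below `bound`, and whose
#' "multiple-scatter" portion carries deviations spread over
#' `(bound, pi]`, with clearly different polarization statistics, plus an
#' optional depolarized background.  The moments of the azimuth and
#' ellipticity maps are therefore approximately constant for sections up to
#' `bound` and shift beyond it, so the detected plane should fall at
#' `bound` (within one scan step).
#'
#' Construction is direct in Stokes space: per pixel the unit polarized
#' direction is `(s2, s3, s4) = (sgn*sqrt(1-w^2), w sin phi, w cos phi)`
#' with `phi` the prescribed phase deviation and `w` a smooth random
#' amplitude whose law differs between the two portions; the complex field
#' realizes that state with a random global phase.  All constituent maps
#' vary smoothly (correlation length ~6 px), so small-window Stokes
#' smoothing does not mix the populations.
#'
#' @param seed integer seed.
#' @param size raster side, pixels.
#' @param bound phase bound of the single-scatter population (default
#'   `pi/8`).
#' @param depol depolarization degree of the added background.
#' @param n_speckle ensemble size for the background.
#' @return list with `field` (ensemble or coherent field), `deviation`
#'   (the programmed phase-deviation map), `single_mask` (logical raster of
#'   the single-scatter portion).
#' @export
bimodal_phase_phantom <- function(seed, size = 256, bound = pi / 8,
                                  depol = 0.5, n_speckle = 96) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- as.integer(size)
  # two half-planes with a guard strip at the interface: smoothing-mixed
  # pixels otherwise acquire intermediate deviations and trickle into the
  # sections between the two bands; guard pixels sit at a very large
  # deviation, so interface mixtures only enter far beyond the bound
  rows <- row(matrix(0, n, n))
  guard_half <- 8L
  region <- rows <= n %/% 2 - guard_half
  guard <- abs(rows - (n %/% 2 - guard_half / 2)) <= guard_half
  q1 <- pnorm(smooth_noise(n, n, 12)) # smooth, ~uniform marginals
  q2 <- pnorm(smooth_noise(n, n, 12))
  q3 <- pnorm(smooth_noise(n, n, 12))
  # The scanning coordinate obeys tan(dev) = s3/s4, so any section mask
  # conditions on the polarization state itself: the conditional state
  # statistics of a broad deviation band necessarily drift as the mask
  # fills it.  The single-scatter portion therefore occupies a *narrow*
  # deviation band just below the bound (inside one default scan cell), so
  # consecutive sections below the bound see the same population and the
  # moments plateau.  The multiple-scatter portion sits at 1.15-2x the
  # bound (a cascade of two to three single-scatter retardances) with a
  # clearly different azimuth/ellipticity make-up, ending the plateau
  # within one step of the bound.  (A unit-intensity pure state has only
  # two degrees of freedom, so the maps cannot be made independent of the
  # scanning coordinate; narrowness of the band is what keeps the
  # in-plateau moments flat.)
  phi <- ifelse(region, bound * (0.88 + 0.06 * q1),
                bound * (1.35 + 0.65 * q1))
  phi[guard] <- 2.6 + 0.4 * q1[guard]
  # Single-scatter portion: s2 = 0 pins the azimuth at pi/4 with tiny,
  # symmetric, mask-independent noise scatter, so its moments are stable
  # under any sub-masking; the ellipticity tracks half the deviation
  # (narrow by construction).  Diffuse portion: s2 > 0 shifts the azimuth
  # and the ellipticity make-up, so every trajectory jumps at its onset.
  s2 <- ifelse(region & !guard, 0, 0.3 + 0.2 * q2)
  wp <- sqrt(pmax(0, 1 - s2^2))
  s3 <- wp * sin(phi)
  s4 <- wp * cos(phi)
  # realize the pure state: |ux|^2-|uy|^2 = s2, ux* uy = (s3 + i s4)/2
  chi <- 0.5 * acos(pmin(1, pmax(-1, s2)))
  dxy <- atan2(s4, s3)
  gph <- exp(2i * pi * q3)
  ux <- cos(chi) * gph
  uy <- sin(chi) * exp(1i * dxy) * gph
  f <- complex_field(ux, uy)
  if (depol > 0) {
    f <- add_depolarized_background(
      f, depol, seed = (as.integer(seed) + 7919L) %% .Machine$integer.max,
      n_speckle = n_speckle
    )
  }
  list(field = f, deviation = phi, single_mask = region)
}

# ---------------------------------------------------------------------------
# Depolarized background (incoherent speckle ensemble)
# ---------------------------------------------------------------------------

#' Add a depolarized speckle background to a field
#'
#' Depolarization is modelled as an incoherent ensemble: each of the
#' `n_speckle` realizations is the coherent field plus an independent
#' circular-Gaussian speckle field (uniform random phases, random
#' polarization), with the speckle power chosen so that the ensemble degree
#' of polarization of the mixture equals `1 - delta_pct`.  Downstream
#' consumers average per-pixel Stokes components over the ensemble.
#'
#' @param field a [complex_field()].
#' @param delta_pct target depolarization degree, in `[0, 1)`.
#' @param seed integer seed.
#' @param n_speckle ensemble size (default 32; see the methods vignette for
#'   why this exceeds the minimal 8).
#' @return for `delta_pct = 0` the input unchanged; otherwise a
#'   `"field_ensemble"`: list with `members` (list of [complex_field()]),
#'   `signal`, `pixel_pitch`.
#' @export
add_depolarized_background <- function(field, delta_pct, seed,
                                       n_speckle = 32) {
  if (delta_pct < 0 || delta_pct >= 1) stop("delta_pct must be in [0, 1)")
  if (delta_pct == 0) return(field)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  d <- dim(field$ux)
  i_sig <- mean(Mod(field$ux)^2 + Mod(field$uy)^2)
  i_noise <- delta_pct / (1 - delta_pct) * i_sig
  sdc <- sqrt(i_noise / 4) # per real/imag component, per x/y channel
  members <- vector("list", n_speckle)
  for (k in seq_len(n_speckle)) {
    nx <- matrix(complex(
      real = rnorm(prod(d), sd = sdc), imaginary = rnorm(prod(d), sd = sdc)
    ), d[1], d[2])
    ny <- matrix(complex(
      real = rnorm(prod(d), sd = sdc), imaginary = rnorm(prod(d), sd = sdc)
    ), d[1], d[2])
    members[[k]] <- complex_field(field$ux + nx, field$uy + ny,
                                  field$pixel_pitch)
  }
  structure(
    list(members = members, signal = field, pixel_pitch = field$pixel_pitch),
    class = "field_ensemble"
  )
}

#' Per-pixel Stokes rasters of a field or ensemble
#'
#' For a coherent field, the pointwise Stokes components; for an ensemble,
#' their per-pixel average over the members (the incoherent mixture).  An
#' optional boxcar window smooths each component spatially.
#'
#' @param field a [complex_field()] or `"field_ensemble"`.
#' @param window boxcar side for spatial smoothing (1 = none).
#' @param members `"all"`, `"odd"` or `"even"`: which ensemble members to
#'   average (the odd/even halves give statistically independent estimates,
#'   used to decouple section masking from map values).
#' @return list of rasters `s1, s2, s3, s4`; ensembles also carry the
#'   per-pixel component variances (`v2, v3, v4`) and member count `k` used
#'   by the unbiased polarization estimator.
#' @export
field_stokes <- function(field, window = 1,
                         members = c("all", "odd", "even")) {
  members <- match.arg(members)
  if (inherits(field, "complex_field")) {
    st <- amplitude_stokes(field$ux, field$uy)
  } else if (inherits(field, "field_ensemble")) {
    mems <- field$members
    if (members != "all") {
      idx <- seq_along(mems)
      mems <- mems[idx %% 2 == (members == "odd")]
    }
    k <- length(mems)
    acc <- NULL
    sq <- list(s2 = 0, s3 = 0, s4 = 0)
    for (m in mems) {
      s <- amplitude_stokes(m$ux, m$uy)
      if (is.null(acc)) acc <- s else for (nm in names(s)) {
        acc[[nm]] <- acc[[nm]] + s[[nm]]
      }
      sq$s2 <- sq$s2 + s$s2^2; sq$s3 <- sq$s3 + s$s3^2; sq$s4 <- sq$s4 + s$s4^2
    }
    st <- lapply(acc, function(m) m / k)
    # Var(mean) = sample variance / k, per Stokes component and pixel
    vm <- function(sumsq, mean) {
      v <- (sumsq - k * mean^2) / max(1, k - 1) / k
      v[v < 0] <- 0
      v
    }
    st$v2 <- vm(sq$s2, st$s2)
    st$v3 <- vm(sq$s3, st$s3)
    st$v4 <- vm(sq$s4, st$s4)
    st$k <- k
  } else {
    stop("field must be a complex_field or field_ensemble")
  }
  if (window > 1) {
    for (nm in intersect(names(st), c("s1", "s2", "s3", "s4"))) {
      st[[nm]] <- boxcar2(st[[nm]], window)
    }
    if (!is.null(st$v2)) {
      for (nm in c("v2", "v3", "v4")) st[[nm]] <- boxcar2(st[[nm]], window) /
          window^2
    }
  }
  st
}

# separable boxcar mean filter with edge renormalization
boxcar2 <- function(m, w) {
  if (w <= 1) return(m)
  half <- (w - 1) %/% 2
  band <- function(n) {
    b <- matrix(0, n, n)
    idx <- abs(row(b) - col(b)) <= half
    idx[abs(row(b) - col(b)) == half + 1 & w %% 2 == 0 &
          row(b) > col(b)] <- TRUE # even widths take one extra trailing tap
    b[idx] <- 1
    b
  }
  b1 <- band(nrow(m)); b2 <- band(ncol(m))
  num <- b1 %*% m %*% b2
  den <- b1 %*% matrix(1, nrow(m), ncol(m)) %*% b2
  num / den
}

#' Measure the depolarization degree of a field
#'
#' Estimates `1 - |<S_pol>| / <S1>`.  For a coherent field the averaging is
#' spatial: Stokes components are averaged over sliding `window x window`
#' boxcars and the polarized magnitude is ratioed against the mean
#' intensity, then averaged over the raster.  For an ensemble the averaging
#' is over the members per pixel, with an unbiased estimate of
#' `|mean Stokes|^2` (the sampling-variance term of the finite ensemble is
#' subtracted) so that small ensembles do not report spuriously high
#' polarization.
#'
#' @param field a [complex_field()] or `"field_ensemble"`.
#' @param window boxcar side, `>= 2`, used in the coherent (spatial) mode.
#' @return estimated depolarization degree in `[0, 1]`.
#' @export
measure_depolarization <- function(field, window = 8) {
  if (window < 2) stop("window must be >= 2")
  if (inherits(field, "field_ensemble")) {
    st <- field_stokes(field)
    # unbiased |mean Stokes|^2 per pixel (may dip below zero); average over
    # window x window blocks BEFORE the square root so the concavity of
    # sqrt does not bias the polarized magnitude down, then weight by
    # intensity (a mean of per-pixel ratios is biased wherever the signal
    # intensity varies across the raster)
    pol2 <- st$s2^2 + st$s3^2 + st$s4^2 - (st$v2 + st$v3 + st$v4)
    bi <- (seq_len(nrow(pol2)) - 1) %/% window
    bj <- (seq_len(ncol(pol2)) - 1) %/% window
    blk <- function(m) rowsum(t(rowsum(m, bi)), bj)
    # per-block polarized fraction sqrt(<pol^2>/<s1^2>): exact when the
    # polarized fraction is spatially uniform, immune to the intensity
    # profile of the signal within a block
    p <- sqrt(pmax(0, blk(pol2) / blk(st$s1^2)))
    w <- blk(st$s1)
    return(min(1, max(0, 1 - sum(p * w) / sum(w))))
  }
  st <- amplitude_stokes(field$ux, field$uy)
  n1 <- nrow(st$s1); n2 <- ncol(st$s1)
  if (n1 < window || n2 < window) stop("window larger than raster")
  # non-overlapping windows: unbiased spatial mean per block
  bi <- (seq_len(n1) - 1) %/% window
  bj <- (seq_len(n2) - 1) %/% window
  block <- function(m) {
    rowsum(t(rowsum(m, bi)), bj) # sums per block (transposed)
  }
  cnt <- block(matrix(1, n1, n2))
  m2 <- block(st$s2) / cnt; m3 <- block(st$s3) / cnt; m4 <- block(st$s4) / cnt
  q2 <- block(st$s2^2) / cnt; q3 <- block(st$s3^2) / cnt
  q4 <- block(st$s4^2) / cnt
  nn <- cnt
  # unbiased |mean|^2: subtract Var(mean) = (E x^2 - (E x)^2) / (n-1)
  corr <- ((q2 - m2^2) + (q3 - m3^2) + (q4 - m4^2)) * nn / (nn - 1) / nn
  pol2 <- pmax(0, m2^2 + m3^2 + m4^2 - corr)
  s1m <- block(st$s1) / cnt
  min(1, max(0, 1 - sum(sqrt(pol2)) / sum(s1m)))
}
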