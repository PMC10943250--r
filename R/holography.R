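# ---------------------------------------------------------------------------
# Off-axis interferogram recording and Fourier-sideband demodulation
# ---------------------------------------------------------------------------

#' Construct an interferogram
#'
#' @param intensity m x n non-negative intensity raster.
#' @param analyzer_omega analyzer transmission-plane angle, 0 or 90 degrees.
#' @param carrier spatial carrier `(u0, v0)` in cycles/pixel, both below
#'   Nyquist.
#' @param ref_amplitude reference-beam amplitude used at recording (kept so
#'   the demodulator can rescale the recovered amplitudes).
#' @param quantize_bits bit depth if the raster was quantized, else `NULL`.
#' @param scale intensity-to-count scale used at quantization.
#' @return list of class `"interferogram"`.
#' @export
interferogram <- function(intensity, analyzer_omega, carrier,
                          ref_amplitude = NULL, quantize_bits = NULL,
                          scale = NULL) {
  if (any(intensity < 0)) stop("intensity must be non-negative")
  if (any(abs(carrier) >= 0.5)) stop("carrier must be below Nyquist")
  if (!analyzer_omega %in% c(0, 90)) stop("analyzer_omega must be 0 or 90")
  structure(
    list(
      intensity = intensity, analyzer_omega = analyzer_omega,
      carrier = carrier, ref_amplitude = ref_amplitude,
      quantize_bits = quantize_bits, scale = scale
    ),
    class = "interferogram"
  )
}

# off-axis carrier phase ramp, x = column index, origin top-left
carrier_ramp <- function(nr, nc, carrier) {
  2 * pi * (outer(rep(1, nr), (seq_len(nc) - 1)) * carrier[1] +
              outer((seq_len(nr) - 1), rep(1, nc)) * carrier[2])
}

#' Record the analyzer-resolved off-axis interferogram pair
#'
#' Digital twin of the recording step: the object field interferes with a
#' tilted right-circular reference beam of amplitude `ref_amplitude`, and
#' the camera records the intensity behind an analyzer at 0 deg (passing the
#' x components) and at 90 deg (y components):
#' `I_omega = |u_omega + r_omega exp(i 2 pi (u0 x + v0 y))|^2`.
#' Optional quantization emulates the camera's 8-bit dynamic range.
#'
#' @param field a [complex_field()].
#' @param ref_amplitude reference amplitude (must be positive); the
#'   reference is right-circular, so its x and y analyzer components are
#'   `r/sqrt(2)` and `i r/sqrt(2)`.
#' @param carrier `(u0, v0)` cycles/pixel, below Nyquist.
#' @param quantize_bits integer bit depth (e.g. 8) or `NULL` for ideal
#'   recording.
#' @return list with elements `omega0` and `omega90`, both
#'   [interferogram()] objects.
#' @export
record_interferograms <- function(field, ref_amplitude = 2,
                                  carrier = c(1 / 8, 1 / 8),
                                  quantize_bits = NULL) {
  if (ref_amplitude <= 0) stop("ref_amplitude must be positive")
  if (any(abs(carrier) >= 0.5)) stop("carrier must be below Nyquist")
  d <- dim(field$ux)
  ramp <- exp(1i * carrier_ramp(d[1], d[2], carrier))
  rx <- ref_amplitude / sqrt(2)
  ry <- complex(imaginary = ref_amplitude / sqrt(2))
  i0 <- Mod(field$ux + rx * ramp)^2
  i90 <- Mod(field$uy + ry * ramp)^2
  scl <- NULL
  if (!is.null(quantize_bits)) {
    top <- 2^quantize_bits - 1
    scl <- max(i0, i90) / top
    i0 <- round(i0 / scl)
    i90 <- round(i90 / scl)
  }
  list(
    omega0 = interferogram(i0, 0, carrier, ref_amplitude, quantize_bits, scl),
    omega90 = interferogram(i90, 90, carrier, ref_amplitude, quantize_bits,
                            scl)
  )
}

# cosine-tapered circular window centred at (uc, vc) cycles/pixel, on the
# FFT frequency grid of an nr x nc raster
sideband_window <- function(nr, nc, uc, vc, radius, taper = 0.3) {
  fu <- (seq_len(nc) - 1) / nc
  fu[fu >= 0.5] <- fu[fu >= 0.5] - 1
  fv <- (seq_len(nr) - 1) / nr
  fv[fv >= 0.5] <- fv[fv >= 0.5] - 1
  du <- fu - uc; du <- du - round(du) # wrap to nearest alias
  dv <- fv - vc; dv <- dv - round(dv)
  r <- sqrt(outer(dv^2, du^2, `+`))
  w <- matrix(0, nr, nc)
  flat <- radius * (1 - taper)
  w[r <= flat] <- 1
  ramp <- r > flat & r < radius
  w[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - flat) / (radius - flat)))
  w
}

#' Reconstruct the complex field from an interferogram pair
#'
#' Fourier demodulation: each interferogram is Fourier transformed, the
#' sideband carrying `U * conj(reference)` (centred at minus the carrier) is
#' selected with a cosine-tapered circular window, shifted to baseband and
#' inverse transformed.  The 0-deg channel yields `ux` and the 90-deg
#' channel `uy`; because both share one reference arm, the inter-component
#' phase `delta_x - delta_y` is preserved across the pair.  The known
#' reference polarization (circular) is divided out, and the global phase
#' gauge is fixed by zeroing the spatial median phase of the `ux` channel.
#'
#' @param pair list with `omega0` and `omega90` interferograms (as returned
#'   by [record_interferograms()]).
#' @param carrier `(u0, v0)` used at recording (default: taken from the
#'   pair).
#' @param filter_radius sideband window radius, cycles/pixel; default half
#'   the carrier magnitude.
#' @param ref_amplitude reference amplitude for absolute rescaling; default
#'   taken from the pair, 1 if unknown (polarization quantities do not
#'   depend on it).
#' @param pixel_pitch micrometres per pixel for the reconstructed field.
#' @param gauge fix the global phase (zero the spatial median phase of the
#'   `ux` channel); polarization quantities are invariant either way.
#' @return a [complex_field()] with attribute `residual`, a relative
#'   re-synthesis error of the demodulated pair.  A warning is issued when
#'   the sideband window overlaps the DC term.
#' @export
fourier_demodulate <- function(pair, carrier = NULL, filter_radius = NULL,
                               ref_amplitude = NULL, pixel_pitch = 1.16,
                               gauge = TRUE) {
  if (is.null(carrier)) carrier <- pair$omega0$carrier
  if (is.null(ref_amplitude)) {
    ref_amplitude <- pair$omega0$ref_amplitude
    if (is.null(ref_amplitude)) ref_amplitude <- 1
  }
  cmag <- sqrt(sum(carrier^2))
  if (is.null(filter_radius)) filter_radius <- cmag / 2
  if (filter_radius >= cmag) {
    warning("sideband window reaches the DC term: degraded reconstruction")
  }
  demod_one <- function(ig) {
    i <- ig$intensity
    if (!is.null(ig$scale)) i <- i * ig$scale
    d <- dim(i)
    w <- sideband_window(d[1], d[2], -carrier[1], -carrier[2], filter_radius)
    ft <- fft(i)
    side <- fft(ft * w, inverse = TRUE) / length(i)
    ramp <- exp(1i * carrier_ramp(d[1], d[2], carrier))
    side * ramp # = U * conj(r_omega), low-passed
  }
  rx <- ref_amplitude / sqrt(2)
  ry <- complex(imaginary = ref_amplitude / sqrt(2))
  ux <- demod_one(pair$omega0) / Conj(rx)
  uy <- demod_one(pair$omega90) / Conj(ry)
  # residual (pre-gauge): relative RMS mismatch between the recorded
  # interferograms and their re-synthesis from the reconstruction
  d <- dim(ux)
  ramp <- exp(1i * carrier_ramp(d[1], d[2], carrier))
  resyn0 <- Mod(ux + rx * ramp)^2
  resyn90 <- Mod(uy + ry * ramp)^2
  rec0 <- pair$omega0$intensity
  if (!is.null(pair$omega0$scale)) rec0 <- rec0 * pair$omega0$scale
  rec90 <- pair$omega90$intensity
  if (!is.null(pair$omega90$scale)) rec90 <- rec90 * pair$omega90$scale
  res <- 0.5 * (
    sqrt(mean((resyn0 - rec0)^2)) / mean(rec0) +
      sqrt(mean((resyn90 - rec90)^2)) / mean(rec90)
  )
  if (gauge) {
    # global phase gauge: spatial median phase of ux, taken about the mean
    # phase to stay clear of the wrap
    g0 <- Arg(sum(ux))
    g <- g0 + median(Arg(ux * exp(-1i * g0)))
    ux <- ux * exp(-1i * g)
    uy <- uy * exp(-1i * g)
  }
  out <- complex_field(ux, uy, pixel_pitch)
  attr(out, "residual") <- res
  out
}

#' Align one field onto another up to a global phase
#'
#' Reconstruction is defined only up to one global phase; this helper
#' applies the least-squares optimal rotation of `field` onto `reference`
#' before pointwise comparison.
#'
#' @param field,reference [complex_field()] objects of one shape.
#' @return `field` rotated by the optimal global phase.
#' @export
align_global_phase <- function(field, reference) {
  z <- sum(Conj(field$ux) * reference$ux + Conj(field$uy) * reference$uy)
  g <- exp(1i * Arg(z))
  complex_field(field$ux * g, field$uy * g, field$pixel_pitch)
}

#' Record and demodulate an ensemble field member-wise
#'
#' Convenience wrapper for depolarized (ensemble) fields: records and
#' demodulates every member with identical settings and returns the
#' reconstructed ensemble, so per-pixel Stokes averaging can proceed as on
#' the source ensemble.
#'
#' @param field a [complex_field()] or `"field_ensemble"`.
#' @inheritParams record_interferograms
#' @inheritParams fourier_demodulate
#' @return a [complex_field()] or `"field_ensemble"` of reconstructions.
#' @export
holographic_roundtrip <- function(field, ref_amplitude = 2,
                                  carrier = c(1 / 8, 1 / 8),
                                  quantize_bits = NULL,
                                  filter_radius = NULL) {
  one <- function(f) {
    pair <- record_interferograms(f, ref_amplitude, carrier, quantize_bits)
    fourier_demodulate(pair, carrier, filter_radius,
                       ref_amplitude = ref_amplitude,
                       pixel_pitch = f$pixel_pitch)
  }
  if (inherits(field, "field_ensemble")) {
    structure(
      list(
        members = lapply(field$members, one),
        signal = one(field$signal), pixel_pitch = field$pixel_pitch
      ),
      class = "field_ensemble"
    )
  } else {
    one(field)
  }
}
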