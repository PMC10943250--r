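#' @importFrom stats fft median pnorm rnorm runif sd var
#' @importFrom utils read.csv write.csv modifyList
NULL

# ---------------------------------------------------------------------------
# Stokes vectors
# ---------------------------------------------------------------------------

#' Construct a Stokes vector
#'
#' A Stokes vector holds the four real components `(s1, s2, s3, s4)` of a
#' polarization state: total intensity, the two linear components and the
#' circular component.  Components follow the convention
#' `s2 = |ux|^2 - |uy|^2`, `s3 = 2 Re(ux* uy)`, `s4 = 2 Im(ux* uy)`, so the
#' right-circular probe beam used throughout the package is `(1, 0, 0, 1)`.
#'
#' @param s1,s2,s3,s4 real components; `s1` must be positive.
#' @return numeric vector of length 4 with class `"stokes"`.
#' @export
stokes_vector <- function(s1, s2, s3, s4) {
  v <- c(s1, s2, s3, s4)
  if (!all(is.finite(v))) stop("Stokes components must be finite")
  if (s1 <= 0) stop("s1 must be positive")
  structure(as.numeric(v), class = "stokes")
}

#' Right-circular probe Stokes vector
#'
#' The illumination used by the method: a right-circularly polarized beam,
#' `S = (1, 0, 0, 1)`.  Circular probing makes the object response invariant
#' to rotation of the sample about the beam axis.
#'
#' @return a [stokes_vector()].
#' @export
stokes_circular <- function() stokes_vector(1, 0, 0, 1)

#' Degree of polarization of a Stokes vector
#' @param S a Stokes vector (length-4 numeric).
#' @return `sqrt(s2^2+s3^2+s4^2)/s1`, in `[0, 1]` for physical states.
#' @export
stokes_dop <- function(S) {
  sqrt(sum(S[2:4]^2)) / S[1]
}

# ---------------------------------------------------------------------------
# Linear-birefringence Mueller matrix
# ---------------------------------------------------------------------------

#' Mueller matrix of a linear-birefringence element
#'
#' Pure linear retarder with optical-axis orientation `rho` and phase
#' retardance `delta = 2*pi*dn*d/lambda`.  The lower-right 3x3 block is a
#' proper rotation of the Poincare sphere by angle `delta` about an
#' equatorial axis, oriented so that a circular probe maps to
#' `(1, sin 2rho sin delta, cos 2rho sin delta, cos delta)`.
#'
#' @param rho optical-axis orientation in radians (reduced modulo pi).
#' @param delta retardance in radians, `>= 0`.
#' @return 4x4 numeric matrix of class `"lb_mueller"` with attributes
#'   `rho` and `delta`.
#' @export
#' @examples
#' lb_mueller(pi / 6, pi / 2) %*% stokes_circular()
lb_mueller <- function(rho, delta) {
  if (!is.finite(rho) || !is.finite(delta)) stop("rho and delta must be finite")
  if (delta < 0) stop("delta must be >= 0")
  rho <- rho %% pi
  c2 <- cos(2 * rho); s2 <- sin(2 * rho)
  k <- cos(delta); t <- sin(delta)
  M <- matrix(0, 4, 4)
  M[1, 1] <- 1
  M[2, 2] <- c2^2 + s2^2 * k
  M[2, 3] <- -c2 * s2 * (1 - k)
  M[2, 4] <- s2 * t
  M[3, 2] <- -c2 * s2 * (1 - k)
  M[3, 3] <- s2^2 + c2^2 * k
  M[3, 4] <- c2 * t
  M[4, 2] <- -s2 * t
  M[4, 3] <- -c2 * t
  M[4, 4] <- k
  structure(M, class = c("lb_mueller", "matrix"), rho = rho, delta = delta)
}

#' Apply a Mueller matrix to a Stokes vector
#'
#' @param M 4x4 Mueller matrix.
#' @param S Stokes vector (length-4 numeric).
#' @return transformed Stokes vector (class `"stokes"`).
#' @export
apply_mueller <- function(M, S) {
  if (!is.matrix(M) || any(dim(M) != c(4, 4))) stop("M must be 4x4")
  if (length(S) != 4) stop("S must have length 4")
  out <- as.numeric(M %*% as.numeric(S))
  structure(out, class = "stokes")
}

# ---------------------------------------------------------------------------
# Jones layer (coherent-field equivalent)
# ---------------------------------------------------------------------------

#' Jones matrix of a linear-birefringence element
#'
#' Coherent-field counterpart of [lb_mueller()]: a unitary 2x2 operator on
#' the complex amplitude components `(ux, uy)`.  Its Mueller image under
#' [jones_to_mueller()] equals `lb_mueller(rho, delta)` exactly, which is the
#' contract that lets multiple-scattering cascades be run on complex fields.
#'
#' @inheritParams lb_mueller
#' @return 2x2 complex matrix of class `"lb_jones"`.
#' @export
lb_jones <- function(rho, delta) {
  if (!is.finite(rho) || !is.finite(delta)) stop("rho and delta must be finite")
  if (delta < 0) stop("delta must be >= 0")
  rho <- rho %% pi
  c <- cos(rho); s <- sin(rho)
  ep <- exp(1i * delta / 2); em <- exp(-1i * delta / 2)
  # R(rho) diag(e^{i d/2}, e^{-i d/2}) R(-rho) with R = [[c, s], [-s, c]];
  # this sign choice reproduces S2 = +sin 2rho sin delta for circular input.
  J <- matrix(c(
    c^2 * ep + s^2 * em, c * s * (em - ep),
    c * s * (em - ep), s^2 * ep + c^2 * em
  ), 2, 2, byrow = TRUE)
  structure(J, class = c("lb_jones", "matrix"), rho = rho, delta = delta)
}

#' Convert a Jones matrix to its Mueller matrix
#'
#' Uses the coherency-vector sandwich `M = A (J x J*) A^-1` with the
#' component convention of [stokes_vector()].  Valid for non-depolarizing
#' elements only.
#'
#' @param J 2x2 complex matrix.
#' @return 4x4 real Mueller matrix.
#' @export
jones_to_mueller <- function(J) {
  if (!is.matrix(J) || any(dim(J) != c(2, 2))) stop("J must be 2x2")
  A <- matrix(c(
    1, 0, 0, 1,
    1, 0, 0, -1,
    0, 1, 1, 0,
    0, 1i, -1i, 0
  ), 4, 4, byrow = TRUE)
  M <- A %*% (J %x% Conj(J)) %*% solve(A)
  Re(M)
}

# ---------------------------------------------------------------------------
# Polarization states (azimuth / ellipticity)
# ---------------------------------------------------------------------------

#' Construct a polarization state
#'
#' @param alpha azimuth of the polarization ellipse, radians in
#'   `[-pi/2, pi/2)`; the laboratory x-axis is the zero reference and the
#'   circular probe maps to `alpha = 0`.
#' @param beta ellipticity angle, radians in `[-pi/4, pi/4]`.
#' @param alpha_defined `FALSE` for circular (or unpolarized) states where
#'   the azimuth is undefined; `alpha` is then reported as the reproducible
#'   reference value 0.
#' @return list of class `"polarization_state"`.
#' @export
polarization_state <- function(alpha, beta, alpha_defined = TRUE) {
  structure(
    list(
      alpha = wrap_azimuth(alpha), beta = beta,
      alpha_defined = isTRUE(alpha_defined)
    ),
    class = "polarization_state"
  )
}

#' @export
print.polarization_state <- function(x, ...) {
  cat(sprintf(
    "polarization state: alpha = %.6f rad%s, beta = %.6f rad\n",
    x$alpha, if (x$alpha_defined) "" else " (undefined: circular)", x$beta
  ))
  invisible(x)
}

# wrap an azimuth to the principal range [-pi/2, pi/2)
wrap_azimuth <- function(a) {
  ((a + pi / 2) %% pi) - pi / 2
}

#' Azimuth and ellipticity from a Stokes vector
#'
#' `alpha = 0.5 atan2(s3, s2)` (two-argument form resolves the pi/2
#' ambiguity of the single-argument arctangent) and
#' `beta = 0.5 asin(s4 / s1)`, with the argument clamped to `[-1, 1]`.
#' With `normalize = "polarized"` the ellipticity is taken relative to the
#' polarized part, `beta = 0.5 asin(s4 / |s_pol|)`, which removes the
#' unpolarized intensity pedestal of ensemble-averaged Stokes maps.
#'
#' @param S Stokes vector.
#' @param normalize `"total"` (divide `s4` by `s1`) or `"polarized"`
#'   (divide by the polarized magnitude).
#' @param tol relative threshold on `sqrt(s2^2+s3^2)` below which the state
#'   is flagged circular and `alpha` is undefined.
#' @return a [polarization_state()].
#' @export
stokes_to_polarization <- function(S, normalize = c("total", "polarized"),
                                   tol = 1e-9) {
  normalize <- match.arg(normalize)
  S <- as.numeric(S)
  lin <- sqrt(S[2]^2 + S[3]^2)
  den <- if (normalize == "total") S[1] else sqrt(sum(S[2:4]^2))
  beta <- 0.5 * asin(pmin(1, pmax(-1, S[4] / den)))
  if (lin <= tol * abs(S[1])) {
    polarization_state(0, beta, alpha_defined = FALSE)
  } else {
    polarization_state(0.5 * atan2(S[3], S[2]), beta)
  }
}

#' Azimuth and ellipticity directly from complex amplitudes
#'
#' Implements the amplitude form of the Stokes relations:
#' `alpha = 0.5 atan2(2 Re(ux* uy), |ux|^2 - |uy|^2)`,
#' `beta  = 0.5 asin(2 Im(ux* uy) / (|ux|^2 + |uy|^2))`.
#' Agrees with [stokes_to_polarization()] of the Stokes vector built from
#' `(ux, uy)` on all states.
#'
#' @param ux,uy complex amplitude components at a point.
#' @return a [polarization_state()].
#' @export
amplitudes_to_polarization <- function(ux, uy) {
  if (abs(ux) + abs(uy) == 0) stop("ux and uy must not both be zero")
  s1 <- Mod(ux)^2 + Mod(uy)^2
  s2 <- Mod(ux)^2 - Mod(uy)^2
  cr <- Conj(ux) * uy
  stokes_to_polarization(c(s1, s2, 2 * Re(cr), 2 * Im(cr)))
}

#' Polarization state of two interfering orthogonal components
#'
#' State of the elliptically polarized wave formed by orthogonal components
#' with magnitudes `ux_mag`, `uy_mag` and inter-component phase shift
#' `delta_xy`.  Computed through the canonical amplitude path, i.e. it is by
#' construction identical to
#' `amplitudes_to_polarization(ux_mag, uy_mag * exp(1i * delta_xy))`.
#'
#' @param ux_mag,uy_mag non-negative component magnitudes (not both zero).
#' @param delta_xy phase of the y component relative to the x component,
#'   radians.
#' @return a [polarization_state()].
#' @export
interference_polarization <- function(ux_mag, uy_mag, delta_xy) {
  if (ux_mag < 0 || uy_mag < 0) stop("magnitudes must be >= 0")
  amplitudes_to_polarization(ux_mag + 0i, uy_mag * exp(1i * delta_xy))
}

# ---------------------------------------------------------------------------
# Vectorized (raster) forms used by the map-level pipeline
# ---------------------------------------------------------------------------

# clamp to [-1, 1] preserving dims (pmin/pmax with a scalar first
# argument silently drop the dim attribute)
clamp_unit <- function(x) {
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

# closed-form single-scatter polarization maps for (rho, delta) rasters:
# alpha = 0.5*atan2(cos 2rho sin delta, sin 2rho sin delta),
# beta  = 0.5*asin(cos delta)        (circular probe)
single_scatter_truth <- function(rho, delta) {
  t <- sin(delta)
  alpha <- wrap_azimuth(0.5 * atan2(cos(2 * rho) * t, sin(2 * rho) * t))
  alpha[t == 0] <- 0 # circular: undefined azimuth, reproducible reference
  beta <- 0.5 * asin(clamp_unit(cos(delta)))
  list(alpha = alpha, beta = beta)
}

# per-pixel Stokes components from amplitude rasters (list of 4 matrices)
amplitude_stokes <- function(ux, uy) {
  cr <- Conj(ux) * uy
  list(
    s1 = Mod(ux)^2 + Mod(uy)^2,
    s2 = Mod(ux)^2 - Mod(uy)^2,
    s3 = 2 * Re(cr),
    s4 = 2 * Im(cr)
  )
}

# map-level azimuth/ellipticity from Stokes rasters; circular pixels get
# alpha = 0 (flag raster returned alongside) so maps stay rectangular
stokes_maps_to_polarization <- function(st, normalize = "polarized",
                                        tol = 1e-9) {
  lin <- sqrt(st$s2^2 + st$s3^2)
  pol <- sqrt(st$s2^2 + st$s3^2 + st$s4^2)
  den <- if (normalize == "total") st$s1 else pol
  den[den == 0] <- .Machine$double.eps
  alpha <- wrap_azimuth(0.5 * atan2(st$s3, st$s2))
  circ <- lin <= tol * abs(st$s1)
  alpha[circ] <- 0
  beta <- 0.5 * asin(clamp_unit(st$s4 / den))
  list(alpha = alpha, beta = beta, circular = circ)
}
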