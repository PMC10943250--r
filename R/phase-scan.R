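# ---------------------------------------------------------------------------
# Phase-section scanning: isolating the single-scattering plane
# ---------------------------------------------------------------------------

#' Inter-component phase map of a field
#'
#' Per pixel, the phase of `uy` relative to `ux`, wrapped to `[0, 2*pi)`.
#' Pixels whose total amplitude is near zero are flagged `NA` (their phase
#' is meaningless).
#'
#' @param field a [complex_field()].
#' @param amp_tol relative amplitude threshold for flagging, as a fraction
#'   of the maximum pixel amplitude.
#' @return m x n numeric matrix of phases in `[0, 2*pi)`, with `NA` at
#'   flagged pixels.
#' @export
inter_component_phase <- function(field, amp_tol = 1e-6) {
  amp <- sqrt(Mod(field$ux)^2 + Mod(field$uy)^2)
  if (max(amp) == 0) stop("all-zero field")
  ph <- Arg(field$uy * Conj(field$ux)) %% (2 * pi)
  ph[amp <= amp_tol * max(amp)] <- NA_real_
  ph
}

#' Phase deviation from the circular-probe baseline
#'
#' The scanning coordinate of the method.  Under right-circular probing an
#' element with zero retardance leaves `uy = i * ux`, i.e. an
#' inter-component phase of `pi/2`; retardance (and, cumulatively, multiple
#' scattering) drives the phase away from that baseline.  The deviation
#' `|wrap(arg(uy conj(ux)) - pi/2)| = |atan2(s3, s4)|`, in `[0, pi]`, is
#' therefore zero for unscattered light and bounded by the accumulated
#' retardance for single scattering, which is what makes cumulative
#' phase sections select the singly scattered component.  Computable from
#' (possibly ensemble-averaged) Stokes rasters.
#'
#' @param field a [complex_field()], `"field_ensemble"`, or a Stokes raster
#'   list as returned by [field_stokes()].
#' @param window optional boxcar side for Stokes smoothing before the phase
#'   is formed.
#' @return m x n matrix of deviations in `[0, pi]`.
#' @export
phase_deviation <- function(field, window = 1) {
  st <- if (is.list(field) && !is.null(field$s3)) field else {
    field_stokes(field, window = window)
  }
  abs(atan2(st$s3, st$s4))
}

# boxcar-smooth the mean Stokes components of a prepared raster list
smooth_stokes <- function(st, window) {
  if (window <= 1) return(st)
  out <- st
  for (nm in intersect(names(st), c("s1", "s2", "s3", "s4"))) {
    out[[nm]] <- boxcar2(st[[nm]], window)
  }
  out
}

# scanning coordinate from Stokes rasters
section_phase <- function(st, phase) {
  if (phase == "deviation") {
    abs(atan2(st$s3, st$s4))
  } else {
    ph <- atan2(st$s4, st$s3) %% (2 * pi) # arg(uy conj(ux)) = atan2(s4, s3)
    ph
  }
}

#' Polarization map of one cumulative phase section
#'
#' Masks the pixels whose phase-scanning coordinate is at most `delta_t`
#' and computes the azimuth and ellipticity maps over the mask from the
#' (ensemble-averaged) Stokes rasters.  Sections are cumulative:
#' `mask(delta_t1)` is a subset of `mask(delta_t2)` whenever
#' `delta_t1 < delta_t2`, and `delta_t = 2*pi` covers every valid pixel.
#'
#' @param field a [complex_field()] or `"field_ensemble"`.
#' @param delta_t section bound, radians, in `(0, 2*pi]`.
#' @param phase `"deviation"` (default: deviation from the circular
#'   baseline, see [phase_deviation()]) or `"raw"` (literal
#'   inter-component phase).
#' @param window boxcar side for Stokes smoothing.
#' @param normalize ellipticity normalization, see
#'   [stokes_to_polarization()].
#' @param beta_reference `"circular"` (default): ellipticity referenced to
#'   the circular probe, `pi/4 - beta_abs`, the method's stated zero
#'   reference (for single scattering it equals half the retardance);
#'   `"absolute"`: the ellipse shape angle itself, in `[-pi/4, pi/4]`.
#' @param phase_window boxcar side used for the scanning coordinate only
#'   (defaults to `window`); a larger value regularizes the section mask
#'   against background speckle noise without blurring the maps.
#' @param split_mask for ensemble fields with at least 4 members, estimate
#'   the scanning coordinate from the odd members and the maps from the
#'   even members, so mask selection does not act on the maps' own noise
#'   (which would bias the section statistics).
#' @return list of class `"polarization_map"`: `alpha_map`, `beta_map`
#'   (radians; entries outside the mask are `NA`), `mask` (logical),
#'   `delta_t`, `fill_fraction`.
#' @export
section_map <- function(field, delta_t, phase = c("deviation", "raw"),
                        window = 1, normalize = "polarized",
                        beta_reference = c("circular", "absolute"),
                        phase_window = window, split_mask = TRUE) {
  phase <- match.arg(phase)
  beta_reference <- match.arg(beta_reference)
  if (delta_t <= 0 || delta_t > 2 * pi) stop("delta_t must be in (0, 2*pi]")
  split <- split_mask && inherits(field, "field_ensemble") &&
    length(field$members) >= 4
  st <- smooth_stokes(
    field_stokes(field, window = 1, members = if (split) "even" else "all"),
    window
  )
  raw_mask <- if (split) field_stokes(field, window = 1, members = "odd")
  else st
  ph <- section_phase(smooth_stokes(raw_mask, phase_window), phase)
  mask <- is.finite(ph) & ph <= delta_t & st$s1 > 0
  if (!any(mask)) stop("empty phase section at delta_t = ", delta_t)
  pol <- stokes_maps_to_polarization(st, normalize = normalize)
  alpha <- pol$alpha
  beta <- if (beta_reference == "circular") pi / 4 - pol$beta else pol$beta
  alpha[!mask] <- NA_real_
  beta[!mask] <- NA_real_
  structure(
    list(
      alpha_map = alpha, beta_map = beta, mask = mask, delta_t = delta_t,
      fill_fraction = mean(mask)
    ),
    class = "polarization_map"
  )
}

#' Statistical moments of a masked sample
#'
#' First- to fourth-order moments in two conventions.  `"paper"` mode is the
#' literal marker definition used throughout the method: `Z1` the mean,
#' `Z2` the raw mean of squares, and `Z3`, `Z4` the raw third and fourth
#' moments normalized by the printed integer powers `Z2^3` and `Z2^4`.
#' `"standard"` mode gives the conventional central variance, skewness and
#' excess-free kurtosis.
#'
#' @param values numeric vector or masked raster (`NA`s dropped); at least
#'   2 finite values required.
#' @param mode `"paper"` or `"standard"`.
#' @return list of class `"moment_set"` with `z1`, `z2`, `z3`, `z4`,
#'   `mode`, `n`.  Higher moments are `NA` when undefined (zero spread).
#' @export
moments <- function(values, mode = c("paper", "standard")) {
  mode <- match.arg(mode)
  x <- as.numeric(values)
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 values")
  n <- length(x)
  if (mode == "paper") {
    z1 <- mean(x)
    z2 <- mean(x^2)
    z3 <- if (z2 > 0) mean(x^3) / z2^3 else NA_real_
    z4 <- if (z2 > 0) mean(x^4) / z2^4 else NA_real_
  } else {
    z1 <- mean(x)
    z2 <- mean((x - z1)^2)
    s <- sqrt(z2)
    z3 <- if (s > 0) mean((x - z1)^3) / s^3 else NA_real_
    z4 <- if (s > 0) mean((x - z1)^4) / s^4 else NA_real_
  }
  structure(list(z1 = z1, z2 = z2, z3 = z3, z4 = z4, mode = mode, n = n),
            class = "moment_set")
}

#' Scan the field over cumulative phase sections
#'
#' Sweeps the section bound over `delta_t = d_step, 2*d_step, ..., 2*pi`
#' and records the four statistical moments of the azimuth and ellipticity
#' maps in every section.  Implemented by sorting pixels once on the
#' scanning coordinate and accumulating power sums, so the full trajectory
#' costs one pass.
#'
#' @inheritParams section_map
#' @param d_step scan step, radians (default `pi/40`).
#' @param mode moment convention, see [moments()].
#' @param min_pixels smallest mask size for which moments are reported;
#'   default `NULL` uses 5 percent of the valid pixels (at least 16), so
#'   statistically meaningless micro-sections do not enter the plateau
#'   test.
#' @return list of class `"phase_scan"`: `delta_t_grid`, `n_pixels`,
#'   `moments_alpha` and `moments_beta` (matrices, one row per step,
#'   columns `z1..z4`), `mode`.
#' @export
phase_scan <- function(field, d_step = pi / 40, phase = "deviation",
                       window = 1, normalize = "polarized",
                       mode = "paper", min_pixels = NULL,
                       beta_reference = c("circular", "absolute"),
                       phase_window = window, split_mask = TRUE) {
  beta_reference <- match.arg(beta_reference)
  split <- split_mask && inherits(field, "field_ensemble") &&
    length(field$members) >= 4
  st <- smooth_stokes(
    field_stokes(field, window = 1, members = if (split) "even" else "all"),
    window
  )
  raw_mask <- if (split) field_stokes(field, window = 1, members = "odd")
  else st
  ph <- section_phase(smooth_stokes(raw_mask, phase_window), phase)
  pol <- stokes_maps_to_polarization(st, normalize = normalize)
  if (beta_reference == "circular") pol$beta <- pi / 4 - pol$beta
  ok <- is.finite(ph) & is.finite(pol$alpha) & is.finite(pol$beta)
  phv <- ph[ok]
  if (is.null(min_pixels)) min_pixels <- max(16, round(0.05 * length(phv)))
  ord <- order(phv)
  phs <- phv[ord]
  grid <- seq(d_step, 2 * pi + 1e-12, by = d_step)
  counts <- findInterval(grid, phs)
  scan_one <- function(vals) {
    v <- vals[ok][ord]
    cs1 <- cumsum(v); cs2 <- cumsum(v^2)
    cs3 <- cumsum(v^3); cs4 <- cumsum(v^4)
    out <- matrix(NA_real_, length(grid), 4,
                  dimnames = list(NULL, c("z1", "z2", "z3", "z4")))
    use <- counts >= min_pixels
    nn <- counts[use]
    m1 <- cs1[nn] / nn; m2 <- cs2[nn] / nn
    m3 <- cs3[nn] / nn; m4 <- cs4[nn] / nn
    if (identical(mode, "paper")) {
      out[use, ] <- cbind(m1, m2, ifelse(m2 > 0, m3 / m2^3, NA),
                          ifelse(m2 > 0, m4 / m2^4, NA))
    } else {
      cv <- pmax(0, m2 - m1^2)
      s <- sqrt(cv)
      mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
      mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
      out[use, ] <- cbind(m1, cv, ifelse(s > 0, mu3 / s^3, NA),
                          ifelse(s > 0, mu4 / s^4, NA))
    }
    out
  }
  structure(
    list(
      delta_t_grid = grid, n_pixels = counts,
      moments_alpha = scan_one(pol$alpha),
      moments_beta = scan_one(pol$beta),
      mode = mode
    ),
    class = "phase_scan"
  )
}

#' Detect the single-scattering phase plane
#'
#' Finds the largest section bound `delta_t_star` such that all eight
#' moment trajectories (`Z1..Z4` of azimuth and of ellipticity) are
#' mutually consistent over every step up to it: the statistical condition
#' of single scattering, "moments approximately constant below the bound".
#' The change between consecutive steps is measured relative to the running
#' maximum magnitude of each trajectory, so near-zero trajectories do not
#' produce spurious relative jumps.
#'
#' @param scan a [phase_scan()] result.
#' @param rel_tol largest tolerated step-to-step relative change (default
#'   0.05).
#' @param cap optional upper bound imposed on the returned plane (e.g.
#'   `pi/8`); `NULL` for none.
#' @return the detected `delta_t_star` in radians, with attribute `index`
#'   (grid position).  Signals an error of class `"holopolar_no_plateau"`
#'   when even the first two usable steps disagree.
#' @export
find_single_scatter_plane <- function(scan, rel_tol = 0.05, cap = NULL) {
  grid <- scan$delta_t_grid
  if (length(grid) < 3) stop("need at least 3 grid steps")
  tr <- cbind(scan$moments_alpha, scan$moments_beta)
  usable <- rowSums(is.finite(tr)) == ncol(tr)
  first <- which(usable)[1]
  if (is.na(first) || sum(usable) < 2) {
    stop(structure(
      class = c("holopolar_no_plateau", "error", "condition"),
      list(message = "no usable scan steps", call = sys.call())
    ))
  }
  idx <- which(usable)
  runmax <- apply(abs(tr[idx, , drop = FALSE]), 2, cummax)
  dz <- abs(apply(tr[idx, , drop = FALSE], 2, diff))
  rel <- dz / pmax(runmax[-1, , drop = FALSE], .Machine$double.eps)
  okstep <- rowSums(rel <= rel_tol) == ncol(rel)
  if (!okstep[1]) {
    stop(structure(
      class = c("holopolar_no_plateau", "error", "condition"),
      list(
        message = "moments drift from the first step: no plateau",
        call = sys.call()
      )
    ))
  }
  last <- if (all(okstep)) length(okstep) else which(!okstep)[1] - 1
  i_star <- idx[last + 1] # plateau covers steps idx[1] .. idx[last+1]
  d_star <- grid[i_star]
  if (!is.null(cap) && d_star > cap) {
    i_star <- max(which(grid <= cap))
    d_star <- grid[i_star]
  }
  structure(d_star, index = i_star)
}
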