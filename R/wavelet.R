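# ---------------------------------------------------------------------------
# Row-wise Mexican-hat continuous wavelet transform and scale markers
# ---------------------------------------------------------------------------

#' Mexican-hat (MHAT) wavelet
#'
#' Second derivative of a Gaussian, in the standard normalization
#' `psi(x) = (1 - x^2) exp(-x^2 / 2)`: `psi(0) = 1`, zero crossings at
#' `x = +-1`, zero mean (admissibility).
#'
#' @param x numeric vector.
#' @return wavelet values.
#' @export
mhat <- function(x) {
  if (any(!is.finite(x))) stop("x must be finite")
  (1 - x^2) * exp(-x^2 / 2)
}

# kernel half-support in samples at scale a: exp(-x^2/2) < 1e-12 beyond ~7.4
mhat_reach <- function(a) ceiling(8 * a)

# fold an out-of-range index into 1..n by whole-sample mirror reflection
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# dense CWT operator at one scale: n x n matrix K with
# W(b,) = K %*% signal, K[b, fold(x)] += psi((x - b)/a) / sqrt(a)
cwt_kernel <- function(n, a) {
  reach <- mhat_reach(a)
  off <- (-reach):reach
  psi <- mhat(off / a) / sqrt(a)
  K <- matrix(0, n, n)
  for (b in seq_len(n)) {
    cols <- reflect_index(b + off, n)
    # accumulate: several extended samples may fold onto one column
    rs <- rowsum(psi, cols)
    K[b, as.integer(rownames(rs))] <- rs[, 1]
  }
  K
}

# cache of CWT kernels keyed by (n, scale)
.cwt_cache <- new.env(parent = emptyenv())

cwt_kernel_cached <- function(n, a) {
  key <- paste0(n, "_", a)
  k <- .cwt_cache[[key]]
  if (is.null(k)) {
    k <- cwt_kernel(n, a)
    .cwt_cache[[key]] <- k
  }
  k
}

#' Continuous MHAT wavelet transform of one scan line
#'
#' `W(a, b) = a^{-1/2} * sum_x signal(x) psi((x - b) / a)` with unit sample
#' spacing and whole-sample mirror reflection at the boundaries.  Scales
#' with `4 * a >= length(signal)` are excluded with a warning.
#'
#' @param signal numeric vector, length at least `4 * max(scales)` for all
#'   scales to be retained.
#' @param scales strictly increasing positive scales, in samples.
#' @return matrix of coefficients, one row per retained scale (rownames are
#'   the scales), one column per position `b`.
#' @export
cwt_row <- function(signal, scales) {
  n <- length(signal)
  if (is.unsorted(scales, strictly = TRUE) || any(scales <= 0)) {
    stop("scales must be strictly increasing and positive")
  }
  keep <- scales < n / 4
  if (!any(keep)) stop("all scales exceed length/4")
  if (!all(keep)) {
    warning(sprintf("excluding %d scale(s) >= length/4", sum(!keep)))
  }
  scales <- scales[keep]
  out <- matrix(0, length(scales), n,
                dimnames = list(as.character(scales), NULL))
  for (i in seq_along(scales)) {
    out[i, ] <- cwt_kernel_cached(n, scales[i]) %*% signal
  }
  out
}

#' Row-wise wavelet decomposition of a polarization map
#'
#' Applies [cwt_row()] to every raster row (the scan lines) of the chosen
#' map component.  Masked pixels are filled with the row median before the
#' transform; rows with no valid pixel are skipped and logged in the result.
#'
#' @param map a [`section_map()`][section_map] result, or a plain numeric
#'   matrix (taken as fully valid).
#' @param scales strictly increasing positive scales, samples.
#' @param component `"alpha"` or `"beta"` when `map` is a polarization map.
#' @param axis `"rows"` (default) or `"cols"`: which index runs along the
#'   scan line.
#' @return list of class `"wavelet_field"`: `coefficients` (array
#'   `scale x row x position`), `scales`, `fill_fraction`, `skipped_rows`.
#' @export
wavelet_map <- function(map, scales, component = c("alpha", "beta"),
                        axis = c("rows", "cols")) {
  component <- match.arg(component)
  axis <- match.arg(axis)
  m <- if (is.matrix(map)) map else {
    if (component == "alpha") map$alpha_map else map$beta_map
  }
  if (axis == "cols") m <- t(m)
  nr <- nrow(m); nc <- ncol(m)
  filled <- 0L
  skipped <- integer(0)
  rows <- vector("list", nr)
  valid <- matrix(TRUE, nr, nc)
  for (r in seq_len(nr)) {
    v <- m[r, ]
    bad <- !is.finite(v)
    if (all(bad)) {
      skipped <- c(skipped, r)
      rows[[r]] <- NULL
      next
    }
    if (any(bad)) {
      v[bad] <- median(v[!bad])
      filled <- filled + sum(bad)
      valid[r, bad] <- FALSE
    }
    rows[[r]] <- v
  }
  use <- setdiff(seq_len(nr), skipped)
  if (!length(use)) stop("no row with a valid segment")
  keep <- scales[scales < nc / 4]
  coef <- array(
    0, c(length(keep), length(use), nc),
    dimnames = list(as.character(keep), NULL, NULL)
  )
  for (i in seq_along(use)) {
    coef[, i, ] <- cwt_row(rows[[use[i]]], scales)
  }
  structure(
    list(
      coefficients = coef, scales = keep,
      fill_fraction = filled / (nr * nc), skipped_rows = skipped,
      valid = valid[use, , drop = FALSE]
    ),
    class = "wavelet_field"
  )
}

#' Per-scale statistics of a wavelet field
#'
#' For every scale `a`, the mean `Z1` and the raw second moment `Z2` of the
#' wavelet coefficients over all scan lines and positions.  By default the
#' statistics are taken on coefficient magnitudes `|W|` (the marker
#' definition: the mean of the signed MHAT coefficients of any bounded map
#' is near zero by admissibility); `on = "value"` uses the signed values.
#'
#' When the wavelet field carries a validity raster (rows decomposed from a
#' masked polarization map), the statistics are taken over coefficients
#' centred on valid pixels only (`masked = TRUE`), keeping the markers
#' consistent with the mask the phase section defined: median-filled spans
#' are flat and would otherwise dilute the markers in proportion to the
#' masked-out area.
#'
#' @param W a [wavelet_map()] result.
#' @param on `"magnitude"` or `"value"`.
#' @param masked restrict the statistics to coefficients centred on valid
#'   (non-filled) pixels when validity information is available.
#' @return list of class `"scale_statistics"`: `scales`, `z1`, `z2`
#'   (numeric per scale), `on`.
#' @export
scale_statistics <- function(W, on = c("magnitude", "value"),
                             masked = TRUE) {
  on <- match.arg(on)
  sc <- W$scales
  keep <- if (masked && !is.null(W$valid)) W$valid else NULL
  z1 <- numeric(length(sc)); z2 <- numeric(length(sc))
  for (i in seq_along(sc)) {
    v <- W$coefficients[i, , ]
    if (!is.null(keep)) v <- v[keep]
    if (on == "magnitude") v <- abs(v)
    z1[i] <- mean(v)
    z2[i] <- mean(v^2)
  }
  structure(list(scales = sc, z1 = z1, z2 = z2, on = on),
            class = "scale_statistics")
}

#' Select the discriminative wavelet scales between two groups
#'
#' Computes, per scale, a standardized between-group separation score
#' `|mean_A - mean_B| / s_pooled` on the `Z1` and on the `Z2` curves, takes
#' the pointwise maximum of the two profiles, and returns the smallest- and
#' the largest-scale local maxima that exceed `threshold`.
#'
#' @param group_a,group_b lists of [scale_statistics()] (>= 2 samples
#'   each, on a common scale grid).
#' @param threshold minimum separation score (pooled-SD units) for a peak
#'   to count.
#' @return list of class `"scale_selection"`: `a_min`, `a_max` (scales),
#'   `scales`, `score` (the combined profile), `score_z1`, `score_z2`.
#'   Signals an error of class `"holopolar_no_separation"` when no peak
#'   reaches the threshold.
#' @export
separation_scores <- function(group_a, group_b) {
  sc <- group_a[[1]]$scales
  pull <- function(g, what) {
    t(vapply(g, function(s) s[[what]], numeric(length(sc))))
  }
  sep <- function(what) {
    a <- pull(group_a, what); b <- pull(group_b, what)
    ma <- colMeans(a); mb <- colMeans(b)
    va <- apply(a, 2, var); vb <- apply(b, 2, var)
    na <- nrow(a); nb <- nrow(b)
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
    abs(ma - mb) / pmax(sp, .Machine$double.eps)
  }
  s1 <- sep("z1"); s2 <- sep("z2")
  list(scales = sc, score = pmax(s1, s2), score_z1 = s1, score_z2 = s2)
}

select_discriminative_scales <- function(group_a, group_b, threshold = 1) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 samples per group")
  }
  prof <- separation_scores(group_a, group_b)
  sc <- prof$scales
  s1 <- prof$score_z1; s2 <- prof$score_z2
  score <- prof$score
  n <- length(score)
  # interior local maxima only (a monotone shoulder at the grid edge, e.g.
  # the small-scale noise floor, is not a discriminative scale), and a peak
  # must stand comparison with the strongest separation found anywhere
  floor_score <- max(threshold, 0.5 * max(score))
  is_peak <- vapply(seq_len(n), function(i) {
    if (i == 1 || i == n) return(FALSE)
    score[i] >= score[i - 1] && score[i] >= score[i + 1] &&
      score[i] >= floor_score
  }, logical(1))
  if (!any(is_peak)) {
    stop(structure(
      class = c("holopolar_no_separation", "error", "condition"),
      list(message = "no scale separates the groups", call = sys.call())
    ))
  }
  peaks <- which(is_peak)
  structure(
    list(
      a_min = sc[peaks[1]], a_max = sc[peaks[length(peaks)]],
      scales = sc, score = score, score_z1 = s1, score_z2 = s2
    ),
    class = "scale_selection"
  )
}
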