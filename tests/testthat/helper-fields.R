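# shared fixtures: small band-limited fields and layers built in code

# smooth unit-variance surface on an n x n grid (seeded)
smooth_surface <- function(n, sigma, seed) {
  set.seed(seed)
  holopolar:::smooth_noise(n, n, sigma)
}

# band-limited random complex field, normalized to unit RMS per component
smooth_complex_field <- function(n, sigma = 10, seed = 1) {
  re1 <- smooth_surface(n, sigma, seed)
  im1 <- smooth_surface(n, sigma, seed + 1000)
  re2 <- smooth_surface(n, sigma, seed + 2000)
  im2 <- smooth_surface(n, sigma, seed + 3000)
  ux <- matrix(complex(real = re1, imaginary = im1), n, n)
  uy <- matrix(complex(real = re2, imaginary = im2), n, n)
  complex_field(ux / sqrt(mean(Mod(ux)^2)), uy / sqrt(mean(Mod(uy)^2)))
}

# smooth single-scatter layer (no strokes): rho in [0, pi), delta in
# range; the orientation swing is kept gentle so the resulting field stays
# well inside the demodulation sideband
smooth_layer <- function(n, seed = 1, delta_range = c(0.3, 1.2),
                         sigma = 12) {
  rho <- (pi / 2 + smooth_surface(n, sigma, seed) * 0.8) %% pi
  q <- pnorm(smooth_surface(n, sigma, seed + 500))
  delta <- delta_range[1] + diff(delta_range) * q
  fibril_layer(rho, delta)
}

# relative complex RMS error between two fields, after optimal global phase
field_rms_error <- function(rec, truth) {
  rec <- align_global_phase(rec, truth)
  num <- sqrt(mean(Mod(rec$ux - truth$ux)^2 + Mod(rec$uy - truth$uy)^2))
  den <- sqrt(mean(Mod(truth$ux)^2 + Mod(truth$uy)^2))
  num / den
}

# absolute azimuth difference respecting the pi-periodicity
azimuth_diff <- function(a, b) {
  abs(((a - b + pi / 2) %% pi) - pi / 2)
}

# brute-force CWT oracle: double loop over positions and extended samples,
# whole-sample mirror reflection (independent of the package implementation)
cwt_oracle <- function(signal, a) {
  n <- length(signal)
  reach <- ceiling(8 * a)
  w <- numeric(n)
  for (b in seq_len(n)) {
    acc <- 0
    for (x in (b - reach):(b + reach)) {
      # fold x into 1..n by mirror reflection about the edge samples
      p <- 2 * (n - 1)
      j <- (x - 1) %% p
      if (j < 0) j <- j + p
      xf <- if (j >= n) p - j + 1 else j + 1
      acc <- acc + signal[xf] * mhat((x - b) / a)
    }
    w[b] <- acc / sqrt(a)
  }
  w
}

# minimum chord length through each TRUE pixel over 4 directions (rows,
# columns, both diagonals); a blind transverse-width estimator
min_chords <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  run_len <- function(lines) {
    out <- matrix(0, n1, n2)
    for (ln in lines) {
      r <- rle(mask[ln$idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in seq_along(r$lengths)) {
        if (r$values[k]) out[ln$idx[starts[k]:ends[k]]] <- r$lengths[k] *
            ln$step
      }
    }
    out
  }
  lin <- function(i, j) (j - 1) * n1 + i
  rows <- lapply(seq_len(n1), function(i) {
    list(idx = lin(i, seq_len(n2)), step = 1)
  })
  cols <- lapply(seq_len(n2), function(j) {
    list(idx = lin(seq_len(n1), j), step = 1)
  })
  diag1 <- lapply(seq(-n1 + 1, n2 - 1), function(d) {
    i <- seq_len(n1); j <- i + d
    ok <- j >= 1 & j <= n2
    if (sum(ok) < 2) return(NULL)
    list(idx = lin(i[ok], j[ok]), step = sqrt(2))
  })
  diag2 <- lapply(seq(2, n1 + n2), function(sm) {
    i <- seq_len(n1); j <- sm - i
    ok <- j >= 1 & j <= n2
    if (sum(ok) < 2) return(NULL)
    list(idx = lin(i[ok], j[ok]), step = sqrt(2))
  })
  cands <- list(
    run_len(rows), run_len(cols),
    run_len(Filter(Negate(is.null), diag1)),
    run_len(Filter(Negate(is.null), diag2))
  )
  mc <- Reduce(pmin, cands)
  v <- mc[mask & mc >= 3]
  v
}
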