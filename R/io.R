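# ---------------------------------------------------------------------------
# Plain-text raster / array / table formats
# ---------------------------------------------------------------------------
# Interferogram rasters travel as plain-text PGM (P2) with a JSON sidecar;
# float arrays and complex fields use a small self-describing text container.
# No binary formats: everything here round-trips through text.

#' Write an 8- or 16-bit grayscale raster as plain-text PGM
#'
#' @param m numeric matrix of non-negative integers (counts).
#' @param path output path (`.pgm`).
#' @param maxval largest representable count (255 for 8-bit, 65535 for
#'   16-bit).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path, maxval = 255) {
  if (any(m < 0) || any(m > maxval)) stop("values out of [0, maxval]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  write(t(round(m)), file = con, ncolumns = min(ncol(m), 16))
  invisible(path)
}

#' Read a plain-text PGM raster
#' @param path input path.
#' @return numeric matrix with attribute `maxval`.
#' @export
read_pgm <- function(path) {
  txt <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (txt[1] != "P2") stop("not a plain-text (P2) PGM file: ", path)
  nc <- as.integer(txt[2]); nr <- as.integer(txt[3])
  maxval <- as.numeric(txt[4])
  vals <- as.numeric(txt[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM payload: ", path)
  structure(matrix(vals, nr, nc, byrow = TRUE), maxval = maxval)
}

#' Write an interferogram (PGM + JSON sidecar)
#'
#' @param ig an [interferogram()].
#' @param stem output path stem; writes `<stem>.pgm` and `<stem>.json`.
#' @return the stem, invisibly.
#' @export
write_interferogram <- function(ig, stem) {
  bits <- if (is.null(ig$quantize_bits)) 16L else ig$quantize_bits
  maxval <- 2^bits - 1
  i <- ig$intensity
  scale <- ig$scale
  if (is.null(ig$quantize_bits)) { # quantize to 16 bit for transport
    scale <- max(i) / maxval
    i <- round(i / scale)
  }
  write_pgm(i, paste0(stem, ".pgm"), maxval)
  meta <- list(
    analyzer_omega = ig$analyzer_omega, carrier = ig$carrier,
    ref_amplitude = ig$ref_amplitude, quantize_bits = bits, scale = scale
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read an interferogram written by [write_interferogram()]
#' @param stem path stem (without extension).
#' @return an [interferogram()].
#' @export
read_interferogram <- function(stem) {
  m <- read_pgm(paste0(stem, ".pgm"))
  attr(m, "maxval") <- NULL
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  interferogram(
    m, meta$analyzer_omega, as.numeric(meta$carrier),
    ref_amplitude = meta$ref_amplitude, quantize_bits = meta$quantize_bits,
    scale = meta$scale
  )
}

#' Write a numeric matrix to the text array container
#'
#' Format: a one-line JSON header (`dims`, `complex` flag) followed by one
#' row of whitespace-separated values per raster row (real, or interleaved
#' re/im pairs for complex input).  Lossless for doubles (written with 17
#' significant digits).
#'
#' @param m numeric or complex matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_array_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cx <- is.complex(m)
  writeLines(jsonlite::toJSON(
    list(dims = dim(m), complex = cx), auto_unbox = TRUE
  ), con)
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  for (r in seq_len(nrow(m))) {
    v <- m[r, ]
    writeLines(if (cx) fmt(as.numeric(rbind(Re(v), Im(v)))) else fmt(v), con)
  }
  invisible(path)
}

#' Read a matrix from the text array container
#' @param path input path.
#' @return numeric or complex matrix.
#' @export
read_array_txt <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  nr <- hdr$dims[1]; nc <- hdr$dims[2]
  out <- if (isTRUE(hdr$complex)) {
    matrix(complex(real = 0), nr, nc)
  } else {
    matrix(0, nr, nc)
  }
  for (r in seq_len(nr)) {
    v <- as.numeric(strsplit(trimws(lines[r + 1]), "\\s+")[[1]])
    out[r, ] <- if (isTRUE(hdr$complex)) {
      complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
    } else {
      v
    }
  }
  out
}

#' Write a complex field (two array containers + JSON manifest)
#' @param field a [complex_field()].
#' @param stem path stem; writes `<stem>_ux.txt`, `<stem>_uy.txt`,
#'   `<stem>.json`.
#' @return the stem, invisibly.
#' @export
write_field <- function(field, stem) {
  write_array_txt(field$ux, paste0(stem, "_ux.txt"))
  write_array_txt(field$uy, paste0(stem, "_uy.txt"))
  jsonlite::write_json(
    list(pixel_pitch = field$pixel_pitch, dims = dim(field$ux)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' Read a complex field written by [write_field()]
#' @param stem path stem.
#' @return a [complex_field()].
#' @export
read_field <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  complex_field(
    read_array_txt(paste0(stem, "_ux.txt")),
    read_array_txt(paste0(stem, "_uy.txt")),
    pixel_pitch = meta$pixel_pitch
  )
}

#' Write a marker table as CSV
#' @param table a [marker_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a marker table CSV
#' @param path input path.
#' @return a [marker_table()].
#' @export
read_marker_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  marker_table(df$sample, df$group, df$marker, df$value)
}

#' Write scale statistics as CSV (`scale, z1, z2`)
#' @param stats a [scale_statistics()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scale_csv <- function(stats, path) {
  write.csv(
    data.frame(scale = stats$scales, z1 = stats$z1, z2 = stats$z2),
    path, row.names = FALSE
  )
  invisible(path)
}
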