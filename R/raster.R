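#' Raster slide container
#'
#' The unit the pipeline consumes: an RGB raster standing in for a whole-slide
#' image, with nominal magnification metadata. Pixels are stored as an integer
#' array `[rows, cols, 3]` with channel values in `[0, 255]`.
#'
#' @param pixels integer/numeric array `[rows, cols, 3]`, values in 0..255.
#' @param magnification nominal objective power (default 40).
#' @param downsample_factor default factor used for field-of-view detection.
#' @return an object of class `raster_slide`.
#' @export
raster_slide <- function(pixels, magnification = 40, downsample_factor = 16L) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be a [rows, cols, 3] array")
  }
  if (any(dim(pixels)[1:2] < 1L)) stop("raster must be nonempty")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop("RGB channel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels,
         magnification = magnification,
         downsample_factor = as.integer(downsample_factor)),
    class = "raster_slide"
  )
}

#' @method print raster_slide
#' @export
print.raster_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_slide %dx%d px, %gx magnification>\n",
              d[1], d[2], x$magnification))
  invisible(x)
}

#' @method dim raster_slide
#' @export
dim.raster_slide <- function(x) dim(x$pixels)

#' Read a slide raster from disk
#'
#' Supports portable pixmap (`.ppm`/`.pnm`, ASCII `P3` or binary `P6`), the
#' plain-raster stand-in for vendor slide formats used throughout this
#' package. PNG/TIFF decoding is intentionally not implemented (no offline
#' decoder is guaranteed); convert externally to PPM.
#'
#' @param path file path.
#' @inheritParams raster_slide
#' @return a [raster_slide].
#' @export
read_slide <- function(path, magnification = 40) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ppm", "pnm")) {
    stop("unsupported raster format '.", ext, "': use .ppm (P3/P6)")
  }
  raster_slide(read_ppm(path), magnification = magnification)
}

#' Write a slide raster to disk
#'
#' `.ppm` writes binary P6 (or ASCII P3 with `ascii = TRUE`). `.png` is
#' honoured when the grDevices PNG device is available (write-only
#' convenience for visual inspection).
#'
#' @param slide a [raster_slide] or `[rows, cols, 3]` array.
#' @param path output path; format chosen by extension.
#' @param ascii write ASCII P3 instead of binary P6.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path, ascii = FALSE) {
  px <- if (inherits(slide, "raster_slide")) slide$pixels else slide
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ppm", "pnm")) {
    write_ppm(px, path, ascii = ascii)
  } else if (ext == "png") {
    if (!isTRUE(capabilities("png"))) stop("PNG device unavailable; use .ppm")
    grDevices::png(path, width = dim(px)[2], height = dim(px)[1])
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::rasterImage(array(px / 255, dim(px)), 0, 0, 1, 1,
                          interpolate = FALSE)
    graphics::par(op)
    grDevices::dev.off()
  } else {
    stop("unsupported raster format '.", ext, "'")
  }
  invisible(path)
}

read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P3", "P6")) stop("not a PPM file (magic ", magic, ")")
  # header tokens may be separated by whitespace/comments
  next_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop("truncated PPM header")
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (ch %in% c("\n", "") || length(ch) == 0L) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  w <- as.integer(next_token()); h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) stop("bad PPM dimensions")
  if (is.na(maxval) || maxval < 1L || maxval > 255L) {
    stop("only 8-bit PPM supported (maxval ", maxval, ")")
  }
  n <- as.double(w) * h * 3
  vals <- if (magic == "P6") {
    as.integer(readBin(con, "raw", n = n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("truncated PPM pixel data")
  # PPM stores row-major RGB triplets; unpack into [h, w, 3]
  px <- array(0L, c(h, w, 3L))
  m <- matrix(vals, nrow = 3L) # columns are pixels in row-major order
  for (ch in 1:3) {
    px[, , ch] <- matrix(m[ch, ], nrow = h, ncol = w, byrow = TRUE)
  }
  px
}

write_ppm <- function(px, path, ascii = FALSE) {
  stopifnot(is.array(px), length(dim(px)) == 3L, dim(px)[3] == 3L)
  h <- dim(px)[1]; w <- dim(px)[2]
  v <- as.integer(pmin(pmax(round(px), 0L), 255L))
  dim(v) <- dim(px)
  # interleave channels in row-major pixel order
  m <- rbind(as.vector(t(v[, , 1])), as.vector(t(v[, , 2])),
             as.vector(t(v[, , 3])))
  con <- file(path, "wb")
  on.exit(close(con))
  if (ascii) {
    writeLines(c("P3", paste(w, h), "255"), con, sep = "\n")
    writeLines(paste(apply(matrix(as.vector(m), nrow = 3L), 2,
                           paste, collapse = " "), collapse = "\n"), con)
  } else {
    writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.vector(m)), con)
  }
  invisible(path)
}
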