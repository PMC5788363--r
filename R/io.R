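#' Read an image as a normalized grayscale matrix
#'
#' Loads PNG, TIFF or JPEG (JPEG requires the `jpeg` package), converts
#' color inputs to luminance (0.2989 R + 0.5870 G + 0.1140 B), and
#' normalizes intensities to \[0, 1\]. The source path is kept as an
#' attribute.
#'
#' @param path Image file path.
#' @return Numeric matrix in \[0, 1\] with attribute `source`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  m <- to_luminance(raw)
  m <- as_image(m)
  attr(m, "source") <- path
  m
}

to_luminance <- function(raw) {
  if (length(dim(raw)) == 2L) return(raw)
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    if (nc >= 3)
      return(0.2989 * raw[, , 1] + 0.5870 * raw[, , 2] + 0.1140 * raw[, , 3])
    return(raw[, , 1])
  }
  stop("unsupported image array layout", call. = FALSE)
}

#' Coerce/validate a matrix as a working image
#'
#' Ensures a finite numeric matrix with intensities in \[0, 1\]. Inputs on
#' a wider scale (e.g. 0-255) are rescaled linearly by their range;
#' inputs already in \[0, 1\] are left untouched.
#'
#' @param x Numeric matrix.
#' @return Numeric matrix in \[0, 1\].
#' @export
as_image <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!all(is.finite(x))) stop("image contains non-finite values", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (lo < 0 || hi > 1) {
    if (hi > lo) x <- (x - lo) / (hi - lo) else x <- pmin(pmax(x, 0), 1)
  }
  x
}

read_mask <- function(path) {
  m <- read_image(path)
  matrix(as.integer(m > 0.5), nrow(m))
}

#' Write a binary mask as an 8-bit PNG
#'
#' Inside pixels (nonzero) become 255, outside 0.
#'
#' @param mask 0/1 or logical matrix.
#' @param path Output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask != 0) * 1.0, path)
  invisible(path)
}

#' Write a scalar field as a 32-bit float TIFF
#'
#' For inspecting level-set snapshots, edge maps and local fits. TIFF
#' float storage here covers \[0, 1\], so fields with values outside that
#' range are affinely mapped into it; the original range is returned so
#' the mapping can be undone.
#'
#' @param field Numeric matrix (any range).
#' @param path Output file.
#' @return (Invisibly) list with `path`, `min`, `max` of the original
#'   field.
#' @export
write_field_tiff <- function(field, path) {
  lo <- min(field); hi <- max(field)
  out <- if (lo < 0 || hi > 1) {
    if (hi > lo) (field - lo) / (hi - lo) else matrix(0.5, nrow(field), ncol(field))
  } else field
  tiff::writeTIFF(out, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(list(path = path, min = lo, max = hi))
}

#' Write a contour overlay PNG
#'
#' Draws the mask's boundary pixels in red over the grayscale image.
#'
#' @param image Matrix in \[0, 1\].
#' @param mask 0/1 matrix.
#' @param path Output file.
#' @export
write_overlay_png <- function(image, mask, path) {
  b <- mask_boundary(mask != 0)
  rgb <- array(rep(image, 3), dim = c(dim(image), 3))
  r <- rgb[, , 1]; g <- rgb[, , 2]; bl <- rgb[, , 3]
  r[b] <- 1; g[b] <- 0; bl[b] <- 0
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- bl
  png::writePNG(rgb, path)
  invisible(path)
}
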