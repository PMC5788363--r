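# Internal spatial operators. All derivatives are central differences and
# all filters use replicate (Neumann) boundary handling, the standard
# choice for variational segmentation on pixel grids with unit spacing.

# Replicate-pad a matrix by `ry` rows top/bottom and `rx` cols left/right.
pad_replicate <- function(m, ry, rx = ry) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rep(1L, ry), seq_len(h), rep(h, ry))
  ci <- c(rep(1L, rx), seq_len(w), rep(w, rx))
  m[ri, ci, drop = FALSE]
}

# Normalized 1-D Gaussian taps truncated at radius ceil(4*sigma).
gaussian_taps <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  k <- dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

# Separable Gaussian filtering with replicate borders; sigma = 0 is identity.
gauss_filter <- function(m, sigma) {
  if (sigma == 0) return(m)
  k <- gaussian_taps(sigma)
  r <- (length(k) - 1L) / 2L
  h <- nrow(m); w <- ncol(m)
  p <- pad_replicate(m, 0L, r)
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * p[, i:(i + w - 1L), drop = FALSE]
  p <- pad_replicate(out, r, 0L)
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * p[i:(i + h - 1L), , drop = FALSE]
  out
}

# Zero-pad a matrix by `ry` rows top/bottom and `rx` cols left/right.
pad_zero <- function(m, ry, rx = ry) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h + 2 * ry, w + 2 * rx)
  out[(ry + 1):(ry + h), (rx + 1):(rx + w)] <- m
  out
}

# Separable Gaussian filtering with zero padding: mass outside the image
# domain contributes nothing, so ratios of two such filterings are local
# weighted means over in-domain pixels only (used by the fit operators).
gauss_filter_zero <- function(m, sigma) {
  if (sigma == 0) return(m)
  k <- gaussian_taps(sigma)
  r <- (length(k) - 1L) / 2L
  h <- nrow(m); w <- ncol(m)
  p <- pad_zero(m, 0L, r)
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * p[, i:(i + w - 1L), drop = FALSE]
  p <- pad_zero(out, r, 0L)
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * p[i:(i + h - 1L), , drop = FALSE]
  out
}

# Central-difference partials with replicate borders. x = columns, y = rows.
grad_x <- function(m) {
  w <- ncol(m)
  right <- m[, c(2:w, w), drop = FALSE]
  left  <- m[, c(1, 1:(w - 1)), drop = FALSE]
  (right - left) / 2
}

grad_y <- function(m) {
  h <- nrow(m)
  down <- m[c(2:h, h), , drop = FALSE]
  up   <- m[c(1, 1:(h - 1)), , drop = FALSE]
  (down - up) / 2
}

grad_mag <- function(m) sqrt(grad_x(m)^2 + grad_y(m)^2)

# Five-point Laplacian, replicate borders.
laplacian <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c(2:h, h), , drop = FALSE] + m[c(1, 1:(h - 1)), , drop = FALSE] +
    m[, c(2:w, w), drop = FALSE] + m[, c(1, 1:(w - 1)), drop = FALSE] - 4 * m
}
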