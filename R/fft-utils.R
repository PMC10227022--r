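# Shared Fourier conventions.
#
# Every module uses the unshifted discrete layout: DC at matrix index [1, 1],
# frequencies in cycles per pixel, pixel coordinates 0-based with centers at
# integers. The "center" pixel of an N-wide axis is 0-based index floor(N/2),
# i.e. R index floor(N/2) + 1, so ifftshift_mat() maps it onto DC.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @keywords internal
fftshift_mat <- function(x) {
  d <- dim(x)
  i <- c(seq.int(floor(d[1] / 2) + 1L, d[1]), seq_len(floor(d[1] / 2)))
  j <- c(seq.int(floor(d[2] / 2) + 1L, d[2]), seq_len(floor(d[2] / 2)))
  x[i, j, drop = FALSE]
}

#' @keywords internal
ifftshift_mat <- function(x) {
  d <- dim(x)
  i <- c(seq.int(d[1] - floor(d[1] / 2) + 1L, d[1]), seq_len(d[1] - floor(d[1] / 2)))
  j <- c(seq.int(d[2] - floor(d[2] / 2) + 1L, d[2]), seq_len(d[2] - floor(d[2] / 2)))
  x[i, j, drop = FALSE]
}

# DFT sample frequencies in cycles/pixel, unshifted order (like fftfreq).
freq_axis <- function(n) {
  f <- seq.int(0L, n - 1L)
  f[f >= ceiling(n / 2)] <- f[f >= ceiling(n / 2)] - n
  f / n
}

# |k| over an unshifted frequency grid, cycles/pixel.
kr_grid <- function(shape) {
  fx <- freq_axis(shape[1])
  fy <- freq_axis(shape[2])
  sqrt(outer(fx^2, fy^2, `+`))
}

# Component grids kx (rows) and ky (cols), unshifted, cycles/pixel.
k_grids <- function(shape) {
  fx <- freq_axis(shape[1])
  fy <- freq_axis(shape[2])
  list(kx = matrix(fx, shape[1], shape[2]),
       ky = matrix(fy, shape[1], shape[2], byrow = TRUE))
}

# Complex plane-wave exp(sign * 2i*pi*(kx*x + ky*y)) over 0-based pixel
# coordinates; `step` rescales coordinates (0.5 on the 2x upsampled grid so k
# stays in cycles per original pixel).
plane_wave <- function(shape, kvec, sign = 1, step = 1) {
  x <- (seq_len(shape[1]) - 1) * step
  y <- (seq_len(shape[2]) - 1) * step
  ph <- outer(kvec[1] * x, kvec[2] * y, `+`)
  exp(sign * 2i * pi * ph)
}

# Embed a small matrix centered into a larger zero matrix (real or complex).
embed_center <- function(m, shape) {
  dm <- dim(m)
  if (any(dm > shape)) stop("cannot embed: source larger than target grid")
  out <- matrix(if (is.complex(m)) 0+0i else 0, shape[1], shape[2])
  r0 <- floor(shape[1] / 2) - floor(dm[1] / 2)
  c0 <- floor(shape[2] / 2) - floor(dm[2] / 2)
  out[r0 + seq_len(dm[1]), c0 + seq_len(dm[2])] <- m
  out
}

# Zero-pad an unshifted spectrum onto an `up`x larger grid (same physical
# frequencies, finer real-space sampling). Scaled by up^2 so real-space
# amplitudes are preserved.
upsample_spectrum <- function(spec, up = 2L) {
  shape <- dim(spec) * up
  ifftshift_mat(embed_center(fftshift_mat(spec), shape)) * up^2
}

# Gaussian blur by FFT, sigma in pixels, periodic boundary.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  kr2 <- kr_grid(dim(img))^2
  Re(ifft2(fft2(img) * exp(-2 * pi^2 * sigma_px^2 * kr2)))
}

# Azimuthally averaged radial profile of a (real) unshifted spectrum.
# Bin b (1-based) covers radii [ (b-1)-0.5, (b-1)+0.5 ) in units of the grid
# frequency step 1/n (square grids only). Returns the profile and the bin
# frequencies in cycles/pixel.
radial_profile <- function(spec, shape = dim(spec)) {
  stopifnot(shape[1] == shape[2])
  n <- shape[1]
  r <- kr_grid(shape) * n
  bin <- pmin(round(r), ceiling(n / sqrt(2))) + 1L
  v <- Re(spec)
  prof <- as.numeric(tapply(as.vector(v), as.vector(bin), mean))
  idx <- as.integer(names(tapply(as.vector(v), as.vector(bin), mean)))
  full <- numeric(max(idx))
  full[idx] <- prof
  list(profile = full, freq = (seq_along(full) - 1) / n)
}

# Linear interpolation of a radial profile at arbitrary |k| (cycles/pixel);
# zero beyond the last bin.
eval_radial <- function(rp, kr) {
  pos <- kr * length(rp$freq) / (rp$freq[2] * length(rp$freq)) # = kr * n
  n <- length(rp$profile)
  lo <- floor(pos) + 1
  frac <- pos - floor(pos)
  lo_ok <- pmin(lo, n)
  hi_ok <- pmin(lo + 1, n)
  v <- rp$profile[lo_ok] * (1 - frac) + rp$profile[hi_ok] * frac
  v[lo >= n] <- 0
  dim(v) <- dim(kr)
  v
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
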