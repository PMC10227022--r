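#' Optical configuration
#'
#' Single source of physical units for the whole pipeline: emission
#' wavelength, numerical aperture, immersion refractive index, lateral pixel
#' size, and the axial grid over which the 3D PSF is generated and split into
#' in-focus and out-of-focus parts.
#'
#' Defaults follow a high-NA oil-immersion 2D-SIM instrument: 488 nm emission,
#' NA 1.4, refractive index 1.5, 65 nm pixels, 100 nm z-step, PSF computed
#' over +/- 4 um with the axial-resolution window +/- 0.4 um treated as
#' in-focus.
#'
#' @param em_wavelength_nm emission wavelength (nm).
#' @param na numerical aperture; must be below `refractive_index`.
#' @param refractive_index immersion medium refractive index.
#' @param pixel_nm lateral sampling (nm/pixel) of the raw data.
#' @param z_step_nm axial step of the PSF grid (nm).
#' @param z_halfrange_nm half-extent of the axial PSF grid (nm).
#' @param infocus_halfrange_nm half-width of the in-focus window (nm);
#'   `|z| <= infocus_halfrange_nm` counts as in-focus (closed interval).
#' @param psf_size_px lateral size of generated PSF slices (even integer).
#' @return an object of class `optical_config`.
#' @details A warning (class `bfsim_nyquist_warning`) is emitted when
#'   `pixel_nm` exceeds the Nyquist spacing for the super-resolution passband,
#'   `em_wavelength_nm / (8 * na)`: the raw data then cannot carry the full
#'   doubled passband without aliasing on the raw grid (the 2x upsampled
#'   reconstruction grid still can, which is why this is a warning and not an
#'   error -- real instruments, including the one modeled by the defaults,
#'   routinely sample at the raw-image Nyquist limit instead).
#' @export
optical_config <- function(em_wavelength_nm = 488, na = 1.4,
                           refractive_index = 1.5, pixel_nm = 65,
                           z_step_nm = 100, z_halfrange_nm = 4000,
                           infocus_halfrange_nm = 400, psf_size_px = 128L) {
  for (v in c(em_wavelength_nm, na, refractive_index, pixel_nm, z_step_nm,
              z_halfrange_nm, infocus_halfrange_nm)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("all optical parameters must be single positive finite numbers")
    }
  }
  if (infocus_halfrange_nm >= z_halfrange_nm) {
    stop("infocus_halfrange_nm must be smaller than z_halfrange_nm")
  }
  if (na >= refractive_index) {
    stop("na must be below refractive_index (propagating-field condition)")
  }
  psf_size_px <- as.integer(psf_size_px)
  if (psf_size_px < 8L || psf_size_px %% 2L != 0L) {
    stop("psf_size_px must be an even integer >= 8")
  }
  if (pixel_nm > em_wavelength_nm / (8 * na)) {
    warning(warningCondition(
      sprintf(paste0("pixel_nm = %g nm exceeds the SR-passband Nyquist ",
                     "spacing %.1f nm = lambda/(8 NA); the raw grid ",
                     "undersamples the doubled passband"),
              pixel_nm, em_wavelength_nm / (8 * na)),
      class = "bfsim_nyquist_warning"))
  }
  structure(list(em_wavelength_nm = em_wavelength_nm, na = na,
                 refractive_index = refractive_index, pixel_nm = pixel_nm,
                 z_step_nm = z_step_nm, z_halfrange_nm = z_halfrange_nm,
                 infocus_halfrange_nm = infocus_halfrange_nm,
                 psf_size_px = psf_size_px),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  lambda_em %g nm | NA %g | n %g | pixel %g nm\n",
              x$em_wavelength_nm, x$na, x$refractive_index, x$pixel_nm))
  cat(sprintf("  z grid +/- %g nm step %g nm | in-focus +/- %g nm\n",
              x$z_halfrange_nm, x$z_step_nm, x$infocus_halfrange_nm))
  cat(sprintf("  k_cutoff = %.4f cycles/pixel\n", k_cutoff(x)))
  invisible(x)
}

#' Incoherent lateral cutoff frequency, cycles per pixel
#'
#' `2 * NA / lambda` converted to cycles/pixel with the configured sampling.
#' @param config an [optical_config()].
#' @export
k_cutoff <- function(config) {
  2 * config$na * config$pixel_nm / config$em_wavelength_nm
}

#' Depth-resolved PSF container
#'
#' Bundles an ordered list of non-negative 2D PSF slices with their signed
#' axial offsets. Slices are normalized so the z = 0 (or brightest, for
#' loaded stacks) slice sums to 1; defocused slices keep their energy
#' relative to focus rather than being renormalized per slice.
#'
#' @param slices 3D array `[x, y, z]` of non-negative values.
#' @param z_nm numeric vector of axial offsets (nm), strictly increasing,
#'   uniformly spaced, containing 0.
#' @param pixel_nm lateral sampling (nm).
#' @param require_symmetric assert that the z grid is symmetric about 0
#'   (every z has a matching -z). Generated PSFs always are; measured stacks
#'   centered on an off-middle brightest page legitimately are not.
#' @return an object of class `psf3d`.
#' @export
psf3d <- function(slices, z_nm, pixel_nm, require_symmetric = TRUE) {
  stopifnot(length(dim(slices)) == 3, dim(slices)[3] == length(z_nm))
  if (any(!is.finite(slices)) || any(slices < 0)) {
    stop("PSF slices must be finite and non-negative")
  }
  if (is.unsorted(z_nm, strictly = TRUE)) stop("z grid must be strictly increasing")
  dz <- diff(z_nm)
  if (length(dz) && max(abs(dz - dz[1])) > 1e-6 * abs(dz[1])) {
    stop("z grid must be uniformly spaced")
  }
  if (min(abs(z_nm)) > 1e-9) stop("z grid must contain 0")
  if (require_symmetric && max(abs(z_nm + rev(z_nm))) > 1e-6 * max(abs(z_nm), 1)) {
    stop("z grid must be symmetric about 0")
  }
  structure(list(slices = slices, z_nm = z_nm, pixel_nm = pixel_nm),
            class = "psf3d")
}

#' @export
print.psf3d <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("3D PSF: %d x %d px (%g nm), %d z slices from %g to %g nm\n",
              d[1], d[2], x$pixel_nm, d[3], min(x$z_nm), max(x$z_nm)))
  invisible(x)
}

# Born-Wolf scalar defocus integral sampled on an npx x npx pixel grid.
# U(r, z) = int_0^1 J0(k NA r rho) exp(-i k z NA^2 rho^2 / (2 n)) rho drho,
# intensity |U|^2; k = 2 pi / lambda. Composite-Simpson quadrature in rho.
born_wolf_slices <- function(npx, pixel_nm, z_nm, em_wavelength_nm, na,
                             refractive_index, n_rho = 201L) {
  if (n_rho %% 2L == 0L) n_rho <- n_rho + 1L
  k0 <- 2 * pi / em_wavelength_nm
  x <- (seq_len(npx) - 1) - floor(npx / 2)
  r_nm <- pixel_nm * sqrt(outer(x^2, x^2, `+`))
  rho <- seq(0, 1, length.out = n_rho)
  w <- rep(c(2, 4), length.out = n_rho); w[1] <- 1; w[n_rho] <- 1
  w <- w * (rho[2] - rho[1]) / 3
  # Bessel matrix reused across z: npx^2 x n_rho.
  J <- besselJ(as.vector(r_nm) %o% (k0 * na * rho), 0)
  psi <- -k0 * na^2 / (2 * refractive_index) * (z_nm %o% rho^2)   # nz x n_rho
  cz <- exp(1i * psi) * rep(rho * w, each = length(z_nm))          # nz x n_rho
  U <- J %*% t(cz)                                                 # npx^2 x nz
  h <- array(Mod(U)^2, dim = c(npx, npx, length(z_nm)))
  h
}

#' Generate a depth-resolved 3D PSF (scalar Born-Wolf model)
#'
#' Evaluates the scalar Born-Wolf defocus integral (circular pupil with a
#' quadratic defocus phase) on the configured lateral/axial grid. This is the
#' standard scalar approximation of the full vectorial high-NA model;
#' [load_psf3d()] covers externally computed or bead-measured PSFs when exact
#' vectorial parity is needed.
#'
#' @param config an [optical_config()].
#' @param n_rho number of pupil-radius quadrature nodes (composite Simpson).
#' @return a [psf3d()] normalized so the z = 0 slice sums to 1.
#' @export
generate_psf3d <- function(config, n_rho = 201L) {
  stopifnot(inherits(config, "optical_config"))
  airy_r_px <- 0.61 * config$em_wavelength_nm / config$na / config$pixel_nm
  if (airy_r_px > config$psf_size_px / 2) {
    stop(sprintf("psf_size_px = %d too small: first Airy zero at %.1f px exceeds half the array",
                 config$psf_size_px, airy_r_px))
  }
  z_nm <- seq(-config$z_halfrange_nm, config$z_halfrange_nm,
              by = config$z_step_nm)
  h <- born_wolf_slices(config$psf_size_px, config$pixel_nm, z_nm,
                        config$em_wavelength_nm, config$na,
                        config$refractive_index, n_rho = n_rho)
  i0 <- which(abs(z_nm) < 1e-9)
  h <- h / sum(h[, , i0])
  psf3d(h, z_nm, config$pixel_nm)
}

#' Load a measured/exported 3D PSF from a multi-page TIFF
#'
#' Pages are interpreted as z-slices in order. The z grid is centered on the
#' brightest page (largest slice sum; exact ties break deterministically to
#' the page closest to the middle, with a warning). Pages are counted from 0
#' in messages, so a brightest page p of P pages yields a z grid from
#' `-p * z_step_nm` to `(P - 1 - p) * z_step_nm`.
#'
#' @param path multi-page TIFF with an odd page count.
#' @param pixel_nm lateral sampling (nm).
#' @param z_step_nm axial page spacing (nm).
#' @param background_offset constant subtracted from every pixel before
#'   negative clipping (camera offset of a bead acquisition).
#' @return a [psf3d()] (z grid possibly asymmetric), brightest slice sums to 1.
#' @export
load_psf3d <- function(path, pixel_nm, z_step_nm, background_offset = 0) {
  pages <- read_tiff(path)
  if (length(pages) %% 2L == 0L) {
    stop(sprintf("PSF stack must have an odd page count, got %d", length(pages)))
  }
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    stop("PSF stack pages have non-uniform shapes")
  }
  h <- array(0, dim = c(shp, length(pages)))
  for (i in seq_along(pages)) h[, , i] <- pmax(pages[[i]] - background_offset, 0)
  sums <- apply(h, 3, sum)
  if (max(sums) <= 0) stop("degenerate PSF stack: all values zero after offset subtraction")
  best <- which(sums >= max(sums) * (1 - 1e-12))
  if (length(best) > 1L) {
    mid <- (length(pages) + 1) / 2
    best <- best[which.min(abs(best - mid))]
    warning("brightest-slice tie; centering on the page closest to the middle")
  }
  z_nm <- (seq_along(pages) - best) * z_step_nm
  h <- h / sum(h[, , best])
  psf3d(h, z_nm, pixel_nm, require_symmetric = FALSE)
}

#' In-focus / out-of-focus transfer-function pair
#'
#' Partitions the PSF z-stack at `infocus_halfrange_nm` (closed interval:
#' boundary slices are in-focus) and collapses each part to a 2D transfer
#' function by summing the 2D Fourier transforms of its slices -- each
#' defocused plane convolves the same 2D sample, so the depth sum acts as a
#' single 2D filter. Slices are embedded centered into the target grid before
#' the FFT so DC sits at index [1, 1] and symmetric PSFs give real OTFs.
#'
#' @param psf a [psf3d()].
#' @param config an [optical_config()] supplying the cutoff frequency and the
#'   default in-focus window.
#' @param infocus_halfrange_nm in-focus half-width (nm); defaults to the
#'   config value. Must be at least one z-step, and at least one slice must
#'   fall outside the window (otherwise there is no background to model).
#' @param shape target frequency grid (defaults to the PSF slice size); use
#'   the raw frame size so the OTFs act directly on raw frames.
#' @return an object of class `otf_pair` with elements `h_in`, `h_out`, `h0`
#'   (the z = 0 slice OTF, used by the no-filter reconstruction branch),
#'   `k_cutoff_cycles_per_px`, `shape`, `pixel_nm`.
#' @export
split_otf <- function(psf, config, infocus_halfrange_nm = NULL, shape = NULL) {
  stopifnot(inherits(psf, "psf3d"), inherits(config, "optical_config"))
  hw <- infocus_halfrange_nm %||% config$infocus_halfrange_nm
  if (hw < config$z_step_nm) stop("infocus_halfrange_nm must be >= z_step_nm")
  tol <- 1e-9
  inside <- abs(psf$z_nm) <= hw + tol
  if (all(inside)) {
    stop("in-focus window covers every z slice: no out-of-focus background to filter")
  }
  shape <- shape %||% dim(psf$slices)[1:2]
  acc <- function(idx) {
    s <- matrix(0 + 0i, shape[1], shape[2])
    for (i in idx) {
      s <- s + fft2(ifftshift_mat(embed_center(psf$slices[, , i], shape)))
    }
    s
  }
  h_in <- acc(which(inside))
  h_out <- acc(which(!inside))
  i0 <- which.min(abs(psf$z_nm))
  h0 <- acc(i0)
  # The incoherent OTF has compact support |k| <= k_cutoff; anything beyond
  # is sampling/truncation leakage of the discrete PSF (~1e-4 of DC at
  # typical grid sizes), so it is zeroed to restore the exact support.
  kc <- 2 * config$na * psf$pixel_nm / config$em_wavelength_nm
  beyond <- kr_grid(shape) > kc + 1e-12
  h_in[beyond] <- 0; h_out[beyond] <- 0; h0[beyond] <- 0
  symmetric <- max(abs(psf$z_nm + rev(psf$z_nm))) <= 1e-6 * max(abs(psf$z_nm), 1)
  if (symmetric) {
    # symmetric z grid + centered slices => real transfer functions
    h_in <- Re(h_in); h_out <- Re(h_out); h0 <- Re(h0)
  }
  structure(list(h_in = h_in, h_out = h_out, h0 = h0,
                 k_cutoff_cycles_per_px =
                   2 * config$na * psf$pixel_nm / config$em_wavelength_nm,
                 shape = as.integer(shape), pixel_nm = psf$pixel_nm),
            class = "otf_pair")
}

#' @export
print.otf_pair <- function(x, ...) {
  cat(sprintf("OTF pair on %d x %d grid: H_in(0) = %.4g, H_out(0) = %.4g, k_cutoff = %.4f cyc/px\n",
              x$shape[1], x$shape[2], Re(x$h_in[1, 1]), Re(x$h_out[1, 1]),
              x$k_cutoff_cycles_per_px))
  invisible(x)
}

# Validate otf_pair invariants; used by build_filter and tests.
validate_otf_pair <- function(otf) {
  stopifnot(inherits(otf, "otf_pair"))
  dc <- Re(otf$h_in[1, 1]) + Re(otf$h_out[1, 1])
  if (Re(otf$h_in[1, 1]) <= 0) stop("H_in(0) must be positive")
  if (Re(otf$h_out[1, 1]) < 0) stop("H_out(0) must be non-negative")
  if (dc <= 0) stop("degenerate OTF pair: zero total DC")
  invisible(TRUE)
}
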