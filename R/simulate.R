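# Forward-model simulator: synthetic scenes and raw SIM stacks.
#
# The noiseless frame model is
#   d = [g_in * I] (x) h_in + [g_out * I] (x) h_out
# evaluated periodically in Fourier space with the OTF pair from split_otf().
# With g_out = g_in this realizes the package's imaging model exactly under
# its discretization, which is what makes every downstream stage testable
# against closed-form oracles. Phantom generators keep structure inside a
# guard margin so the periodic boundary carries no visible wrap-around.

#' Sinusoidal illumination pattern
#'
#' `I(r) = dc * (1 + modulation * cos(2 pi k . r + phase))` with `r` in
#' 0-based pixel coordinates and `k` in cycles/pixel.
#'
#' @param k_vec length-2 wave vector (cycles/pixel), non-zero.
#' @param phases_rad per-frame phase offsets (default the standard 3-phase
#'   set 0, 2pi/3, 4pi/3).
#' @param modulation modulation depth in (0, 1].
#' @param dc mean illumination level (positive).
#' @export
illumination_pattern <- function(k_vec, phases_rad = 2 * pi * (0:2) / 3,
                                 modulation = 0.8, dc = 1) {
  stopifnot(length(k_vec) == 2, all(is.finite(k_vec)))
  if (sqrt(sum(k_vec^2)) <= 0) stop("pattern wave vector must be non-zero")
  if (!is.finite(modulation) || modulation <= 0 || modulation > 1) {
    stop("modulation must lie in (0, 1] so the pattern stays non-negative")
  }
  if (dc <= 0) stop("dc must be positive")
  structure(list(k_vec = as.numeric(k_vec), phases_rad = as.numeric(phases_rad),
                 modulation = modulation, dc = dc),
            class = "illumination_pattern")
}

# Rasterize one phase of a pattern on `shape` (0-based pixel coords).
pattern_image <- function(pattern, shape, phase_idx = 1L) {
  x <- seq_len(shape[1]) - 1
  y <- seq_len(shape[2]) - 1
  ph <- 2 * pi * outer(pattern$k_vec[1] * x, pattern$k_vec[2] * y, `+`) +
    pattern$phases_rad[phase_idx]
  pattern$dc * (1 + pattern$modulation * cos(ph))
}

#' Evenly rotated pattern set for multi-angle SIM
#'
#' @param n_angles number of pattern orientations (default 3).
#' @param k_fraction_of_cutoff pattern frequency as a fraction of `k_cutoff`
#'   (in (0, 1]); the standard instrument setting is ~0.8.
#' @param modulation,dc see [illumination_pattern()].
#' @param k_cutoff incoherent cutoff in cycles/pixel (see [k_cutoff()]).
#' @param angle_offset_deg orientation of the first pattern.
#' @param phases_rad per-frame phases shared by all angles.
#' @return list of [illumination_pattern()], angles evenly spaced over 180
#'   degrees.
#' @export
make_pattern_set <- function(n_angles = 3L, k_fraction_of_cutoff = 0.8,
                             modulation = 0.8, dc = 1, k_cutoff,
                             angle_offset_deg = 0,
                             phases_rad = 2 * pi * (0:2) / 3) {
  if (k_fraction_of_cutoff <= 0 || k_fraction_of_cutoff > 1) {
    stop("k_fraction_of_cutoff must lie in (0, 1]")
  }
  kmag <- k_fraction_of_cutoff * k_cutoff
  ang <- (angle_offset_deg + 180 * (seq_len(n_angles) - 1) / n_angles) * pi / 180
  lapply(ang, function(a) {
    illumination_pattern(kmag * c(cos(a), sin(a)), phases_rad, modulation, dc)
  })
}

#' Camera noise model
#'
#' Poisson shot noise on `photons_per_unit * signal` (0 disables it), then
#' additive Gaussian read noise, then a constant camera offset -- the usual
#' sCMOS forward model. Reproducible through `seed`.
#'
#' @param photons_per_unit photon conversion gain; 0 disables shot noise.
#' @param read_sigma read-noise standard deviation (image units).
#' @param camera_offset constant detector offset added last.
#' @param seed RNG seed.
#' @export
noise_model <- function(photons_per_unit = 0, read_sigma = 0,
                        camera_offset = 0, seed = 1L) {
  stopifnot(photons_per_unit >= 0, read_sigma >= 0, camera_offset >= 0)
  structure(list(photons_per_unit = photons_per_unit, read_sigma = read_sigma,
                 camera_offset = camera_offset, seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthetic sample container
#'
#' `g_in` is the in-focus sample distribution; `g_out` the out-of-focus one
#' (equal to `g_in` in the pure imaging model; a distinct layer probes model
#' mismatch). `truth_labels` records the generating structures (filament
#' polylines or bead centers with intensities) for use as oracles.
#'
#' @param g_in,g_out same-shape non-negative matrices.
#' @param pixel_nm lateral sampling (nm).
#' @param truth_labels list of structure descriptors.
#' @export
phantom <- function(g_in, g_out = g_in, pixel_nm = 65,
                    truth_labels = list()) {
  stopifnot(is.matrix(g_in), identical(dim(g_in), dim(g_out)))
  if (any(!is.finite(g_in)) || any(!is.finite(g_out)) ||
      any(g_in < 0) || any(g_out < 0)) {
    stop("phantom arrays must be finite and non-negative")
  }
  structure(list(g_in = g_in, g_out = g_out, pixel_nm = pixel_nm,
                 truth_labels = truth_labels),
            class = "phantom")
}

# Smooth random polyline: correlated random walk clamped to the margin box.
random_polyline <- function(shape, margin, step = 2, n_steps) {
  lo <- margin + 1; hix <- shape[1] - margin; hiy <- shape[2] - margin
  p <- c(stats::runif(1, lo, hix), stats::runif(1, lo, hiy))
  theta <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(0, n_steps + 1, 2)
  pts[1, ] <- p
  for (i in seq_len(n_steps)) {
    theta <- theta + stats::rnorm(1, 0, 0.15)
    cand <- p + step * c(cos(theta), sin(theta))
    if (cand[1] < lo || cand[1] > hix) { theta <- pi - theta; cand <- p + step * c(cos(theta), sin(theta)) }
    if (cand[2] < lo || cand[2] > hiy) { theta <- -theta; cand <- p + step * c(cos(theta), sin(theta)) }
    cand[1] <- min(max(cand[1], lo), hix)
    cand[2] <- min(max(cand[2], lo), hiy)
    p <- cand
    pts[i + 1, ] <- p
  }
  pts
}

polyline_length_px <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Splat polyline points onto a grid with bilinear weights.
rasterize_polyline <- function(img, pts, value = 1, oversample = 4) {
  seg <- diff(pts)
  for (i in seq_len(nrow(seg))) {
    len <- sqrt(sum(seg[i, ]^2))
    nsub <- max(2L, ceiling(len * oversample))
    t <- seq(0, 1, length.out = nsub)
    xs <- pts[i, 1] + t * seg[i, 1]
    ys <- pts[i, 2] + t * seg[i, 2]
    w <- value * len / nsub
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    for (dd in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
      wx <- if (dd[1] == 0) 1 - fx else fx
      wy <- if (dd[2] == 0) 1 - fy else fy
      idx <- cbind(x0 + dd[1] + 1, y0 + dd[2] + 1)
      ok <- idx[, 1] >= 1 & idx[, 1] <= nrow(img) & idx[, 2] >= 1 & idx[, 2] <= ncol(img)
      if (any(ok)) {
        add <- w * wx[ok] * wy[ok]
        # accumulate (indices can repeat within a segment)
        for (j in which(ok)) img[idx[j, 1], idx[j, 2]] <- img[idx[j, 1], idx[j, 2]] + w * wx[j] * wy[j]
      }
    }
  }
  img
}

#' Filament phantom (actin-like scene)
#'
#' Random smooth polyline filaments rasterized with a Gaussian cross-section.
#' A fraction of filaments is rendered at 10% of the strong intensity range
#' to emulate weakly labeled branches.
#'
#' @param shape image size (pixels), at least 64 x 64.
#' @param n_filaments number of filaments (0 gives an empty phantom with a
#'   warning).
#' @param intensity_range range of per-filament line density for strong
#'   filaments.
#' @param weak_fraction fraction (rounded to a count) of filaments rendered
#'   at 10% intensity; flagged `weak` in `truth_labels`.
#' @param fwhm_nm full width at half maximum of the filament cross-section.
#' @param pixel_nm lateral sampling (nm).
#' @param margin_px guard margin kept structure-free (periodic-boundary
#'   contract of the simulator).
#' @param length_px_range polyline length range in pixels.
#' @param non_crossing if `TRUE`, filaments are re-drawn (bounded retries)
#'   until they keep a clearance of `2 * fwhm` from previously placed ones,
#'   so each remains a separate connected component after segmentation.
#' @param rng_seed RNG seed.
#' @return a [phantom()]; `truth_labels` has one entry per filament with
#'   `points`, `intensity`, `weak`, `length_um`.
#' @export
make_filament_phantom <- function(shape = c(256L, 256L), n_filaments = 12L,
                                  intensity_range = c(0.5, 1), weak_fraction = 0,
                                  fwhm_nm = 130, pixel_nm = 65, margin_px = 24L,
                                  length_px_range = c(60, 140),
                                  non_crossing = FALSE, rng_seed = 1L) {
  stopifnot(all(shape >= 64), fwhm_nm >= pixel_nm)
  g <- matrix(0, shape[1], shape[2])
  labels <- list()
  if (n_filaments == 0) {
    warning("zero filaments requested: returning an empty phantom")
    return(phantom(g, g, pixel_nm, labels))
  }
  sigma_px <- fwhm_nm / (2 * sqrt(2 * log(2))) / pixel_nm
  with_seed(rng_seed, {
    n_weak <- round(weak_fraction * n_filaments)
    weak <- c(rep(TRUE, n_weak), rep(FALSE, n_filaments - n_weak))
    occupied <- matrix(FALSE, shape[1], shape[2])
    for (f in seq_len(n_filaments)) {
      n_steps <- ceiling(stats::runif(1, length_px_range[1], length_px_range[2]) / 2)
      pts <- NULL
      for (try in seq_len(50L)) {
        cand <- random_polyline(shape, margin_px, step = 2, n_steps = n_steps)
        if (!non_crossing) { pts <- cand; break }
        ij <- cbind(pmin(pmax(round(cand[, 1]) + 1, 1), shape[1]),
                    pmin(pmax(round(cand[, 2]) + 1, 1), shape[2]))
        if (!any(occupied[ij])) { pts <- cand; break }
      }
      if (is.null(pts)) stop("could not place a non-crossing filament after bounded retries")
      if (non_crossing) {
        clear <- ceiling(2 * fwhm_nm / pixel_nm)
        for (i in seq_len(nrow(pts))) {
          xi <- round(pts[i, 1]) + 1; yi <- round(pts[i, 2]) + 1
          xs <- max(1, xi - clear):min(shape[1], xi + clear)
          ys <- max(1, yi - clear):min(shape[2], yi + clear)
          occupied[xs, ys] <- TRUE
        }
      }
      strong_int <- stats::runif(1, intensity_range[1], intensity_range[2])
      val <- if (weak[f]) 0.1 * strong_int else strong_int
      g <- rasterize_polyline(g, pts, value = val)
      labels[[f]] <- list(points = pts, intensity = val, weak = weak[f],
                          length_um = polyline_length_px(pts) * pixel_nm / 1000)
    }
  })
  g <- gaussian_blur(g, sigma_px)
  g[g < 0] <- 0
  phantom(g, g, pixel_nm, labels)
}

#' Bead phantom (point-emitter scene)
#'
#' Sub-pixel bead centers rendered by Fourier phase-ramp shifting of a unit
#' impulse through a small Gaussian (sigma 0.5 px, peak-normalized so an
#' isolated bead's peak equals its listed intensity). Per-bead peak
#' intensities are the regression targets for the linearity metric.
#'
#' @param shape image size (pixels).
#' @param n_beads number of beads.
#' @param intensities per-bead peak intensities; default draws log-uniformly
#'   over 100..4000 (a 40x range).
#' @param min_separation_px minimum pairwise center distance (>= 3).
#' @param margin_px guard margin.
#' @param rng_seed RNG seed.
#' @param max_tries placement retries per bead before a placement error.
#' @param centers optional `n_beads` x 2 matrix of 0-based (sub-pixel) center
#'   coordinates; skips random placement.
#' @export
make_bead_phantom <- function(shape = c(256L, 256L), n_beads = 50L,
                              intensities = NULL, min_separation_px = 8,
                              margin_px = 24L, rng_seed = 1L,
                              max_tries = 2000L, centers = NULL) {
  stopifnot(min_separation_px >= 3)
  if (!is.null(centers)) {
    stopifnot(is.matrix(centers), nrow(centers) == n_beads)
  }
  with_seed(rng_seed, {
    if (is.null(intensities)) {
      intensities <- exp(stats::runif(n_beads, log(100), log(4000)))
    }
    stopifnot(length(intensities) == n_beads)
    if (is.null(centers)) centers <- matrix(0, 0, 2)
    lo <- margin_px; hix <- shape[1] - 1 - margin_px; hiy <- shape[2] - 1 - margin_px
    for (b in if (nrow(centers) == n_beads) integer(0) else seq_len(n_beads)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        c_try <- c(stats::runif(1, lo, hix), stats::runif(1, lo, hiy))
        if (!nrow(centers) ||
            min(sqrt(rowSums(sweep(centers, 2, c_try)^2))) >= min_separation_px) {
          centers <- rbind(centers, c_try)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("bead packing infeasible: could not satisfy min_separation_px = %g for bead %d of %d",
                     min_separation_px, b, n_beads))
      }
    }
  })
  kg <- k_grids(shape)
  spec <- matrix(0 + 0i, shape[1], shape[2])
  for (b in seq_len(n_beads)) {
    spec <- spec + intensities[b] *
      exp(-2i * pi * (kg$kx * centers[b, 1] + kg$ky * centers[b, 2]))
  }
  sigma <- 0.5
  kern <- exp(-((seq_len(shape[1]) - 1 - floor(shape[1] / 2))^2)/(2 * sigma^2))
  kern2 <- outer(kern, exp(-((seq_len(shape[2]) - 1 - floor(shape[2] / 2))^2)/(2 * sigma^2)))
  g <- Re(ifft2(spec * fft2(ifftshift_mat(kern2))))
  g[g < 0] <- 0
  labels <- lapply(seq_len(n_beads), function(b) {
    list(center = centers[b, ], intensity = intensities[b])
  })
  phantom(g, g, pixel_nm = 65, truth_labels = labels)
}

#' Add a defocused layer to a phantom
#'
#' Replaces `g_out` with `intensity_scale` times a heavily blurred copy of
#' `g_in`, emulating bright out-of-focus structure above/below the focal
#' plane (the regime where unfiltered SIM reconstructions show honeycomb
#' artifacts).
#'
#' @param ph a [phantom()].
#' @param intensity_scale brightness of the defocused layer relative to the
#'   in-focus scene (the stress-test scenes use 5).
#' @param blur_fwhm_nm lateral blur of the defocused layer.
#' @export
with_defocus_layer <- function(ph, intensity_scale = 5, blur_fwhm_nm = 2000) {
  stopifnot(inherits(ph, "phantom"))
  sigma_px <- blur_fwhm_nm / (2 * sqrt(2 * log(2))) / ph$pixel_nm
  ph$g_out <- intensity_scale * gaussian_blur(ph$g_in, sigma_px)
  ph$g_out[ph$g_out < 0] <- 0
  ph
}

#' Raw SIM stack container
#'
#' @param frames 4D array `[x, y, angle, phase]` of raw frames.
#' @param pixel_nm lateral sampling (nm).
#' @param patterns_truth optional list of generating [illumination_pattern()]s
#'   (one per angle).
#' @param meta free-form provenance list.
#' @export
raw_sim_stack <- function(frames, pixel_nm, patterns_truth = NULL,
                          meta = list()) {
  stopifnot(length(dim(frames)) == 4)
  if (dim(frames)[4] < 3) stop("need at least 3 phases per angle")
  if (dim(frames)[3] < 1) stop("need at least 1 angle")
  structure(list(frames = frames, pixel_nm = pixel_nm,
                 patterns_truth = patterns_truth, meta = meta),
            class = "raw_sim_stack")
}

#' @export
print.raw_sim_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Raw SIM stack: %d x %d px, %d angles x %d phases (%g nm/px)\n",
              d[1], d[2], d[3], d[4], x$pixel_nm))
  invisible(x)
}

#' Simulate a raw SIM stack through the two-layer imaging model
#'
#' Per frame, `d = [g_in * I] (x) h_in + [g_out * I] (x) h_out`, evaluated
#' periodically in Fourier space with the supplied OTF pair; then shot/read
#' noise and camera offset are applied per the noise model. With
#' `g_out = g_in` and noise disabled this realizes the imaging model exactly
#' under the package discretization.
#'
#' @param ph a [phantom()] whose shape matches `otf$shape`.
#' @param patterns list of [illumination_pattern()] (one per angle).
#' @param otf an `otf_pair` from [split_otf()] built on the frame grid.
#' @param noise a [noise_model()] (default: noiseless, zero offset).
#' @return a [raw_sim_stack()]; `meta` records the RNG algorithm and seed.
#' @export
simulate_raw_stack <- function(ph, patterns, otf, noise = noise_model()) {
  stopifnot(inherits(ph, "phantom"), inherits(otf, "otf_pair"))
  shape <- dim(ph$g_in)
  if (!identical(as.integer(shape), otf$shape)) {
    stop(sprintf("phantom shape %dx%d does not match OTF grid %dx%d",
                 shape[1], shape[2], otf$shape[1], otf$shape[2]))
  }
  nyq <- 0.5
  for (p in patterns) {
    if (max(abs(p$k_vec)) >= nyq) {
      stop("pattern frequency at or beyond the raw-grid Nyquist limit (aliasing)")
    }
  }
  n_angles <- length(patterns)
  n_phases <- length(patterns[[1]]$phases_rad)
  frames <- array(0, dim = c(shape, n_angles, n_phases))
  same_g <- identical(ph$g_in, ph$g_out)
  for (a in seq_len(n_angles)) {
    for (pidx in seq_len(n_phases)) {
      I <- pattern_image(patterns[[a]], shape, pidx)
      Gin <- fft2(ph$g_in * I)
      Gout <- if (same_g) Gin else fft2(ph$g_out * I)
      frames[, , a, pidx] <- Re(ifft2(Gin * otf$h_in + Gout * otf$h_out))
    }
  }
  if (noise$photons_per_unit > 0 || noise$read_sigma > 0) {
    with_seed(noise$seed, {
      if (noise$photons_per_unit > 0) {
        lam <- pmax(frames, 0) * noise$photons_per_unit
        frames <- array(stats::rpois(length(lam), as.vector(lam)),
                        dim = dim(frames)) / noise$photons_per_unit
      }
      if (noise$read_sigma > 0) {
        frames <- frames + array(stats::rnorm(length(frames), 0, noise$read_sigma),
                                 dim = dim(frames))
      }
    })
  }
  frames <- frames + noise$camera_offset
  raw_sim_stack(frames, ph$pixel_nm,
                patterns_truth = patterns,
                meta = list(rng = "Mersenne-Twister", seed = noise$seed,
                            noise = unclass(noise)))
}
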