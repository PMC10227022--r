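# Standard 2D-SIM Wiener reconstruction: per-angle band separation,
# illumination-parameter estimation by complex cross-correlation, sub-pixel
# band placement on a 2x grid, generalized Wiener combination with
# apodization, plus the OTF-attenuation (notch) comparator.

#' Reconstruction parameters
#'
#' @param wiener_w global Wiener regularization constant (positive).
#' @param apodization `"triangle"` (distance to the extended cutoff,
#'   default -- bounds ringing at the cost of slightly broader FWHM),
#'   `"gaussian"`, or `"none"`.
#' @param upsample lateral upsampling factor (fixed at 2 for 2D-SIM).
#' @param use_bf apply the background filter before reconstruction; bands are
#'   then combined against `H_in` (the filtered data's transfer function),
#'   otherwise against the z = 0 slice OTF.
#' @param notch optional list `(att_strength, att_fwhm_cycles)` enabling the
#'   OTF-attenuation baseline (see [notch_attenuation_baseline()]).
#' @param modulation_floor lower bound applied to the estimated modulation
#'   before dividing it out of the +/-1 bands (guards against noise blow-up).
#' @export
recon_params <- function(wiener_w = 0.05,
                         apodization = c("triangle", "gaussian", "none"),
                         upsample = 2L, use_bf = TRUE, notch = NULL,
                         modulation_floor = 0.1) {
  apodization <- match.arg(apodization)
  stopifnot(wiener_w > 0)
  if (as.integer(upsample) != 2L) stop("upsample is fixed at 2 for 2D-SIM")
  if (!is.null(notch)) {
    if (!is.list(notch) || is.null(notch$att_strength) || is.null(notch$att_fwhm_cycles)) {
      stop("notch must be a list with att_strength and att_fwhm_cycles")
    }
    if (notch$att_strength < 0 || notch$att_strength >= 1) {
      stop("att_strength must lie in [0, 1): total suppression is disallowed")
    }
    stopifnot(notch$att_fwhm_cycles > 0)
  }
  structure(list(wiener_w = wiener_w, apodization = apodization,
                 upsample = 2L, use_bf = isTRUE(use_bf), notch = notch,
                 modulation_floor = modulation_floor),
            class = "recon_params")
}

#' Separate the 0th and +/-1st order bands of one pattern angle
#'
#' Solves the per-frequency 3x3 linear phase-mixing system
#' `D_phi = C0 + e^{i phi} C+ + e^{-i phi} C-` over the three phase frames
#' (the modulation factor m/2 and the global pattern phase stay folded into
#' C+/- at this stage).
#'
#' @param frames 3D array `[x, y, 3]` (or list of 3 matrices) of raw frames.
#' @param phases the 3 nominal phase offsets (radians), pairwise distinct
#'   modulo 2 pi.
#' @return an object of class `band_set` with complex spectra `C0`, `Cp`,
#'   `Cm` on the raw-image grid.
#' @export
separate_bands <- function(frames, phases = 2 * pi * (0:2) / 3) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3, length(phases) == 3)
  M <- cbind(1, exp(1i * phases), exp(-1i * phases))
  dt <- prod(svd(M)$d)  # |det|; base det() has no complex method
  if (dt < 1e-8) {
    stop(sprintf("degenerate phase set: mixing matrix is singular (|det| = %.3g)", dt))
  }
  Minv <- solve(M)
  D <- lapply(1:3, function(j) fft2(frames[, , j]))
  comb <- function(row) Minv[row, 1] * D[[1]] + Minv[row, 2] * D[[2]] + Minv[row, 3] * D[[3]]
  structure(list(C0 = comb(1), Cp = comb(2), Cm = comb(3), phases = phases),
            class = "band_set")
}

#' Estimate the illumination pattern of one angle from its separated bands
#'
#' The product `conj(c0(r)) * c1(r)` of the real-space order-0 and order-(+1)
#' bands oscillates at the pattern frequency. Its FFT peak (restricted to
#' `|k| > min_k_frac * k_cutoff` to avoid residual-background peaks near DC;
#' exact ties break to the lowest index) gives the integer-pixel wave vector,
#' refined to sub-pixel precision by maximizing the continuous DTFT
#' magnitude. The complex factor `(m/2) e^{i phi}` then comes from an
#' OTF-weighted least-squares ratio of the two bands over their overlap
#' region, which makes the modulation estimate invariant to global intensity
#' scaling.
#'
#' @param bands a `band_set` from [separate_bands()].
#' @param otf 2D OTF (complex/real matrix on the raw grid) used for overlap
#'   weighting -- the same OTF the reconstruction will use.
#' @param k_cutoff_cycles_per_px incoherent cutoff (cycles/pixel).
#' @param min_k_frac exclusion radius for the peak search, as a fraction of
#'   the cutoff.
#' @param peak_snr significance threshold: the correlation peak must exceed
#'   `peak_snr` times the median magnitude in the search region.
#' @return an [illumination_pattern()] with estimated `k_vec`, per-frame
#'   phases (global phase + nominal offsets), and modulation (`dc` is not
#'   identifiable from the bands and is reported as 1).
#' @export
estimate_pattern <- function(bands, otf, k_cutoff_cycles_per_px,
                             min_k_frac = 0.3, peak_snr = 4) {
  stopifnot(inherits(bands, "band_set"))
  shape <- dim(bands$C0)
  c0 <- ifft2(bands$C0)
  c1 <- ifft2(bands$Cp)
  q <- Conj(c0) * c1
  Q <- fft2(q)
  kr <- kr_grid(shape)
  allowed <- kr > min_k_frac * k_cutoff_cycles_per_px & kr < 2 * k_cutoff_cycles_per_px
  mag <- Mod(Q)
  mag[!allowed] <- -Inf
  peak_val <- max(mag)
  med <- stats::median(Mod(Q)[allowed])
  if (!is.finite(peak_val) || peak_val < peak_snr * med) {
    stop(sprintf("pattern not found: correlation peak %.3g below %g x median %.3g (unusable data)",
                 peak_val, peak_snr, med))
  }
  idx <- which(mag == peak_val)[1]  # lowest index on exact ties
  ij <- arrayInd(idx, shape)
  k0 <- c(freq_axis(shape[1])[ij[1]], freq_axis(shape[2])[ij[2]])
  # Sub-pixel refinement: maximize the normalized complex cross-correlation
  # of the OTF-weighted bands over their overlap, C0(k'-k)H(k') against
  # C+(k')H(k'-k). Its magnitude is exactly 1 at the true wave vector for
  # noiseless data, so the refinement is unbiased by the scene envelope
  # (unlike a plain peak of the band-product spectrum).
  H <- otf
  rp <- radial_profile(Mod(H))
  kg <- k_grids(shape)
  overlap <- function(k_hat) {
    H_shift <- eval_radial(rp, sqrt((kg$kx - k_hat[1])^2 + (kg$ky - k_hat[2])^2))
    A <- fft2(c0 * plane_wave(shape, k_hat, sign = 1)) * H  # C0(k'-k) H(k')
    B <- bands$Cp * H_shift
    # exclude small disks around both band origins: residual (model-mismatch)
    # background concentrates there and would bias the amplitude ratio
    r_excl <- 0.15 * k_cutoff_cycles_per_px
    keep <- (kg$kx^2 + kg$ky^2 > r_excl^2) &
      ((kg$kx - k_hat[1])^2 + (kg$ky - k_hat[2])^2 > r_excl^2)
    A[!keep] <- 0; B[!keep] <- 0
    list(A = A, B = B)
  }
  obj <- function(k_hat) {
    ov <- overlap(k_hat)
    -Mod(sum(Conj(ov$A) * ov$B)) /
      sqrt(sum(Mod(ov$A)^2) * sum(Mod(ov$B)^2))
  }
  opt <- stats::optim(k0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500,
                                     parscale = rep(1 / shape[1], 2)))
  k_hat <- opt$par
  # Complex amplitude (m/2) e^{i phi} by OTF-weighted least squares over the
  # band overlap: C+(k') H(k'-k) ~ s * C0(k'-k) H(k').
  ov <- overlap(k_hat)
  s <- sum(Conj(ov$A) * ov$B) / sum(Mod(ov$A)^2)
  m <- min(2 * Mod(s), 1)
  phi <- Arg(s)
  illumination_pattern(k_hat, phases_rad = phi + bands$phases,
                       modulation = max(m, 1e-6), dc = 1)
}

# Attenuation factor of one band order at its raw-data DC position
# (kappa = -order * k_vec on the final grid).
notch_factor <- function(kg, order, k_vec, att_strength, att_fwhm_cycles) {
  sigma <- att_fwhm_cycles / (2 * sqrt(2 * log(2)))
  d2 <- (kg$kx + order * k_vec[1])^2 + (kg$ky + order * k_vec[2])^2
  1 - att_strength * exp(-d2 / (2 * sigma^2))
}

#' Generalized Wiener combination of separated bands
#'
#' Each band is placed on the 2x-upsampled grid shifted by its order times
#' the pattern wave vector (sub-pixel, via a real-space phase ramp), the
#' estimated modulation and global phase are divided out of the +/-1 orders
#' (with the configured floor on the modulation), and all bands are merged as
#' `sum(conj(OTF_b) C_b) / (sum |OTF_b|^2 + w^2)` followed by apodization and
#' an inverse FFT. Band OTFs are evaluated from the radial profile of the
#' supplied OTF at the shifted frequencies.
#'
#' @param band_sets list of `band_set` (one per angle).
#' @param otf 2D OTF on the raw grid the bands were imaged through.
#' @param patterns list of [illumination_pattern()] per angle (estimated or
#'   known).
#' @param params a [recon_params()].
#' @param k_cutoff_cycles_per_px incoherent cutoff (cycles/pixel).
#' @return an object of class `reconstruction_result`: `sr_image` (2x grid),
#'   `effective_otf` (sum of squared shifted band OTFs, unshifted layout),
#'   `patterns`, `params`, `provenance`.
#' @export
wiener_combine <- function(band_sets, otf, patterns, params = recon_params(),
                           k_cutoff_cycles_per_px) {
  stopifnot(length(band_sets) == length(patterns), length(band_sets) >= 1)
  shape <- dim(band_sets[[1]]$C0)
  up <- params$upsample
  ushape <- shape * up
  kg <- k_grids(ushape)
  # frequencies on the upsampled grid in cycles per *original* pixel
  kg <- list(kx = kg$kx * up, ky = kg$ky * up)
  rp <- radial_profile(Mod(otf))
  num <- matrix(0 + 0i, ushape[1], ushape[2])
  den <- matrix(0, ushape[1], ushape[2])
  eff <- matrix(0, ushape[1], ushape[2])
  sr_angles <- vapply(patterns, function(p) p$modulation >= params$modulation_floor,
                      logical(1))
  for (a in seq_along(band_sets)) {
    bs <- band_sets[[a]]
    pat <- patterns[[a]]
    m <- max(pat$modulation, params$modulation_floor)
    phi <- pat$phases_rad[1] - bs$phases[1]
    s <- (m / 2) * exp(1i * phi)
    comps <- list(list(order = 0, C = bs$C0))
    if (sr_angles[a]) {
      # below the modulation floor the +/-1 bands carry no usable SR content
      # and are dropped rather than amplified (ties to pattern-not-found)
      comps <- c(comps, list(list(order = +1, C = bs$Cp / s),
                             list(order = -1, C = bs$Cm / Conj(s))))
    }
    for (cc in comps) {
      if (any(!is.finite(Mod(cc$C)))) {
        stop(sprintf("NaN in separated band (angle %d, order %+d)", a, cc$order))
      }
      o <- cc$order
      b_up <- ifft2(upsample_spectrum(cc$C, up))
      if (o != 0) {
        b_up <- b_up * plane_wave(ushape, o * pat$k_vec, sign = -1, step = 1 / up)
      }
      B <- fft2(b_up)
      otf_b <- eval_radial(rp, sqrt((kg$kx + o * pat$k_vec[1])^2 +
                                      (kg$ky + o * pat$k_vec[2])^2))
      if (!is.null(params$notch)) {
        # attenuate the band content only; compensating the denominator too
        # would undo the notch through the Wiener division
        B <- B * notch_factor(kg, o, pat$k_vec,
                              params$notch$att_strength,
                              params$notch$att_fwhm_cycles)
      }
      num <- num + otf_b * B          # OTFs are real and non-negative here
      den <- den + otf_b^2
      eff <- eff + otf_b^2
    }
  }
  spec <- num / (den + params$wiener_w^2)
  kmax_pat <- if (any(sr_angles)) {
    max(vapply(patterns[sr_angles], function(p) sqrt(sum(p$k_vec^2)), numeric(1)))
  } else 0
  k_ext <- k_cutoff_cycles_per_px + kmax_pat
  kr <- sqrt(kg$kx^2 + kg$ky^2)
  apod <- switch(params$apodization,
                 triangle = pmax(1 - kr / k_ext, 0),
                 gaussian = exp(-kr^2 / (2 * (k_ext / 3)^2)),
                 none = matrix(1, ushape[1], ushape[2]))
  sr_c <- ifft2(spec * apod)
  sr <- Re(sr_c)
  structure(list(sr_image = sr, effective_otf = eff, patterns = patterns,
                 params = params,
                 provenance = list(
                   k_cutoff_cycles_per_px = k_cutoff_cycles_per_px,
                   k_extended = k_ext,
                   imag_residue = max(abs(Im(sr_c))) / max(abs(sr), 1e-300),
                   wiener_w = params$wiener_w,
                   apodization = params$apodization)),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  d <- dim(x$sr_image)
  cat(sprintf("SIM reconstruction: %d x %d px, wiener_w = %g, apod = %s\n",
              d[1], d[2], x$params$wiener_w, x$params$apodization))
  for (p in x$patterns) {
    cat(sprintf("  pattern |k| = %.4f cyc/px, phase %.3f rad, m = %.3f\n",
                sqrt(sum(p$k_vec^2)), p$phases_rad[1], p$modulation))
  }
  invisible(x)
}

#' OTF-attenuation (notch) baseline reconstruction
#'
#' The comparator used against the background filter: each band's OTF
#' weighting is multiplied by `1 - att_strength * exp(-|k - k_c|^2/(2
#' sigma^2))` centered on that band's raw-data DC position before Wiener
#' combination; the pipeline is otherwise identical. `att_strength = 0`
#' reproduces [wiener_combine()] exactly.
#'
#' @inheritParams wiener_combine
#' @param att_strength Gaussian notch depth in \[0, 1).
#' @param att_fwhm_cycles notch FWHM in cycles/pixel.
#' @export
notch_attenuation_baseline <- function(band_sets, otf, patterns,
                                       att_strength, att_fwhm_cycles,
                                       params = recon_params(use_bf = FALSE),
                                       k_cutoff_cycles_per_px) {
  params$notch <- NULL
  params <- recon_params(wiener_w = params$wiener_w,
                         apodization = params$apodization,
                         upsample = params$upsample, use_bf = params$use_bf,
                         notch = list(att_strength = att_strength,
                                      att_fwhm_cycles = att_fwhm_cycles),
                         modulation_floor = params$modulation_floor)
  if (att_strength == 0) params$notch <- NULL
  wiener_combine(band_sets, otf, patterns, params, k_cutoff_cycles_per_px)
}

#' Full BF-SIM reconstruction of a raw stack
#'
#' Orchestrates: optional background filtering of every raw frame
#' ([build_filter()] + [filter_stack()]), per-angle band separation,
#' illumination-parameter estimation, and Wiener combination. With the
#' filter on, bands are separated from the filtered frames and combined
#' against `H_in` (the filtered data's true transfer function); without it,
#' against the z = 0 slice OTF. Deterministic given its inputs.
#'
#' @param stack a [raw_sim_stack()].
#' @param otf_pair an `otf_pair` from [split_otf()] on the frame grid.
#' @param params a [recon_params()].
#' @param offset camera offset removed before filtering.
#' @param patterns optional list of known [illumination_pattern()]s per
#'   angle; skips estimation (useful for degenerate or oracle scenes).
#' @export
reconstruct <- function(stack, otf_pair, params = recon_params(), offset = 0,
                        patterns = NULL) {
  stopifnot(inherits(stack, "raw_sim_stack"))
  validate_otf_pair(otf_pair)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (params$use_bf) {
    filt <- stage("build_filter", build_filter(otf_pair))
    stack <- stage("filter_stack", filter_stack(stack, filt, offset = offset))
    otf_used <- otf_pair$h_in
  } else {
    if (offset != 0) stack$frames <- stack$frames - offset
    otf_used <- otf_pair$h0
  }
  d <- dim(stack$frames)
  nominal_phases <- 2 * pi * (seq_len(d[4]) - 1) / d[4]
  band_sets <- lapply(seq_len(d[3]), function(a) {
    stage(sprintf("separate_bands angle %d", a),
          separate_bands(stack$frames[, , a, ], nominal_phases))
  })
  if (is.null(patterns)) {
    patterns <- lapply(seq_len(d[3]), function(a) {
      stage(sprintf("estimate_pattern angle %d", a),
            estimate_pattern(band_sets[[a]], otf_used,
                             otf_pair$k_cutoff_cycles_per_px))
    })
  }
  res <- stage("wiener_combine",
               wiener_combine(band_sets, otf_used, patterns, params,
                              otf_pair$k_cutoff_cycles_per_px))
  res$provenance$use_bf <- params$use_bf
  res$provenance$offset <- offset
  res
}
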