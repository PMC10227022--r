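# Quantitative evaluation: Fourier ring correlation resolution, profile
# FWHM / Michelson contrast, peak-intensity linearity, and filament skeleton
# statistics.

#' Fourier ring correlation resolution
#'
#' `FRC(q) = Re sum F_a conj(F_b) / sqrt(sum |F_a|^2 sum |F_b|^2)` over rings
#' of one frequency-bin width. The effective resolution is the inverse of the
#' first frequency at which the curve crosses the threshold from above:
#' either the 3-sigma curve `3 / sqrt(N_q / 2)` (with `N_q` the number of
#' Fourier samples in ring q) or the fixed 1/7 level. Curves that never fall
#' below the threshold resolve to the Nyquist floor `2 * pixel_nm`; curves
#' already below it in the lowest rings (pure noise) report `"unresolved"`.
#'
#' @param img_a,img_b two same-shape, non-constant realizations of the scene
#'   (two noise realizations, or an odd/even pixel split of one image).
#' @param pixel_nm lateral sampling (nm).
#' @param threshold_mode `"three_sigma"` (default) or `"fixed_1_over_7"`.
#' @param block_size optional block edge (pixels): the images are tiled, FRC
#'   resolution is computed per block, and the mean over finite blocks is
#'   reported separately as `mean_resolution_nm` with the block map.
#' @return an object of class `frc_result` with `freqs` (cycles/pixel),
#'   `curve`, `threshold`, `resolution_nm` (number, or the string
#'   `"unresolved"`), and optionally `block_map` / `mean_resolution_nm`.
#' @export
frc_resolution <- function(img_a, img_b, pixel_nm,
                           threshold_mode = c("three_sigma", "fixed_1_over_7"),
                           block_size = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(identical(dim(img_a), dim(img_b)))
  if (stats::sd(img_a) == 0 || stats::sd(img_b) == 0) {
    stop("FRC undefined for constant images")
  }
  shape <- dim(img_a)
  n <- min(shape)
  Fa <- fft2(img_a)
  Fb <- fft2(img_b)
  r <- kr_grid(shape) * n
  bin <- round(r) + 1L
  nbins <- floor(n / 2) + 1L
  keep <- bin <= nbins
  bin_v <- bin[keep]
  cross <- tapply(Re(Fa[keep] * Conj(Fb[keep])), bin_v, sum)
  pa <- tapply(Mod(Fa[keep])^2, bin_v, sum)
  pb <- tapply(Mod(Fb[keep])^2, bin_v, sum)
  nq <- tapply(rep(1, sum(keep)), bin_v, sum)
  curve <- as.numeric(cross / sqrt(pa * pb))
  freqs <- (seq_len(nbins) - 1) / n
  thr <- switch(threshold_mode,
                three_sigma = 3 / sqrt(as.numeric(nq) / 2),
                fixed_1_over_7 = rep(1 / 7, nbins))
  res <- structure(list(freqs = freqs, curve = curve, threshold = thr,
                        threshold_mode = threshold_mode,
                        pixel_nm = pixel_nm),
                   class = "frc_result")
  # First crossing FROM ABOVE: the 3-sigma threshold exceeds 1 in the lowest
  # rings (few samples), so the curve must first establish itself above the
  # threshold at low q; images that never do are decorrelated noise.
  above <- curve >= thr
  first_above <- which(above & seq_len(nbins) > 1)[1]
  if (is.na(first_above) || first_above > 6) {
    res$resolution_nm <- "unresolved"
  } else {
    below_after <- which(!above & seq_len(nbins) > first_above)
    if (!length(below_after)) {
      res$resolution_nm <- 2 * pixel_nm      # never crosses: Nyquist floor
    } else {
      q <- below_after[1]
      # linear interpolation of the crossing between bins q-1 and q
      f0 <- freqs[q - 1]; f1 <- freqs[q]
      c0 <- curve[q - 1] - thr[q - 1]; c1 <- curve[q] - thr[q]
      fc <- f0 + (f1 - f0) * c0 / (c0 - c1)
      res$resolution_nm <- max(pixel_nm / fc, 2 * pixel_nm)
    }
  }
  if (!is.null(block_size)) {
    nbx <- floor(shape[1] / block_size); nby <- floor(shape[2] / block_size)
    bm <- matrix(NA_real_, nbx, nby)
    for (i in seq_len(nbx)) for (j in seq_len(nby)) {
      xs <- (i - 1) * block_size + seq_len(block_size)
      ys <- (j - 1) * block_size + seq_len(block_size)
      sub <- tryCatch(
        frc_resolution(img_a[xs, ys], img_b[xs, ys], pixel_nm, threshold_mode),
        error = function(e) NULL)
      if (!is.null(sub) && is.numeric(sub$resolution_nm)) {
        bm[i, j] <- sub$resolution_nm
      }
    }
    res$block_map <- bm
    res$mean_resolution_nm <- mean(bm, na.rm = TRUE)
  }
  res
}

#' @export
print.frc_result <- function(x, ...) {
  r <- if (is.numeric(x$resolution_nm)) sprintf("%.1f nm", x$resolution_nm) else x$resolution_nm
  cat(sprintf("FRC resolution (%s): %s\n", x$threshold_mode, r))
  if (!is.null(x$mean_resolution_nm)) {
    cat(sprintf("  mean block FRC: %.1f nm\n", x$mean_resolution_nm))
  }
  invisible(x)
}

# Bilinear sampling of image values at fractional 0-based coordinates.
bilinear_sample <- function(img, xs, ys) {
  x0 <- pmin(pmax(floor(xs), 0), nrow(img) - 2)
  y0 <- pmin(pmax(floor(ys), 0), ncol(img) - 2)
  fx <- xs - x0; fy <- ys - y0
  i <- x0 + 1; j <- y0 + 1
  img[cbind(i, j)] * (1 - fx) * (1 - fy) +
    img[cbind(i + 1, j)] * fx * (1 - fy) +
    img[cbind(i, j + 1)] * (1 - fx) * fy +
    img[cbind(i + 1, j + 1)] * fx * fy
}

#' Profile FWHM and contrast along a line segment
#'
#' Samples the image along the segment (bilinear interpolation at `step_px`
#' spacing, then a natural cubic spline through the samples), fits a Gaussian
#' plus constant to the dominant peak region by least squares, and reports
#' the full width at half maximum in nm together with the peak-valley
#' Michelson contrast `(I_peak - I_valley) / (I_peak + I_valley)`, where
#' `I_valley` is the mean of the two profile minima flanking the peak.
#'
#' @param image real image.
#' @param endpoints 2x2 matrix of 0-based pixel coordinates (rows = the two
#'   endpoints; sub-pixel allowed).
#' @param pixel_nm lateral sampling of `image` (nm).
#' @param step_px sampling step along the segment (pixels).
#' @return an object of class `profile_measurement` with `samples`, `t_px`,
#'   `fwhm_nm`, `contrast`, `peak`, `valley`, `fit`.
#' @export
measure_profile <- function(image, endpoints, pixel_nm, step_px = 0.25) {
  stopifnot(is.matrix(endpoints), all(dim(endpoints) == c(2, 2)))
  d <- endpoints[2, ] - endpoints[1, ]
  len <- sqrt(sum(d^2))
  nsamp <- max(16L, ceiling(len / step_px) + 1L)
  t <- seq(0, len, length.out = nsamp)
  xs <- endpoints[1, 1] + t / len * d[1]
  ys <- endpoints[1, 2] + t / len * d[2]
  raw <- bilinear_sample(image, xs, ys)
  # peak/valley/significance on the raw (bilinear) samples -- the cubic
  # spline below can overshoot, which would push contrast outside [0, 1]
  ipk_raw <- which.max(raw)
  ntail <- max(3L, round(0.1 * length(raw)))
  tails <- c(raw[seq_len(ntail)], raw[seq(length(raw) - ntail + 1, length(raw))])
  if (raw[ipk_raw] <= mean(tails) + 3 * stats::sd(tails)) {
    stop("no peak above background along the profile")
  }
  left_min <- if (ipk_raw > 1) min(raw[seq_len(ipk_raw - 1)]) else raw[1]
  right_min <- if (ipk_raw < length(raw)) {
    min(raw[seq(ipk_raw + 1, length(raw))])
  } else raw[length(raw)]
  valley <- mean(c(left_min, right_min))
  peak <- raw[ipk_raw]
  sp <- stats::spline(t, raw, n = 4 * nsamp)
  tt <- sp$x; vv <- sp$y
  ipk <- which.max(vv)
  contrast <- if (peak + valley > 0) (peak - valley) / (peak + valley) else NA_real_
  # Gaussian + offset fit around the peak
  half <- peak - (peak - valley) / 2
  lo <- ipk; while (lo > 1 && vv[lo] > half) lo <- lo - 1
  hi <- ipk; while (hi < length(vv) && vv[hi] > half) hi <- hi + 1
  w0 <- max(tt[hi] - tt[lo], 2 * step_px)
  win <- tt > tt[ipk] - 2 * w0 & tt < tt[ipk] + 2 * w0
  tw <- tt[win]; vw <- vv[win]
  ssq <- function(p) {
    mu <- p[1]; sig <- exp(p[2]); A <- p[3]; b <- p[4]
    sum((vw - (b + A * exp(-(tw - mu)^2 / (2 * sig^2))))^2)
  }
  fit <- stats::optim(c(tt[ipk], log(w0 / 2.3548), peak - valley, valley), ssq,
                      control = list(maxit = 2000, reltol = 1e-12))
  sigma_px <- exp(fit$par[2])
  fwhm_nm <- 2 * sqrt(2 * log(2)) * sigma_px * pixel_nm
  structure(list(endpoints = endpoints, t_px = tt, samples = vv,
                 fwhm_nm = fwhm_nm, contrast = contrast, peak = peak,
                 valley = valley,
                 fit = list(mu_px = fit$par[1], sigma_px = sigma_px,
                            amplitude = fit$par[3], offset = fit$par[4],
                            sse = fit$value)),
            class = "profile_measurement")
}

#' @export
print.profile_measurement <- function(x, ...) {
  cat(sprintf("Profile: FWHM = %.1f nm, contrast = %.3f\n",
              x$fwhm_nm, x$contrast))
  invisible(x)
}

#' Peak-intensity linearity between a reconstruction and a reference
#'
#' For each reference peak, the local maximum of `sr_image` within
#' `match_radius_px` of the (scaled) expected position is taken as its
#' reconstructed intensity; peaks whose local maximum sits on the search
#' window border are counted unmatched. Reports the Pearson correlation and
#' least-squares slope of reconstructed vs reference intensity.
#'
#' @param sr_image reconstructed image.
#' @param peaks data frame / list with per-peak `cx`, `cy` (0-based pixel
#'   coordinates in the *reference* frame) and `intensity` (ground truth or
#'   widefield measurement).
#' @param scale coordinate scale from reference frame to `sr_image` (2 for a
#'   2x reconstruction measured against raw-grid truth).
#' @param match_radius_px matching radius in reference pixels.
#' @return list with `r`, `slope`, `n_matched`, and the per-peak `table`.
#' @export
linearity_correlation <- function(sr_image, peaks, scale = 2,
                                  match_radius_px = 3) {
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- data.frame(cx = vapply(peaks, function(p) p$center[1], numeric(1)),
                        cy = vapply(peaks, function(p) p$center[2], numeric(1)),
                        intensity = vapply(peaks, function(p) p$intensity, numeric(1)))
  }
  if (nrow(peaks) < 10) stop("need at least 10 peaks for a linearity estimate")
  rad <- ceiling(match_radius_px * scale)
  est <- rep(NA_real_, nrow(peaks))
  matched <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cx <- round(peaks$cx[i] * scale) + 1
    cy <- round(peaks$cy[i] * scale) + 1
    xs <- max(1, cx - rad):min(nrow(sr_image), cx + rad)
    ys <- max(1, cy - rad):min(ncol(sr_image), cy + rad)
    win <- sr_image[xs, ys]
    ij <- arrayInd(which.max(win), dim(win))
    interior <- ij[1] > 1 && ij[1] < length(xs) && ij[2] > 1 && ij[2] < length(ys)
    est[i] <- max(win)
    matched[i] <- interior
  }
  if (mean(!matched) > 0.2) {
    stop(sprintf("peak matching failed: %.0f%% of peaks unmatched (> 20%%)",
                 100 * mean(!matched)))
  }
  tab <- data.frame(cx = peaks$cx, cy = peaks$cy,
                    reference = peaks$intensity, reconstructed = est,
                    matched = matched)
  use <- tab[matched, ]
  r <- stats::cor(use$reference, use$reconstructed)
  slope <- stats::coef(stats::lm(reconstructed ~ reference, data = use))[["reference"]]
  list(r = r, slope = slope, n_matched = sum(matched), table = tab)
}

# ---- thresholding -----------------------------------------------------------

#' Otsu's threshold on a 256-bin histogram
#' @param x numeric vector or matrix.
#' @return threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x) {
  v <- as.vector(x)
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * 256) + 1L, 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_bin <- which.max(sigma_b)
  rng[1] + t_bin / 256 * diff(rng)
}

#' Huang's fuzzy-entropy threshold on a 256-bin histogram
#' @inheritParams otsu_threshold
#' @export
huang_threshold <- function(x) {
  v <- as.vector(x)
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * 256) + 1L, 256L), 256L)
  lev <- seq_len(256)
  w <- cumsum(h); wt <- sum(h)
  s <- cumsum(h * lev); st <- sum(h * lev)
  best <- Inf; t_best <- 128L
  C <- max(lev) - min(lev)
  for (t in which(w > 0 & w < wt)) {
    mu0 <- s[t] / w[t]
    mu1 <- (st - s[t]) / (wt - w[t])
    mu_x <- ifelse(lev <= t, 1 / (1 + abs(lev - mu0) / C), 1 / (1 + abs(lev - mu1) / C))
    mu_x <- pmin(pmax(mu_x, 1e-12), 1 - 1e-12)
    ent <- -sum(h * (mu_x * log(mu_x) + (1 - mu_x) * log(1 - mu_x)))
    if (ent < best) { best <- ent; t_best <- t }
  }
  rng[1] + t_best / 256 * diff(rng)
}

# ---- skeletonization --------------------------------------------------------

# Zhang-Suen thinning of a logical matrix (8-connectivity).
zhang_suen_thin <- function(b) {
  pad <- matrix(FALSE, nrow(b) + 2, ncol(b) + 2)
  pad[2:(nrow(b) + 1), 2:(ncol(b) + 1)] <- b
  sh <- function(m, di, dj) {
    m[(2 + di):(nrow(pad) - 1 + di), (2 + dj):(ncol(pad) - 1 + dj)]
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      core <- pad[2:(nrow(pad) - 1), 2:(ncol(pad) - 1)]
      p2 <- sh(pad, -1, 0); p3 <- sh(pad, -1, 1); p4 <- sh(pad, 0, 1)
      p5 <- sh(pad, 1, 1); p6 <- sh(pad, 1, 0); p7 <- sh(pad, 1, -1)
      p8 <- sh(pad, 0, -1); p9 <- sh(pad, -1, -1)
      Bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nrow(core), ncol(core))
      for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
      if (phase == 1) {
        cond <- core & Bn >= 2 & Bn <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- core & Bn >= 2 & Bn <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        changed <- TRUE
        core[cond] <- FALSE
        pad[2:(nrow(pad) - 1), 2:(ncol(pad) - 1)] <- core
      }
    }
    if (!changed) break
  }
  pad[2:(nrow(pad) - 1), 2:(ncol(pad) - 1)]
}

#' Filament skeleton statistics
#'
#' Global threshold (Otsu or Huang), morphological (Zhang-Suen) thinning,
#' then per-connected-component geodesic length: skeleton pixels form an
#' 8-connected graph with edge weights 1 (orthogonal) and sqrt(2) (diagonal),
#' and a component's length is the total weight of its minimum spanning tree
#' -- the standard skeleton-length estimate. Density is the segmented
#' foreground area divided by the cell-footprint (mask) area.
#'
#' @param image real, non-constant image.
#' @param threshold_method `"otsu"` (default) or `"huang"`.
#' @param cell_mask optional logical matrix (same shape) restricting the
#'   analysis and defining the footprint area; default: whole frame.
#' @param pixel_nm lateral sampling (nm).
#' @return list with `lengths_um` (per component), `mean_length_um`,
#'   `density`, `threshold`, `n_components`, and the logical `skeleton`.
#' @export
skeleton_stats <- function(image, threshold_method = c("otsu", "huang"),
                           cell_mask = NULL, pixel_nm = 65) {
  threshold_method <- match.arg(threshold_method)
  if (stats::sd(image) == 0) stop("cannot analyze a constant image")
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(identical(dim(cell_mask), dim(image)))
  thr <- switch(threshold_method, otsu = otsu_threshold(image),
                huang = huang_threshold(image))
  binary <- image > thr & cell_mask
  density <- sum(binary) / sum(cell_mask)
  if (!any(binary)) {
    warning("empty segmentation: no foreground above the threshold")
    return(list(lengths_um = numeric(0), mean_length_um = NA_real_,
                density = density, threshold = thr, n_components = 0L,
                skeleton = binary))
  }
  skel <- zhang_suen_thin(binary)
  idx <- which(skel)
  if (!length(idx)) {
    return(list(lengths_um = numeric(0), mean_length_um = NA_real_,
                density = density, threshold = thr, n_components = 0L,
                skeleton = skel))
  }
  ij <- arrayInd(idx, dim(skel))
  id_of <- matrix(0L, nrow(skel), ncol(skel))
  id_of[idx] <- seq_along(idx)
  edges <- integer(0); wts <- numeric(0)
  offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (r in seq_len(nrow(offs))) {
    ni <- ij[, 1] + offs[r, 1]; nj <- ij[, 2] + offs[r, 2]
    ok <- ni >= 1 & ni <= nrow(skel) & nj >= 1 & nj <= ncol(skel)
    ok[ok] <- skel[cbind(ni[ok], nj[ok])]
    if (any(ok)) {
      from <- id_of[cbind(ij[ok, 1], ij[ok, 2])]
      to <- id_of[cbind(ni[ok], nj[ok])]
      edges <- c(edges, rbind(from, to))
      wts <- c(wts, rep(sqrt(sum(offs[r, ]^2)), sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges, weight = wts)
  comp <- igraph::components(g)
  lengths_px <- numeric(comp$no)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  mem <- comp$membership
  if (igraph::ecount(mst)) {
    ends <- igraph::ends(mst, igraph::E(mst))
    ew <- igraph::E(mst)$weight
    for (e in seq_along(ew)) {
      cid <- mem[ends[e, 1]]
      lengths_px[cid] <- lengths_px[cid] + ew[e]
    }
  }
  lengths_um <- lengths_px * pixel_nm / 1000
  list(lengths_um = lengths_um, mean_length_um = mean(lengths_um),
       density = density, threshold = thr, n_components = comp$no,
       skeleton = skel)
}

#' Perpendicular profile endpoints along a truth filament
#'
#' Convenience for contrast/FWHM measurements on simulated scenes: picks
#' evenly spaced anchor points along a filament's truth polyline and returns
#' segments of half-length `half_len_px` perpendicular to the local tangent,
#' in image coordinates scaled by `scale`.
#'
#' @param label one `truth_labels` entry of a filament [phantom()].
#' @param n_profiles number of anchor points.
#' @param half_len_px profile half-length in (scaled) pixels.
#' @param scale coordinate scale (2 when measuring on a 2x reconstruction).
#' @return list of 2x2 endpoint matrices for [measure_profile()].
#' @export
filament_profiles <- function(label, n_profiles = 5, half_len_px = 12,
                              scale = 2) {
  pts <- label$points
  n <- nrow(pts)
  anchors <- round(seq(0.25, 0.75, length.out = n_profiles) * (n - 1)) + 1
  lapply(anchors, function(i) {
    i0 <- max(i - 2, 1); i1 <- min(i + 2, n)
    tg <- pts[i1, ] - pts[i0, ]
    tg <- tg / sqrt(sum(tg^2))
    nv <- c(-tg[2], tg[1])
    ctr <- pts[i, ] * scale
    rbind(ctr - half_len_px * nv, ctr + half_len_px * nv)
  })
}
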