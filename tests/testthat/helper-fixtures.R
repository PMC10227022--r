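# Shared fixtures, memoized per test run. Two scales:
#  - "small": psf 64 px, frames 128 px -- unit tests
#  - "acc":   psf 128 px, frames 256 px -- acceptance criteria (paper-scale
#             optics: 488 nm / NA 1.4 / 65 nm pixels / z +/- 4 um / 100 nm)

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# default optics violate SR-passband Nyquist by design (65 nm pixels); the
# warning contract is tested explicitly in test-optics.R
quiet_optics <- function(...) {
  withCallingHandlers(
    optical_config(...),
    bfsim_nyquist_warning = function(w) invokeRestart("muffleWarning"))
}

small_optics <- function() memo("small_optics", quiet_optics(psf_size_px = 64L))
small_psf <- function() memo("small_psf", generate_psf3d(small_optics()))
small_otf <- function() {
  memo("small_otf", split_otf(small_psf(), small_optics(), shape = c(128L, 128L)))
}
small_patterns <- function() {
  memo("small_patterns", make_pattern_set(3, k_cutoff = k_cutoff(small_optics())))
}

acc_optics <- function() memo("acc_optics", quiet_optics(psf_size_px = 128L))
acc_psf <- function() memo("acc_psf", generate_psf3d(acc_optics()))
acc_otf <- function() {
  memo("acc_otf", split_otf(acc_psf(), acc_optics(), shape = c(256L, 256L)))
}
acc_patterns <- function() {
  memo("acc_patterns", make_pattern_set(3, k_cutoff = k_cutoff(acc_optics())))
}

# Direct-convolution oracle for one noiseless frame: [g * I] (x) otf_part.
frame_oracle <- function(ph, pattern, phase_idx, otf_part) {
  I <- bfsim:::pattern_image(pattern, dim(ph$g_in), phase_idx)
  Re(bfsim:::ifft2(bfsim:::fft2(ph$g_in * I) * otf_part))
}

# Peak amplitude of |FT(img)| in a small window around +/- kvec
# (kvec in cycles per *original* pixel; img may be on the 2x grid).
spot_amplitude <- function(img, kvec, n_raw, halfwin = 3L) {
  S <- Mod(bfsim:::fft2(img))
  n <- nrow(img)
  amp <- 0
  for (sgn in c(1, -1)) {
    idx <- round(sgn * kvec * n_raw)
    i <- (idx[1] %% n) + 1L
    j <- (idx[2] %% n) + 1L
    ii <- ((i - halfwin):(i + halfwin) - 1L) %% n + 1L
    jj <- ((j - halfwin):(j + halfwin) - 1L) %% n + 1L
    amp <- max(amp, max(S[ii, jj]))
  }
  amp
}

# Mean profile contrast over truth filaments; profiles that fail the
# 3-sigma peak test score 0 (structure not detected).
mean_filament_contrast <- function(img, labels, idx, pixel_nm,
                                   n_profiles = 3, half_len_px = 16) {
  cs <- c()
  for (i in idx) {
    for (ep in filament_profiles(labels[[i]], n_profiles = n_profiles,
                                 half_len_px = half_len_px)) {
      m <- tryCatch(measure_profile(img, ep, pixel_nm),
                    error = function(e) NULL)
      cs <- c(cs, if (is.null(m)) 0 else m$contrast)
    }
  }
  mean(cs)
}
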