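# simulate: phantoms, patterns, and the two-layer forward model

test_that("filament phantom is deterministic, counts weak filaments, guards margins", {
  a <- make_filament_phantom(c(128, 128), n_filaments = 20, weak_fraction = 0.25,
                             rng_seed = 4)
  b <- make_filament_phantom(c(128, 128), n_filaments = 20, weak_fraction = 0.25,
                             rng_seed = 4)
  expect_identical(a$g_in, b$g_in)
  expect_length(a$truth_labels, 20L)
  expect_equal(sum(vapply(a$truth_labels, function(l) l$weak, logical(1))), 5L)
  # weak filaments carry 10% of their strong draw, i.e. below the strong range
  weak_int <- vapply(Filter(function(l) l$weak, a$truth_labels),
                     function(l) l$intensity, numeric(1))
  expect_true(all(weak_int < 0.1))
  # guard margin: only FFT-Gaussian ringing (~1e-5 of peak) near the border
  expect_lt(max(a$g_in[1:10, ]), 1e-4 * max(a$g_in))
  expect_lt(max(a$g_in[, 1:10]), 1e-4 * max(a$g_in))
  expect_warning(e <- make_filament_phantom(c(128, 128), n_filaments = 0),
                 "empty")
  expect_equal(max(e$g_in), 0)
})

test_that("bead phantom honors peaks, separation, and packing limits", {
  shape <- c(64, 64)
  # a bead of intensity 7 placed exactly on a pixel center peaks at 7 there
  ph <- make_bead_phantom(shape, n_beads = 1, intensities = 7,
                          min_separation_px = 3, rng_seed = 2,
                          centers = matrix(c(30, 24), 1, 2))
  expect_equal(max(ph$g_in), 7, tolerance = 1e-6)
  expect_equal(as.integer(arrayInd(which.max(ph$g_in), shape)), c(31L, 25L))

  ph2 <- make_bead_phantom(c(128, 128), n_beads = 30, min_separation_px = 9,
                           rng_seed = 3)
  ctrs <- t(vapply(ph2$truth_labels, function(l) l$center, numeric(2)))
  d <- as.matrix(stats::dist(ctrs))
  expect_gte(min(d[upper.tri(d)]), 9)
  # identical seeds give identical intensity draws
  ph3 <- make_bead_phantom(c(128, 128), n_beads = 30, min_separation_px = 9,
                           rng_seed = 3)
  expect_identical(vapply(ph2$truth_labels, function(l) l$intensity, numeric(1)),
                   vapply(ph3$truth_labels, function(l) l$intensity, numeric(1)))
  expect_error(make_bead_phantom(c(64, 64), n_beads = 200,
                                 min_separation_px = 20, rng_seed = 1,
                                 max_tries = 50),
               "packing")
})

test_that("pattern sets are evenly rotated with the requested frequency", {
  ps <- make_pattern_set(3, k_fraction_of_cutoff = 0.8, k_cutoff = 0.373)
  angs <- vapply(ps, function(p) atan2(p$k_vec[2], p$k_vec[1]) * 180 / pi,
                 numeric(1))
  expect_equal(angs, c(0, 60, 120), tolerance = 1e-9)
  expect_equal(vapply(ps, function(p) sqrt(sum(p$k_vec^2)), numeric(1)),
               rep(0.8 * 0.373, 3), tolerance = 1e-12)
  # full modulation reaches an exact zero
  p1 <- illumination_pattern(c(4 / 64, 0), modulation = 1)
  img <- bfsim:::pattern_image(p1, c(64, 64), 1)
  expect_equal(min(img), 0, tolerance = 1e-12)
  expect_error(make_pattern_set(3, modulation = 1.2, k_cutoff = 0.373),
               "modulation")
  expect_error(make_pattern_set(3, k_fraction_of_cutoff = 0, k_cutoff = 0.373),
               "k_fraction")
})

test_that("noiseless simulator realizes the two-layer model identities", {
  otf <- small_otf()
  pats <- small_patterns()
  # zero phantom -> zero frames
  z <- phantom(matrix(0, 128, 128), pixel_nm = 65)
  expect_equal(max(abs(simulate_raw_stack(z, pats, otf)$frames)), 0)

  ph <- make_filament_phantom(c(128, 128), n_filaments = 5, rng_seed = 8)
  stk <- simulate_raw_stack(ph, pats, otf)
  # phase-sum identity: the 3 phases of one angle sum to 3*dc*(widefield)
  wf <- Re(bfsim:::ifft2(bfsim:::fft2(ph$g_in) * otf$h_in)) +
    Re(bfsim:::ifft2(bfsim:::fft2(ph$g_out) * otf$h_out))
  for (a in 1:3) {
    s3 <- stk$frames[, , a, 1] + stk$frames[, , a, 2] + stk$frames[, , a, 3]
    expect_lt(max(abs(s3 - 3 * wf)) / max(abs(wf)), 1e-9)
  }
  # linearity in the phantom
  ph2 <- ph; ph2$g_in <- 2 * ph$g_in; ph2$g_out <- 2 * ph$g_out
  stk2 <- simulate_raw_stack(ph2, pats, otf)
  expect_equal(stk2$frames, 2 * stk$frames, tolerance = 1e-12)
  # flux accounting at DC
  I <- bfsim:::pattern_image(pats[[1]], c(128, 128), 1)
  want <- sum(ph$g_in * I) * Re(otf$h_in[1, 1]) +
    sum(ph$g_out * I) * Re(otf$h_out[1, 1])
  expect_lt(abs(sum(stk$frames[, , 1, 1]) - want) / abs(want), 1e-9)
})

test_that("noise is reproducible and applied in the documented order", {
  otf <- small_otf(); pats <- small_patterns()
  ph <- make_filament_phantom(c(128, 128), n_filaments = 5, rng_seed = 8)
  nm <- noise_model(photons_per_unit = 100, read_sigma = 0.3,
                    camera_offset = 50, seed = 77)
  s1 <- simulate_raw_stack(ph, pats, otf, nm)
  s2 <- simulate_raw_stack(ph, pats, otf, nm)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$meta$rng, "Mersenne-Twister")
  # offset is added last: frame means sit ~offset above the noiseless means
  s0 <- simulate_raw_stack(ph, pats, otf)
  expect_equal(mean(s1$frames) - mean(s0$frames), 50, tolerance = 0.05)
})

test_that("simulator rejects incompatible inputs", {
  otf <- small_otf()
  ph64 <- make_filament_phantom(c(64, 64), n_filaments = 2, rng_seed = 1)
  expect_error(simulate_raw_stack(ph64, small_patterns(), otf), "match")
  fast <- list(illumination_pattern(c(0.55, 0)))
  ph <- make_filament_phantom(c(128, 128), n_filaments = 2, rng_seed = 1)
  expect_error(simulate_raw_stack(ph, fast, otf), "Nyquist")
})

test_that("defocus layer helper blurs and scales g_out only", {
  ph <- make_filament_phantom(c(128, 128), n_filaments = 4, rng_seed = 5)
  phd <- with_defocus_layer(ph, intensity_scale = 5, blur_fwhm_nm = 2000)
  expect_identical(phd$g_in, ph$g_in)
  expect_equal(sum(phd$g_out), 5 * sum(ph$g_in), tolerance = 1e-6)
  expect_gt(max(ph$g_in), max(phd$g_out) / 5)  # blur flattens the peak
})
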