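# recon: band separation, pattern estimation, Wiener combination, notch

test_that("separate_bands solves the phase-mixing system exactly", {
  otf <- small_otf(); pats <- small_patterns()
  ph <- make_filament_phantom(c(128, 128), n_filaments = 6, rng_seed = 3)
  stk <- simulate_raw_stack(ph, pats, otf)
  bs <- separate_bands(stk$frames[, , 1, ])
  # forward-model oracle: C+ = (m/2) e^{i phi0} FT{g e^{2 pi i k.r}} (Hin+Hout)
  pw <- bfsim:::plane_wave(c(128, 128), pats[[1]]$k_vec, sign = 1)
  want <- (0.8 / 2) * bfsim:::fft2(ph$g_in * pw) * (otf$h_in + otf$h_out)
  expect_lt(max(Mod(bs$Cp - want)) / max(Mod(want)), 1e-8)
  # order -1 equals the conjugate reflection of order +1 for real frames
  conj_reflect <- function(M) {
    n <- nrow(M)
    Conj(M)[c(1, n:2), c(1, n:2)]
  }
  expect_lt(max(Mod(bs$Cm - conj_reflect(bs$Cp))), 1e-9 * max(Mod(bs$Cp)))
  # relabeling invariance
  perm <- c(3, 1, 2)
  bs2 <- separate_bands(stk$frames[, , 1, perm], phases = 2 * pi * (0:2)[perm] / 3)
  expect_equal(bs2$C0, bs$C0, tolerance = 1e-10)
  expect_equal(bs2$Cp, bs$Cp, tolerance = 1e-10)
  # zero modulation: C+ = C- = 0 and C0 is the FT of the mean frame
  flat <- array(rep(stk$frames[, , 1, 1], 3), dim = c(128, 128, 3))
  bsf <- separate_bands(flat)
  expect_lt(max(Mod(bsf$Cp)), 1e-9 * max(Mod(bsf$C0)))
  expect_equal(bsf$C0, bfsim:::fft2(stk$frames[, , 1, 1]), tolerance = 1e-9)
  expect_error(separate_bands(flat, phases = c(0, 2 * pi, 4 * pi)), "singular")
})

test_that("estimate_pattern recovers wave vector, phase, and modulation", {
  otf <- small_otf(); pats <- small_patterns()
  ph <- make_filament_phantom(c(128, 128), n_filaments = 8, rng_seed = 3)
  stk <- simulate_raw_stack(ph, pats, otf)
  fs <- filter_stack(stk, build_filter(otf))
  for (a in 1:3) {
    bs <- separate_bands(fs$frames[, , a, ])
    pe <- estimate_pattern(bs, otf$h_in, otf$k_cutoff_cycles_per_px)
    expect_lt(sqrt(sum((pe$k_vec - pats[[a]]$k_vec)^2)) * 128, 0.05)
    expect_lt(abs(atan2(sin(pe$phases_rad[1]), cos(pe$phases_rad[1]))), 0.01)
    expect_lt(abs(pe$modulation - 0.8) / 0.8, 0.05)
  }
  # modulation estimate is invariant to global intensity scaling
  bs1 <- separate_bands(fs$frames[, , 1, ])
  bs10 <- separate_bands(10 * fs$frames[, , 1, ])
  m1 <- estimate_pattern(bs1, otf$h_in, otf$k_cutoff_cycles_per_px)$modulation
  m10 <- estimate_pattern(bs10, otf$h_in, otf$k_cutoff_cycles_per_px)$modulation
  expect_equal(m1, m10, tolerance = 1e-9)
})

test_that("integer-pixel wave vectors are recovered exactly before refinement", {
  otf <- small_otf()
  ph <- make_filament_phantom(c(128, 128), n_filaments = 8, rng_seed = 3)
  kint <- c(24 / 128, 8 / 128)
  pat <- illumination_pattern(kint, modulation = 0.8)
  stk <- simulate_raw_stack(ph, list(pat), otf)
  fs <- filter_stack(stk, build_filter(otf))
  bs <- separate_bands(fs$frames[, , 1, ])
  pe <- estimate_pattern(bs, otf$h_in, otf$k_cutoff_cycles_per_px)
  # integer peak is hit exactly; the refinement may wander by < 1e-5 cyc/px
  expect_equal(pe$k_vec, kint, tolerance = 1e-5)
})

test_that("pattern-not-found fires on structureless data", {
  otf <- small_otf()
  set.seed(1)
  noise <- array(rnorm(128 * 128 * 3) + 10, dim = c(128, 128, 3))
  bs <- separate_bands(noise)
  expect_error(estimate_pattern(bs, otf$h_in, otf$k_cutoff_cycles_per_px),
               "pattern not found")
})

test_that("degenerate single-angle, zero-modulation input reduces to Wiener widefield", {
  otf <- small_otf()
  ph <- make_filament_phantom(c(128, 128), n_filaments = 6, rng_seed = 3)
  ph$g_out <- ph$g_in * 0
  pat <- illumination_pattern(c(0.2, 0), modulation = 1e-6)
  # three identical frames = modulation 0 acquisition
  wf <- Re(bfsim:::ifft2(bfsim:::fft2(ph$g_in) * otf$h_in))
  frames <- array(rep(wf, 3), dim = c(128, 128, 3))
  bs <- separate_bands(frames)
  res <- wiener_combine(list(bs), otf$h0, list(pat),
                        recon_params(use_bf = FALSE),
                        otf$k_cutoff_cycles_per_px)
  # effective OTF support stops at the detection cutoff (no SR bands kept)
  kr <- bfsim:::kr_grid(dim(res$effective_otf)) * 2
  sup <- max(kr[res$effective_otf > 1e-6 * max(res$effective_otf)])
  expect_lt(abs(sup - otf$k_cutoff_cycles_per_px), 1.5 / 128)
  # and the output equals a direct Wiener deconvolution of the widefield image
  rp <- bfsim:::radial_profile(Mod(otf$h0))
  kg <- bfsim:::k_grids(c(256, 256))
  H <- bfsim:::eval_radial(rp, sqrt((kg$kx * 2)^2 + (kg$ky * 2)^2))
  spec <- bfsim:::upsample_spectrum(bfsim:::fft2(wf), 2L) * H /
    (H^2 + 0.05^2)
  apod <- pmax(1 - kr / otf$k_cutoff_cycles_per_px, 0)
  want <- Re(bfsim:::ifft2(spec * apod))
  expect_lt(max(abs(res$sr_image - want)) / max(abs(want)), 1e-9)
})

test_that("notch baseline: identity at zero strength, continuity, validation", {
  otf <- small_otf(); pats <- small_patterns()
  ph <- make_filament_phantom(c(128, 128), n_filaments = 6, rng_seed = 3)
  stk <- simulate_raw_stack(ph, pats, otf)
  bsets <- lapply(1:3, function(a) separate_bands(stk$frames[, , a, ]))
  base <- wiener_combine(bsets, otf$h0, pats, recon_params(use_bf = FALSE),
                         otf$k_cutoff_cycles_per_px)
  n0 <- notch_attenuation_baseline(bsets, otf$h0, pats, 0, 0.08,
                                   recon_params(use_bf = FALSE),
                                   otf$k_cutoff_cycles_per_px)
  expect_lt(max(abs(n0$sr_image - base$sr_image)), 1e-12 * max(abs(base$sr_image)))
  n1 <- notch_attenuation_baseline(bsets, otf$h0, pats, 0.50, 0.08,
                                   recon_params(use_bf = FALSE),
                                   otf$k_cutoff_cycles_per_px)
  n2 <- notch_attenuation_baseline(bsets, otf$h0, pats, 0.50 + 1e-4, 0.08,
                                   recon_params(use_bf = FALSE),
                                   otf$k_cutoff_cycles_per_px)
  expect_lt(max(abs(n2$sr_image - n1$sr_image)),
            1e-2 * max(abs(n1$sr_image)))
  expect_error(recon_params(notch = list(att_strength = 1,
                                         att_fwhm_cycles = 0.08)),
               "att_strength")
})

test_that("end-to-end exactness anchor: BF commutes with the pipeline under the model", {
  otf <- small_otf(); pats <- small_patterns()
  ph <- make_filament_phantom(c(128, 128), n_filaments = 6, rng_seed = 3)
  stk <- simulate_raw_stack(ph, pats, otf)             # g_out = g_in
  res_bf <- reconstruct(stk, otf, recon_params(use_bf = TRUE), patterns = pats)
  # oracle: directly simulated in-focus-only stack, reconstructed against the
  # same H_in without any filtering
  ph0 <- ph; ph0$g_out <- ph$g_in * 0
  otf_in_only <- otf; otf_in_only$h_out <- otf$h_out * 0
  stk0 <- simulate_raw_stack(ph0, pats, otf_in_only)
  bsets <- lapply(1:3, function(a) separate_bands(stk0$frames[, , a, ]))
  res0 <- wiener_combine(bsets, otf$h_in, pats, recon_params(use_bf = TRUE),
                         otf$k_cutoff_cycles_per_px)
  expect_lt(max(abs(res_bf$sr_image - res0$sr_image)) /
              max(abs(res0$sr_image)), 1e-6)
  # real output: conjugate symmetry holds to numerical precision
  expect_lt(res_bf$provenance$imag_residue, 1e-6)
})

test_that("reconstruct is deterministic, plane-independent, and names failing stages", {
  otf <- small_otf(); pats <- small_patterns()
  ph <- make_filament_phantom(c(128, 128), n_filaments = 8, rng_seed = 3)
  stk <- simulate_raw_stack(ph, pats, otf,
                            noise_model(photons_per_unit = 500, seed = 3))
  r1 <- reconstruct(stk, otf, recon_params())
  r2 <- reconstruct(stk, otf, recon_params())
  expect_identical(r1$sr_image, r2$sr_image)
  expect_equal(dim(r1$sr_image), c(256L, 256L))
  # plane-by-plane: an independent second plane reconstructs identically to
  # its standalone call (no state leaks between calls)
  ph2 <- make_filament_phantom(c(128, 128), n_filaments = 5, rng_seed = 99)
  stk2 <- simulate_raw_stack(ph2, pats, otf)
  alone <- reconstruct(stk2, otf, recon_params(), patterns = pats)
  after <- { reconstruct(stk, otf, recon_params());
             reconstruct(stk2, otf, recon_params(), patterns = pats) }
  expect_identical(alone$sr_image, after$sr_image)
  broken <- stk
  broken$frames[1, 1, 1, 1] <- NaN
  expect_error(reconstruct(broken, otf, recon_params()), "stage")
})
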