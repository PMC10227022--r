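# optics: configuration contracts, Born-Wolf PSF, OTF split

test_that("optical_config validates its invariants", {
  expect_error(quiet_optics(na = 1.6, refractive_index = 1.5), "propagating")
  expect_error(quiet_optics(infocus_halfrange_nm = 4000, z_halfrange_nm = 4000),
               "smaller")
  expect_error(quiet_optics(psf_size_px = 65), "even")
  expect_error(quiet_optics(pixel_nm = -1), "positive")
  # the paper-default 65 nm pixels undersample the SR passband -> warning
  expect_warning(optical_config(), class = "bfsim_nyquist_warning")
  # fine sampling is silent
  expect_silent(optical_config(pixel_nm = 40, psf_size_px = 64))
  expect_equal(k_cutoff(quiet_optics()), 2 * 1.4 * 65 / 488)
})

test_that("generate_psf3d produces the configured z grid with focus brightest", {
  cfg <- quiet_optics(psf_size_px = 32L)
  psf <- generate_psf3d(cfg)
  expect_length(psf$z_nm, 81L)               # -4000..4000 by 100
  expect_equal(range(psf$z_nm), c(-4000, 4000))
  i0 <- which(psf$z_nm == 0)
  expect_equal(sum(psf$slices[, , i0]), 1, tolerance = 1e-12)
  am <- arrayInd(which.max(psf$slices), dim(psf$slices))
  expect_equal(as.integer(am), c(17L, 17L, i0))  # lateral center, z = 0
  expect_true(all(psf$slices >= 0))
})

test_that("psf sizing error fires when the Airy core does not fit", {
  # at 20 nm pixels the first Airy zero (~212 nm) spans 10.6 px > half of 8
  expect_error(generate_psf3d(quiet_optics(pixel_nm = 20, psf_size_px = 8L)),
               "Airy")
})

test_that("z = 0 slice matches a 4x-finer Born-Wolf quadrature oracle (FWHM)", {
  cfg <- quiet_optics(psf_size_px = 64L)
  psf <- small_psf()
  i0 <- which(psf$z_nm == 0)
  ctr <- 33L
  fwhm_of <- function(prof, step_nm) {
    prof <- prof / max(prof)
    fine_x <- seq(1, length(prof), by = 0.01)
    fine <- stats::spline(seq_along(prof), prof, xout = fine_x)$y
    above <- fine_x[fine >= 0.5]
    (max(above) - min(above)) * step_nm
  }
  got <- fwhm_of(psf$slices[, ctr, i0], cfg$pixel_nm)
  # oracle: same integral, 4x finer lateral grid and quadrature
  fine <- bfsim:::born_wolf_slices(128L, cfg$pixel_nm / 4, 0,
                                   cfg$em_wavelength_nm, cfg$na,
                                   cfg$refractive_index, n_rho = 801L)
  want <- fwhm_of(fine[, 65L, 1], cfg$pixel_nm / 4)
  expect_lt(abs(got - want) / want, 0.05)
})

test_that("low-NA focal slice agrees with the Airy closed form to 2% RMS", {
  cfg <- quiet_optics(na = 0.3, refractive_index = 1.5, pixel_nm = 200,
                      psf_size_px = 64L, z_halfrange_nm = 400, z_step_nm = 200,
                      infocus_halfrange_nm = 200)
  psf <- generate_psf3d(cfg)
  slice <- psf$slices[, , which(psf$z_nm == 0)]
  x <- (seq_len(64) - 1) - 32
  r_nm <- cfg$pixel_nm * sqrt(outer(x^2, x^2, `+`))
  v <- 2 * pi / cfg$em_wavelength_nm * cfg$na * r_nm
  airy <- ifelse(v < 1e-9, 1, (2 * besselJ(v, 1) / v)^2)
  got <- slice / max(slice)
  expect_lt(sqrt(mean((got - airy)^2)), 0.02)
})

test_that("split_otf partitions energy exactly and respects the closed interval", {
  psf <- small_psf()
  cfg <- small_optics()
  otf <- small_otf()
  # Parseval at DC: H_in(0) + H_out(0) = total voxel sum
  expect_equal(Re(otf$h_in[1, 1] + otf$h_out[1, 1]), sum(psf$slices),
               tolerance = 1e-9)
  # boundary slices (|z| = halfrange) belong to in-focus: 9 slices of the
  # z = 0 neighborhood sum into H_in(0)
  in_sum <- sum(vapply(which(abs(psf$z_nm) <= 400), function(i)
    sum(psf$slices[, , i]), numeric(1)))
  expect_equal(Re(otf$h_in[1, 1]), in_sum, tolerance = 1e-9)
  # both transfer functions real (symmetric z grid) and sane at DC
  expect_true(is.numeric(otf$h_in) && is.numeric(otf$h_out))
  expect_gt(Re(otf$h_in[1, 1]), 0)
  expect_gte(Re(otf$h_out[1, 1]), 0)
})

test_that("H_in is tiny at the cutoff and zero beyond", {
  otf <- small_otf()
  rp <- bfsim:::radial_profile(Mod(otf$h_in))
  kc <- otf$k_cutoff_cycles_per_px
  at_cut <- bfsim:::eval_radial(rp, matrix(kc, 1, 1))[1]
  expect_lt(at_cut / Re(otf$h_in[1, 1]), 1e-3)
  kr <- bfsim:::kr_grid(dim(otf$h_in))
  expect_equal(max(Mod(otf$h_in)[kr > kc + 1e-9]), 0)
  expect_equal(max(Mod(otf$h_out)[kr > kc + 1e-9]), 0)
})

test_that("energy partition is invariant and monotone in the in-focus window", {
  psf <- small_psf(); cfg <- small_optics()
  totals <- c(); h_ins <- c(); h_outs <- c()
  for (hw in c(200, 400, 800, 1600)) {
    o <- split_otf(psf, cfg, infocus_halfrange_nm = hw)
    totals <- c(totals, Re(o$h_in[1, 1] + o$h_out[1, 1]))
    h_ins <- c(h_ins, Re(o$h_in[1, 1]))
    h_outs <- c(h_outs, Re(o$h_out[1, 1]))
  }
  expect_equal(max(totals) - min(totals), 0, tolerance = 1e-9)
  expect_true(all(diff(h_ins) >= 0))
  expect_true(all(diff(h_outs) <= 0))
})

test_that("split_otf rejects windows with no out-of-focus slice", {
  expect_error(split_otf(small_psf(), small_optics(),
                         infocus_halfrange_nm = 5000),
               "no out-of-focus")
  expect_error(split_otf(small_psf(), small_optics(), infocus_halfrange_nm = 50),
               ">= z_step")
})

test_that("load_psf3d round-trips, centers on the brightest page, ties to middle", {
  psf <- small_psf()
  # round-trip a thinned copy (odd page count preserved)
  keep <- seq(1, 81, by = 8)   # 11 pages incl. z = 0
  tmp <- tempfile(fileext = ".tif")
  write_tiff(tmp, lapply(keep, function(i) psf$slices[, , i]))
  got <- load_psf3d(tmp, pixel_nm = 65, z_step_nm = 800)
  expect_equal(got$z_nm, psf$z_nm[keep])
  expect_equal(got$slices, psf$slices[, , keep] / sum(psf$slices[, , 41]),
               tolerance = 1e-6)

  # brightest at 0-based page 2 of 7 -> z from -2*dz to +4*dz
  pages <- lapply(0:6, function(i) matrix(ifelse(i == 2, 5, 1), 8, 8))
  tmp2 <- tempfile(fileext = ".tif")
  write_tiff(tmp2, pages)
  got2 <- load_psf3d(tmp2, pixel_nm = 65, z_step_nm = 100)
  expect_equal(got2$z_nm, seq(-200, 400, by = 100))

  # all-identical pages: deterministic tie-break to the middle, with warning
  tmp3 <- tempfile(fileext = ".tif")
  write_tiff(tmp3, lapply(1:3, function(i) matrix(1, 8, 8)))
  expect_warning(got3 <- load_psf3d(tmp3, 65, 100), "tie")
  expect_equal(got3$z_nm, c(-100, 0, 100))

  # even page count and degenerate stacks are rejected
  tmp4 <- tempfile(fileext = ".tif")
  write_tiff(tmp4, lapply(1:4, function(i) matrix(1, 8, 8)))
  expect_error(load_psf3d(tmp4, 65, 100), "odd")
  tmp5 <- tempfile(fileext = ".tif")
  write_tiff(tmp5, lapply(1:3, function(i) matrix(0, 8, 8)))
  expect_error(load_psf3d(tmp5, 65, 100), "degenerate")
})
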