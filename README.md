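# bfsim — model-based background filtering for quantitative 2D-SIM

Structured illumination microscopy (SIM) doubles lateral resolution with a
modest photon budget, which makes it the tool of choice for live-cell
super-resolution imaging. But SIM is a widefield method: out-of-focus
fluorescence leaks through the band-separation algebra, producing honeycomb
and hammer-stroke artifacts, burying weak structures, and — when it is
suppressed with hand-tuned spectrum attenuation — breaking the linearity
between reconstructed and true fluorescence intensities that quantitative
imaging depends on.

`bfsim` is for microscopists and imaging-methods developers who need a
reconstruction whose background handling is *physical* rather than tuned.
It models every raw frame as

```
d(r) = [g·I](r) ⊗ h(r, z_in)  +  [g·I](r) ⊗ h(r, z_out)
```

with `h(·, z_in)` the 3D PSF summed over the axial-resolution window
|z| ≤ 0.4 µm and `h(·, z_out)` the 0.4–4 µm remainder. Under that model the
defocused background of a frame is known exactly in Fourier space, and its
removal is a fixed, parameter-free linear filter:

```
d_in(r) = d(r) − iFt{ D(k) · W(k) },      W = H_out / (H_in + H_out)
```

The filtered frames then enter a standard Wiener-SIM reconstruction
(3-phase band unmixing, correlation-based pattern estimation, sub-pixel
band shifting on a 2× grid, generalized Wiener combination with
apodization). The package also ships a Born–Wolf 3D PSF generator and a
loader for measured PSF stacks, a forward-model simulator that realizes the
imaging equation exactly (so every stage has a machine-precision oracle),
an OTF-attenuation ("notch") baseline for comparison, and evaluation
metrics: FRC resolution, profile FWHM/contrast, peak-intensity linearity,
and filament skeleton statistics. Everything reads and writes multi-page
TIFF plus JSON sidecars, with a small `bfsim` CLI (`inst/cli/bfsim`).

## Worked example

An actin-like scene with a 5×-intensity defocused layer — the regime where
plain Wiener-SIM shows pattern-frequency artifacts:

```r
library(bfsim)
cfg  <- optical_config(psf_size_px = 128)     # 488 nm, NA 1.4, 65 nm px (warns: SR Nyquist)
psf  <- generate_psf3d(cfg)
otf  <- split_otf(psf, cfg, shape = c(256, 256))
filt <- build_filter(otf)

ph   <- make_filament_phantom(c(256, 256), n_filaments = 8,
                              weak_fraction = 0.25, rng_seed = 11)
phd  <- with_defocus_layer(ph, intensity_scale = 5, blur_fwhm_nm = 2000)
pats <- make_pattern_set(3, k_cutoff = k_cutoff(cfg))
stk  <- simulate_raw_stack(phd, pats, otf,
                           noise_model(photons_per_unit = 500, seed = 7))

res_bf  <- reconstruct(stk, otf, recon_params(use_bf = TRUE))
res_off <- reconstruct(stk, otf, recon_params(use_bf = FALSE))

weak <- which(sapply(ph$truth_labels, function(l) l$weak))
ep   <- filament_profiles(ph$truth_labels[[weak[1]]], n_profiles = 3)[[3]]
measure_profile(res_bf$sr_image,  ep, 32.5)
measure_profile(res_off$sr_image, ep, 32.5)
```

which prints:

```
OTF pair on 256 x 256 grid: H_in(0) = 9, H_out(0) = 71.73, k_cutoff = 0.3730 cyc/px
Background filter on 256 x 256 grid: W(0) = 0.8885
SIM reconstruction: 512 x 512 px, wiener_w = 0.05, apod = triangle
  pattern |k| = 0.2983 cyc/px, phase 0.039 rad, m = 0.732
  ...
Profile: FWHM = 174.4 nm, contrast = 0.863     # BF-SIM, weak filament
Profile: FWHM = 204.7 nm, contrast = 0.164     # plain Wiener, same profile
```

Reading it: 89% of the total collected DC flux is modeled as defocused
(`W(0) = 0.89`) — that is what an 8 µm fluorescent column does to a
high-NA widefield image. After filtering, the weak (10%-intensity) filament
stands at Michelson contrast 0.86 in the BF reconstruction versus 0.16 in
the unfiltered one, with the estimated pattern wave vector recovered to a
fraction of a frequency bin (truth: 0.2984 cyc/px). On the same scenes, the
pattern-frequency "spots" in the reconstructed spectrum are ~30× weaker
with BF than without, and 50-bead scenes over a 40× intensity range
reconstruct with peak-intensity linearity r ≈ 0.997 against ground truth.

The same pipeline from the shell:

```sh
bfsim simulate --preset filaments --seed 7 --shape 256 --output raw.tif
bfsim reconstruct --input raw.tif --use-bf --output sr.tif
bfsim filter --input raw.tif --offset 0 --output filtered.tif
```

## Honest limitations

On a scene with *no* out-of-focus emitters the filter still removes the
modeled background share of every Fourier coefficient (exactly `1 − W(k)`),
so BF-on and BF-off reconstructions of a purely in-focus scene correlate at
r ≈ 0.85, not ≥ 0.999 — that acceptance test is kept red by design. The
methods vignette (`vignettes/background-filtered-sim.Rmd`) documents this,
the simulator's scope, and every numerical design choice.
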