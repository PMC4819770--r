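# nanosep

Nanometer-scale separation measurement for two-color RNA-FISH
transcription foci imaged on a conventional widefield microscope.

## The problem

Intronic RNA-FISH marks nascent transcripts — and therefore active gene
loci — as diffraction-limited spots (~200 nm). The biological questions
live at tens of nanometers: is the promoter-proximal focus on top of the
focus made by a polymerase far downstream, or displaced from it? A
standard fluorescence microscope cannot *resolve* two such foci, but when
the two targets are labeled in different colors, the *center* of each
spot can be localized far more precisely than the diffraction limit, and
the distance between the two centers measured with nanometer-scale
uncertainty. `nanosep` implements that measurement chain for people
doing two-color smFISH colocalization on ordinary widefield hardware:

1. **Spot QC** — candidate foci must be Gaussian-like, bright enough
   (peak well above background) and locally contrasted.
2. **Sub-pixel localization** — least-squares 2D Gaussian fitting (the
   workhorse), plus centroid and Poisson maximum-likelihood estimators.
3. **Localization precision** — per-axis uncertainty of a fitted center,
   \[ \sigma = \sqrt{\frac{s^2}{N} + \frac{a^2}{12N}
      + \frac{8\pi s^4 b^2}{a^2 N^2}} \]
   with `s` the Gaussian PSF width (`s = 0.21 λ / NA`), `N` the photons
   in the spot, `a` the pixel size and `b` the background noise in
   photons/pixel.
4. **Chromatic registration** — a local-weighted-mean transform built
   from multispectral fiducial beads maps channel B into the channel-A
   frame; the residual misalignment `r` is measured on held-out beads.
5. **Separation analysis** — mutual-nearest pairing of two-color foci,
   Euclidean separation `d`, combined uncertainty
   `sqrt(σ_A² + σ_B² + r²)` (a separation is meaningful only if `d`
   exceeds it), 30-nm-bin histograms with Gaussian fits normalized to
   equal areas.
6. **Synthetic imaging** — a ground-truth-annotated generator
   (pixel-integrated Gaussian PSF, Poisson shot noise, camera gain and
   read noise, smooth inter-channel warps) so the whole chain is testable
   without a microscope.
7. **Probe design helper** — GC-matched 50-mer windows, fluor-spacing
   assignment (>8 nt apart), 20-mer genomic uniqueness, minimal-span
   probe sets within 600 nt.

## Worked example

Simulate a bead calibration and a two-color nucleus scene, register the
channels, and measure the separations:

```r
library(nanosep)
library(tibble)

frame  <- frame_geometry(128, 128, pixel_size_nm = 200)
red    <- optics_model(594, 1.45)   # Alexa-594-like channel
farred <- optics_model(647, 1.45)   # Alexa-647-like channel
cfg    <- run_config(frame = list(width_px = 128, height_px = 128))

# a day's chromatic aberration, and the bead field that measures it
warp  <- warp_random(frame, max_displacement_nm = 30, seed = 5)
beads <- render_bead_field(40, warp, frame, red, farred,
                           noise_model(5, 2, 1), seed = 11,
                           bead_photons = 20000)
model <- cmd_register(beads$image_a, beads$image_b, cfg)
glance(model)
#> # A tibble: 1 × 5
#>   n_pairs     k grid_pitch_px evaluation residual_nm
#>     <int> <int>         <dbl> <chr>            <dbl>
#> 1      24    12             8 grid              2.16

# three focus pairs at true separations 0, 68 and 150 nm
scene <- render_nucleus_scene(
  tibble(x_nm = c(6000, 14000, 20000), y_nm = c(6000, 18000, 9000),
         separation_nm = c(0, 68, 150)),
  frame, red, farred, noise_model(10, 2, 1), warp, seed = 24,
  photons = 2000)

res <- cmd_measure(scene$image_a, scene$image_b, model, cfg)
dplyr::select(res$separations, d_nm, sigma_a, sigma_b,
              combined_uncertainty_nm, significant)
#> # A tibble: 3 × 5
#>     d_nm sigma_a sigma_b combined_uncertainty_nm significant
#>    <dbl>   <dbl>   <dbl>                   <dbl> <lgl>
#> 1 150.      2.35    2.43                    4.01 TRUE
#> 2  71.4     2.34    2.48                    4.04 TRUE
#> 3   3.07    2.32    2.51                    4.04 FALSE
```

Reading the output: the bead model re-aligns the channels to a residual
misalignment of 2.2 nm; at 2000 photons per focus each center is
localized to ~2.4 nm, so the combined uncertainty per separation is
~4 nm. The 68- and 150-nm pairs are recovered within a few nm and
flagged significant; the truly colocalized pair measures 3.1 nm — below
its combined uncertainty, hence not a real separation. Histograms and
their fitted Gaussians come from `histogram_separations()` +
`fit_histogram_gaussian()` and plot with `autoplot()`.

A thin command-line wrapper over the same functions is installed at
`inst/cli/nanosep.R` (`simulate`, `register`, `measure`, `probes`
subcommands; TIFF/TSV/FASTA/YAML in and out).

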