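# ctpipe

A CPU reference implementation of the processing pipeline used for
parallel-beam / slightly-cone-beam synchrotron micro-CT: from a raw HDF5
acquisition (16-bit projections, flat fields and dark fields with rotation
angles) to a 32-bit floating-point reconstructed volume. It is aimed at
beamline and imaging scientists who want a small, fully inspectable,
deterministic counterpart to production GPU pipelines — for algorithm
verification, teaching and test-data generation — and it ships a synthetic
acquisition simulator so every stage can be exercised with no external
data.

## What it computes

The pipeline has the three canonical sections, applied in order:

**1. Raw correction.** Each raw projection *I* is normalised by the
averaged references,

```
I_cor = (I - D̄) / (F̄ - D̄)
```

with *D̄* the averaged dark intensity and *F̄* the averaged flat intensity;
defective pixels (robust MAD outliers in the reference statistics, or dead
flat response) are repaired from their neighbourhood median; an optional
threshold median filter suppresses impulses; projections can be trimmed;
tiled sub-scans are stitched by dead reckoning (motor positions) or by
phase-correlation refinement of the overlap regions.

**2. Pre-processing.** Single-distance TIE-Hom phase retrieval for a
homogeneous object multiplies the 2-D spectrum of `I_cor` (padded to the
next power of two) by the low-pass response

```
H(u) = 1 / (1 + π λ z γ |u|²),      γ = δ/β
```

where *λ* is the X-ray wavelength, *z* the propagation distance and *u* the
transverse spatial frequency — suppressing propagation fringes and boosting
the contrast of slight density differences. Beam hardening from a
polychromatic beam is corrected by the second-order linearisation
`f(p) = p + C₂ p²` of the attenuation values, with *C₂* adjusted until
cupping disappears.

**3. Reconstruction.** The centre of rotation is estimated by Fourier
correlation of a 180°-separated projection pair (the second mirrored; half
the correlation shift is the axis offset) and the projection set is
re-aligned; ring artefacts — stripes in the sinogram — are removed by
stripe-sorting and large-stripe detection applied sequentially; slices are
reconstructed by filtered back-projection (ramp filter apodised by
Ram–Lak / Shepp–Logan / Cosine / Hamming / Hann windows, scaled `π/n` over
180°), or by FDK cone-beam weighting for a finite source distance; a circle
mask (default 98% of the width) trims the corners. Limited-angle subsets
and memory-bounded streaming slab reconstruction (bit-identical to the
single pass) are supported.

The simulator forward-models all of it analytically: exact ellipse Radon
transforms, beam profile, detector offset and read noise, Poisson photon
statistics, planted bad pixels and column-gain stripes, axis misalignment,
TIE propagation fringes, two-component polychromatic hardening, tiled
sub-scans, and 16-bit quantisation — with every planted parameter recorded
in the file metadata for recovery tests.

## Worked example

```r
library(ctpipe)

g   <- scan_geometry(n_projections = 101, detector_rows = 4, detector_cols = 64,
                     pixel_size_um = 6.5, energy_keV = 20)
acq <- simulate_acquisition(default_phantom(64), g,
                            artefact_model(cor_offset_px = 2, seed = 1),
                            n_flats = 4, n_darks = 4)
vol <- reconstruct_pipeline(acq)
```

prints

```
<recon_volume> 64 x 64 x 4 float32 voxels @ 6.5 um, 6 stage(s)
estimated COR offset: 1.950 px (planted: 2)
slice RMSE: 0.046 of the phantom value range
```

— the automatic COR search recovered the planted 2-pixel axis offset to
0.05 px, and the reconstructed slice matches the analytic phantom to under
5% of its value range (the residual is Gibbs ringing at the shell edges at
this small raster). Scan planning arithmetic works the same way:

```r
plan_sizes(c(2560, 2560, 2160), proj_dims = c(1820, 2160, 2560))
#> <size_plan> volume 2560 x 2560 x 2160 float32 = 56,623,104,000 bytes (52.7 GiB ~ 53 GB)
#>   raw 16-bit input: 18.7 GiB
min_projection_count(2560)
#> 4022                       # the pi/2 sampling rule
```

A command-line launcher (`inst/exec/ctpipe`) exposes the same machinery as
`simulate | process | info | plan` subcommands driven by YAML configs
validated against the schema in `inst/schema/pipeline-config.yaml`.

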