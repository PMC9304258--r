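# eedn — edge-enhancement denoising for low-dose X-ray fluoroscopy

Fluoroscopy guides catheters during cardiac electrophysiology procedures at
the lowest X-ray dose the operator can tolerate, and at that dose the images
are dominated by Poisson quantum noise. Denoising can buy back image quality
— effectively a dose increase without the radiation — but conventional CNN
denoisers over-smooth exactly the content cardiologists need: anatomical
borders and thin curvilinear devices. This package implements, end to end,
an **edge-enhancement denoising network (EEDN)** for single fluoroscopy
frames, together with the noise simulation, training procedure, quality
metrics and frequency-spectrum analysis needed to evaluate it — all testable
on synthetic fluoroscopy phantoms, with no clinical data required.

For R users in medical imaging and image-restoration research, the package
provides:

* **Degradation model** (`addPoissonNoise`, `buildTrainingSet`): every pixel
  receives an independent `Poisson(λ)` draw with `λ = μ·α/100`, where `μ` is
  the percentage noise level and `α` the clean-frame mean intensity; the
  clinical fluoroscopy regime corresponds to `μ ≈ 60%`. Training corpora mix
  noise levels following a Gaussian `N(60, 20²)` over 10–100% in 10% bins.
* **The network** (`buildModel`, `denoise`, `trainModel`): an initial
  denoiser built from ultra-dense blocks (UDBs) produces `I_inter`; its
  4-neighbour Laplacian gives the edge map `I_edge`; a stride-2 encoder, a
  parallel UDB stack gated by a 6-layer attention block, and a
  deconvolutional decoder enhance it to `I_edge+`; the output composes as

      I_output = I_inter + I_edge+ − I_edge

  The Charbonnier loss `ρ(x) = √(x² + ε²)` (ε = 10⁻³) is minimized with
  batches of 16 patches of 96×96 and a learning rate of 10⁻³ halved every
  2000 steps. The 6-UDB baseline (UDDN) is included for comparison.
* **Metrics** (`psnr`, `ssim`, `localSNR`, `relativeDose`): reference-based
  PSNR/SSIM for synthetic data, and the reference-free mean local SNR
  (per-tile μ/σ over 16×16 tiles) for clinical-style evaluation; since
  SNR ∝ √dose for quantum noise, `relativeDose` converts an SNR ratio into
  the implied dose ratio.
* **Spectrum analysis** (`radialProfile`, `transferRatio`, `bandpassFilter`,
  `bandConsensus`, `nyquistCyclesPerMm`): radially averaged DFT magnitude,
  rescaled to cycles/mm from the acquisition geometry (detector spacing
  demagnified by SED/SID), frequency-transfer curves between processed and
  input frames, and the brick-wall bandpass used to locate the band of
  clinically useful content.
* **Phantoms** (`generatePhantom`, `generateDataset`): deterministic
  synthetic fluoroscopy frames — smooth anatomy-like background, dark
  catheter-like spline tracks, sharp step edges — so the whole pipeline
  runs and is tested without any external data.
* **I/O** (`readFrame`, `writeFrame`): 8/16-bit grayscale PNG/TIFF and
  uncompressed DICOM, including the geometry tags that drive the Nyquist
  rescaling.

The methods vignette (`vignettes/fluoroscopy-denoising.Rmd`) documents the
models, every reconstructed architectural detail, and the numerical
choices.

## A worked example

```r
library(eedn)

spec  <- defaultPhantomSpec(size = c(256L, 256L))
clean <- generatePhantom(spec)
noisy <- addPoissonNoise(clean, NoiseSpec(muPercent = 60, seed = 1L))

clean
#> ImageFrame 256x256, 8-bit, 0.5 mm/px
#>   intensity range [71.95, 187.8]

psnr(clipFrame(noisy), clean)          # 9.22 dB
ssim(clipFrame(noisy), clean)          # 0.7733
localSNR(clean)@meanSnr                # 129.3
localSNR(noisy)@meanSnr                # 23.3

# SNR ratio -> implied dose ratio (SNR proportional to sqrt(dose)):
relativeDose(24.5, 11.3)               # 4.70 - the clinical worked example
radialProfile(noisy)
#> SpectrumProfile: 182 annuli, Nyquist 1 cycles/mm
bandConsensus(list(c(0.051, 0.254), c(0.079, 0.289)))$consensus
#> Band: 0.079 - 0.254 cycles/mm
```

The 60% degradation drops the PSNR to ~9 dB — the added noise has positive
mean `λ`, a deliberate property of the literal degradation model (see the
vignette) — and the mean local SNR from ~129 to ~23. Training a small EEDN
on phantom patches and denoising held-out degraded frames recovers both;
that full study is what the acceptance script below runs.

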