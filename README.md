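# myoquant

Quantification pipelines for comparative cardiac-injury studies, in R.

After myocardial infarction (ligation of the left anterior descending
coronary artery), study read-outs span very different modalities: ECG QRS
morphology, M-mode echocardiography, trichrome and Evans-blue section
morphometry, picrosirius birefringence under polarized light, collagen
fiber architecture (waviness, structure-tensor anisotropy, box-counting
fractal dimension and lacunarity), fluorescence cell-counting recipes
(proliferation, dividing cardiomyocytes, arteries, fibroblast coverage),
and expression-level cardiomyocyte maturation analytics. `myoquant`
re-implements each of these quantification stages as tested functions —
the setting is a spiny mouse (*Acomys cahirinus*) versus laboratory mouse
(*Mus musculus*) comparison, but the machinery is generic — together with
synthetic-data generators that produce every input with known ground
truth, so the whole pipeline is verifiable without any external data.

The core quantities, in the field's standard notation:

* **ECG**: per-beat Q/R/S amplitudes relative to the isoelectric baseline
  and durations between the 5%-of-peak baseline re-crossings;
  `HR = 60 / mean(RR)`.
* **Echo**: `FS = (LVID;d − LVID;s)/LVID;d × 100%` and
  `EF = (LVID;d³ − LVID;s³)/LVID;d³ × 100%`, parameters averaged over five
  replicates before the formulas.
* **Morphometry**: scar fraction = area(H 140–200 gate)/area(H 60–255
  gate), averaged over six serial levels; hue-binned birefringence with
  total birefringence set to 100%; wall thickness along five centroid rays.
* **Fibers**: waviness `W = L_curved / L_chord ≥ 1`; anisotropy
  `(λ₁−λ₂)/(λ₁+λ₂)` of the structure tensor; box-counting
  `D = slope of log N(ε) vs log(1/ε)` (minimal cover over slipped grids)
  and lacunarity `Λ = mean((σ/μ)² + 1)` of box masses.
* **Counting**: ImageJ-style recipes (rolling-ball background, median
  filters, Default/Yen/Triangle/Moments thresholds, particle analysis with
  edge exclusion and hole filling), a ≥ 10 µm Feret gate for arteries.
* **Maturation**: variable genes (variance > 0.5, > 1 FPKM in ≥ 3
  samples), per-PC loading selection (|loading| > 0.2, ≤ 50 genes/PC),
  Pearson sample networks (r > 0.6), cumulative gene-set z-score sums, and
  the Tnni3/Tnni1, Myl2/Myl7 ratiometric maturation signature.

## Worked example

```r
library(myoquant)

# a 60 s murine ECG at 480 bpm with 10 dB noise, plus its ground truth
g <- gen_ecg(ecg_sim_spec(sampling_rate = 1000, duration = 60,
                          heart_rate = 480, snr_db = 10, seed = 1))
peaks <- detect_r_peaks(g$trace)
qrs <- segment_qrs(g$trace, peaks)
summarize_qrs(qrs)
#> <qrs_summary> 480 beats, heart rate 480.0 bpm
#>   Q: amplitude -0.203 +/- 0.040 mV, duration 10.35 +/- 5.66 ms
#>   R: amplitude +1.000 +/- 0.044 mV, duration 6.69 +/- 2.87 ms
#>   S: amplitude -0.300 +/- 0.042 mV, duration 8.21 +/- 3.71 ms

# ejection fraction / fractional shortening from five M-mode replicates
summarize_echo(mmode_measurements(LVID_d = rep(4.0, 5), LVID_s = rep(3.0, 5)))
#> <echo_summary> EF 57.81%, FS 25.00% (n = 5 replicates)

# scar fraction of a synthetic trichrome section with a 30% planted scar
sec <- gen_section(section_sim_spec(image_size = 400,
                                    scar_fraction_target = 0.30,
                                    hue_jitter = 10, seed = 2))
scar_area_fraction(sec$image)$fraction
#> [1] 0.3
```

The detected heart rate (480 bpm), the R amplitude (1.0 mV, the generator's
setting), the EF/FS pair (57.81%, 25.00% — the cubic versus linear diameter
formulas at LVID;d = 4 mm, LVID;s = 3 mm) and the recovered scar fraction
(0.30) all match their planted ground truth.

The numbered scripts under `analysis/` run each stage end to end on
synthetic data and write their tables under `results/`:

```sh
Rscript analysis/01_cardiac_function.R
Rscript analysis/02_scar_morphometry.R
Rscript analysis/03_fiber_architecture.R
Rscript analysis/04_cell_quantification.R
Rscript analysis/05_maturation_transcriptomics.R
```

The methods vignette (`vignettes/methods.Rmd`) documents the models,
conventions and design choices behind every stage.

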