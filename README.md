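# xpct

Quantitative virtual histology by simulated propagation-based x-ray
phase-contrast tomography (XPCT).

Synchrotron XPCT images unstained, paraffin-embedded nervous tissue through
the phase shifts the specimen imprints on a coherent hard x-ray beam. The
refractive index is n = 1 − δ + iβ with

    δ = r_e λ² ρ_e / (2π),

so a reconstructed δ volume is — up to the known constant — a 3D map of
electron density ρ_e (e/nm³), and the uniform paraffin matrix (328 e/nm³
for CH₂ paraffin at 0.9554 g/cm³) provides an absolute calibration anchor.
This makes label-free, quantitative densitometry of neurodegenerative
inclusions possible: Lewy bodies, Hirano bodies, granulovacuolar
degeneration (GvD), amyloid plaques, neuromelanin.

`xpct` implements the whole measurement as a reproducible simulation and
analysis pipeline for method development and validation:

- **Phantoms** with exact ground truth: neuron somata (nucleus, nucleolus),
  Lewy bodies (core/halo/rim inclusions), rod-shaped Hirano bodies that
  pierce the cell border, GvD vacuoles with central grains, cored plaques,
  neuromelanin clusters, vessels — each with configurable electron density.
- **Forward optics**: projection, multi-distance Fresnel propagation in the
  holographic regime (F ≪ 1), detector gain, Poisson noise, flat/dark
  frames; cone-beam geometries via the Fresnel scaling theorem.
- **Phase retrieval**: multi-distance CTF, single-distance Paganin,
  nonlinear Tikhonov (NLT) refinement; ring suppression.
- **Reconstruction**: rotation-axis correction, 360°→180° folding,
  filtered back projection (Ram-Lak / Shepp-Logan / Hann).
- **Densitometry**: δ→ρ_e conversion, offset calibration on the paraffin
  background, per-compartment distribution statistics.
- **Statistics & segmentation**: exact/approximate Mann-Whitney U with
  Bonferroni correction, box-plot reports, Otsu/fixed thresholding and 3D
  seeded watershed.

## A worked example

The default study configuration is a 160³ phantom at 100 nm voxels holding
one neuron with a Lewy body, 18 GvD vacuoles, a neuromelanin cluster and a
Hirano body, plus three extrasomal plaques and a vessel; it is acquired at
17.1 keV over 181 angles and four distances with 5000 photons/pixel:

```r
library(xpct)

cfg <- default_run_config(seed = 1, outdir = "run1")
manifest <- run_pipeline(cfg)
print(manifest)
#> run_manifest (config f3413f74 )
#>   phantom       2.2s  5 file(s)
#>   acquire      87.5s  5 file(s)
#>   retrieve     40.9s  2 file(s)
#>   reconstruct  11.4s  2 file(s)
#>   calibrate     8.8s  3 file(s)
#>   quantify      0.0s  1 file(s)
#>   report       15.1s  2 file(s)

stats <- read_table_csv(file.path("run1", "roi_stats.csv"))
stats[stats$class == "gvd", c("compartment", "n_voxels", "rel_mean",
                              "rel_median")]
#>    compartment n_voxels   rel_mean rel_median
#> 9        lumen     7590  0.4424814  0.4916815
#> 10       grain      311 11.6897042 11.4178888
```

`rel_*` columns are electron densities relative to the paraffin reference
(e/nm³) after calibration. Here the GvD vacuole lumens — which the phantom
assigns the embedding density — read back at ≈0 (+0.5 in this noise
realization), and the grains at ≈+11.5 (+12 configured, slightly reduced by
partial volume at their 0.5 µm size): the pipeline recovers the "nearly
protein-free vacuole" signature quantitatively. `run1/report.csv` adds pairwise Mann-Whitney/Bonferroni
comparisons between all compartments and `report.png` the box-plot panel.

Every stage writes TIFF/JSON/CSV artifacts plus a manifest with md5
checksums; re-running with the same seed reproduces them bit for bit. A
thin command-line wrapper is installed at `inst/cli/xpct.R`
(`Rscript xpct.R run --seed 1 --outdir out`).

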