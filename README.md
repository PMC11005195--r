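# fretbench

Quantification toolkit for FRET-based ERK activity imaging in zebrafish
embryos, with a synthetic-microscopy phantom generator providing ground truth
for every analysis stage.

## The problem

Genetically encoded ERK biosensors (EKAREV-type, expressed in the zebrafish
*Teen* line) report kinase activity through intramolecular Förster resonance
energy transfer between a CFP donor and a YPet acceptor: phosphorylation of
the sensor's substrate domain closes the molecule and raises transfer
efficiency. Two complementary readouts quantify this in embryos:

* **Ratiometric spectral imaging (live):** a lambda stack is acquired under
  458 nm excitation (462–572 nm collection, 5 or 7 nm detection steps), split
  into donor (465–500 nm) and acceptor (525–570 nm) channels, and the *FRET
  index* — the raw integrated density of the acceptor/donor ratio image
  within an ROI, computed on sum-intensity z-projections — is compared across
  genotypes and MEK-inhibitor doses as fold changes.
* **Acceptor photobleaching (fixed):** after 50 bleach iterations of the
  acceptor inside an ROI, the donor de-quenches, and the transfer efficiency
  is estimated as

  ```
  E = (D_Ω − D_A) / D_Ω
  ```

  where `D_A` and `D_Ω` are the ROI-mean donor intensities before and after
  bleaching. The donor–acceptor distance follows from the Förster relation

  ```
  R_DA = R0 · (1/E − 1)^(1/6),   R0 = 4.7 nm (CFP–YFP pair)
  ```

Around these sit the morphological disease readouts of the Noonan-syndrome
(Shp2-D61G) model — the major/minor axis ratio of the ~11 hpf embryo and the
body length of hatched larvae — and the biochemical validation readouts
(immunoblot densitometry with GAPDH normalisation, immunofluorescence
pERK/tERK integrated-density ratios).

Because raw confocal data of this kind are rarely deposited, every stage here
runs against a **phantom generator** (`make_embryo_phantom()`,
`make_cohort()`, `make_morphology_phantom()`, `make_gel_phantom()`) whose
per-pixel sensor activity, FRET efficiency, group effects and dose responses
are known exactly — so estimator accuracy, bias and power are all testable.

## Worked example

```r
library(fretbench)

ph <- make_embryo_phantom("gastrula_5hpf", shape = c(96, 96),
                          domain_activities = c(margin = 0.6, bulk = 0.2),
                          seed = 7)
ph
#> <activity_phantom> stage gastrula_5hpf, 96x96 px, domains: bulk, margin
#>   bulk       mean activity 0.200 (3260 px)
#>   margin     mean activity 0.600 (1832 px)

stack <- render_lambda_stack(ph, seed = 7)
stack
#> <lambda_stack> 1 z x 96x96 px x 22 bands, 462-572 nm (exc 458 nm), stage gastrula_5hpf

channels <- band_window_separation(stack)
margin <- roi_from_domain(ph, "margin")
fret_index(channels, margin)
#> <fret_index> 676.4 a.u. over 1832/1832 valid ROI px (floor 1.08, ratio_of_projections)

series <- render_bleach_series(ph, margin, iterations = 50, seed = 7)
run_abfret(series, list(margin = margin), embryo_id = "demo")
#>   embryo_id    roi         E E_percent  R_DA_nm excluded_reason pre_ratio pre_donor
#> 1      demo margin 0.2309903  23.09903 5.743203            none  1.296829  77.54384
```

Reading the output: the margin domain was generated with 60% active sensor,
i.e. a true effective efficiency of `0.05 + 0.6 × (0.35 − 0.05) = 0.23`; the
acceptor-photobleaching estimate recovers `E = 0.231` (23.1%) from the noisy
rendered frames, and the corresponding donor–acceptor distance is 5.74 nm.
The FRET index (676 a.u. over the 1832-pixel margin ROI) is the unitless
live-imaging counterpart: it rises with activity and is compared across
groups as a fold change (`fold_change()`, `compare_groups()`).

A full four-group dose-response experiment (wild type, D61G mutant, mutant
plus 0.25 and 1 µM MEK inhibitor) is one call each:

```r
cohort <- make_cohort(noonan_cohort_config(n_embryos = 8, seed = 1))
idx    <- cohort_fret_index(cohort)   # per-embryo FRET index at the margin
ab     <- cohort_abfret(cohort)       # per-embryo E, R_DA, pre-bleach metrics
morpho <- cohort_morphometry(cohort)  # axis ratio, body length
```

or, end to end with CSV outputs and a hashed manifest:

```r
run_pipeline(run_config(out_dir = "demo_run", seed = 1))
```

## Documentation

The methods vignette (`vignettes/fret-quantification.Rmd`) describes the
forward model, the estimators, every tunable threshold, what the phantoms do
and do not emulate, and the package's numerical conventions.
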