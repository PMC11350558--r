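# cytovar

Longitudinal murine immunophenotyping from low-volume flow cytometry:
declarative panel/gating definitions, automated hierarchical gating,
absolute-count normalization, repeated-measures variance decomposition,
challenge-study statistics, and a synthetic event-level generator with
known ground truth.

## What it does

Repeated blood sampling of the same mouse (50 µL per draw) makes
longitudinal immune monitoring possible, but the resulting data need a
reproducible pipeline: consistent gating across many samples, conversion
to absolute counts, and an honest account of how much of the observed
variability is biological (between animals), occasion-driven (within an
animal over time), or residual. `cytovar` implements that pipeline:

- **Panel model** — three built-in 14-marker panels (`myeloid`,
  `lymphoid`, `intracellular`) as versioned YAML configurations; the two
  peripheral surface panels jointly define 42 reported subsets. Custom
  panels are first-class (`cyto_panel()`, `gate_node()`,
  `write_panel_config()`), with eager validation that reports every
  violation at once.
- **Gating engine** — `asinh(x/150)` transform, per-sample data-driven
  thresholds (density-valley default, Gaussian-mixture option, tagged
  quantile fallback), top-down hierarchical gating
  (`gate_sample()`, `gate_study()`).
- **Quantification** — cells/µL of whole blood from gated counts,
  acquired volume and the tube dilution factor
  (50 µL blood + 500 µL diluent → ×11), on a `log10(x+1)` analysis
  scale (`absolute_count()`, `quantify_study()`).
- **Variance statistics** — two-factor (animal × timepoint) sums of
  squares from scratch, η² intra/inter shares, minimum detectable change
  `d·SD`, exact noncentral-*t* sample sizes (`anova_components()`,
  `eta_squared()`, `variance_tables()`, `required_n()`), plus shipped
  reference tables from healthy mice (`reference_variability()`).
- **Group analysis** — percent change from baseline, pooled/Welch *t*
  tests, randomized-block ANOVA, variance-ratio *F* test, humane-endpoint
  scoring (`compare_groups()`, `endpoint_reached()`).
- **Synthetic data** — event-level generator with per-animal and
  per-occasion log-normal abundance effects and full ground truth down to
  every gate node (`sim_config()`, `generate_study()`,
  `node_ground_truth()`).
- **IO & pipeline** — minimal FCS 3.0/3.1 reader/writer and tabular IO
  (`read_events()`), and a staged runner with a JSON run manifest so a
  single seed reproduces a whole analysis (`run_pipeline()`).

## Quick start

```r
library(cytovar)

# simulate a 5-animal x 5-timepoint study on the myeloid panel
cfg   <- sim_config(builtin_panel("myeloid"), seed = 11)
study <- generate_study(cfg)

# gate, quantify, decompose
q  <- quantify_study(gate_study(study), study)
vt <- variance_tables(q)
head(vt$eta)            # per-subset intra/inter eta-squared shares (%)
panel_mean_eta(vt$eta)  # panel averages

# study planning
required_n(cohens_d = 0.5, power = 0.80, alpha = 0.05)  # 64 per group
reference_variability()$mdc |> head()                    # shipped MDC table
```

## Installation and checks

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "cytovar",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The test suite covers each module with unit and property-based tests
against independent oracles (brute-force sums of squares, `stats::aov`,
`t.test`, `var.test`, `power.t.test`, closed-form variances of the
abundance model) and `tests/testthat/test-acceptance.R` holds one block
per acceptance criterion. `scripts/acceptance.R` recomputes the headline
quantities on freshly simulated data and writes them as JSON.

## Package layout

| Path | Contents |
| --- | --- |
| `R/panels.R` | panel/hierarchy model, YAML configs, validation |
| `R/simulate.R` | population specs, abundance model, event generator, ground truth |
| `R/gating.R` | transform, threshold estimation, hierarchical gating |
| `R/quantify.R` | dilution factor, absolute counts, log scale |
| `R/variance.R` | ANOVA components, η², MDC, power/sample size |
| `R/group.R` | percent change, t/F tests, block ANOVA, endpoint rule |
| `R/io.R` | FCS 3.1 and tabular IO, study export |
| `R/pipeline.R` | staged runner and run manifest |
| `inst/extdata/panels/` | the three built-in panel configurations |
| `inst/extdata/reference/` | healthy-mouse η² and MDC reference tables |
| `vignettes/cytovar-methods.Rmd` | methods walk-through |
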