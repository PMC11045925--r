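# deorphanr

Most solute carriers — the secondary transporters that move small molecules
across membranes without direct ATP hydrolysis — have no experimentally
assigned substrate. `deorphanr` implements the statistical side of a
deorphanization workflow that pairs an **exometabolome screen** in yeast
(which compounds does the cell take up or release?) with **heterologous
transporter assays in *Xenopus* oocytes** (which transporter moves which
compound, and how?) and **growth phenotyping of deletion strains** (does
losing the transporter matter *in vivo*?). Every analysis stage ships with a
seeded synthetic-data generator with known ground truth, so the pipeline's
sensitivity and error rates can be measured rather than assumed.

## What the package computes

* **Exometabolome screen** (`run_exo_screen`): for each compound in a
  control-vs-treated LC-MS response table, log2FC = log2(mean_treated /
  mean_control) and per-group CV (%). A compound is *consumed* when
  log2FC < −0.5, *secreted* when log2FC > +0.5, in both cases requiring
  max(CV_control, CV_treated) < 30%; otherwise *unchanged*.
* **Oocyte uptake calls** (`call_uptake`): pooled responses are normalized
  per oocyte, outliers removed by the interquartile method (fences
  Q1 − 1.5·IQR, Q3 + 1.5·IQR, recomputed to a fixpoint), and each
  transporter × compound condition is tested against the GFP-only control
  with a two-sided Student's *t*-test. Significant positive log2FC ⇒
  *import*; significant negative log2FC ⇒ *export*, but only when the
  control shows endogenous background uptake (otherwise the negative shift
  is *indeterminate*).
* **Transport mode** (`call_transport_mode`): imported compounds are
  classified *concentrative* when the intracellular concentration
  significantly exceeds the medium (one-sided *t*-test against the constant
  2 mM medium, log2FC > 0), else *equilibrative*; calls are reported raw and
  after subtracting the GFP control's endogenous background.
* **Growth phenotypes** (`fit_growth_metrics`, `estimate_lc50`,
  `compare_strains`): μ_max from sliding-window log-linear fits of ln(OD)
  (window slopes extrapolated to OD → 0, which for a logistic curve equals
  the specific growth rate), Max OD from a median-smoothed curve, LC50 from
  a four-parameter logistic dose-response fit (with monotone interpolation
  as fallback), and per-metric Student's *t* comparisons of deletion strains
  to the reference.
* **Pipeline** (`run_pipeline`, `exec/deorphan`): YAML-configured stage
  sequencing with schema validation, tidy CSV/JSON intermediates, and a
  seeded, reproducible combined report.

## Worked example

Simulate a small oocyte assay for 2-benzoxazolol (BXZ) with one
concentrative importer, one exporter and one inactive transporter, then call
activity and mode:

```r
library(deorphanr)

design <- dplyr::bind_rows(
  transporter_truth("Ecm3",  "BXZ", "importer", accumulation_ratio_A = 4, rate_k = 2),
  transporter_truth("Thi74", "BXZ", "exporter", exporter_factor_beta = 0.25),
  transporter_truth("Sly41", "BXZ", "none")
)
sim <- simulate_oocyte_assay(design, oocyte_sim_params(
  background_ratio = 0.25, noise_cv = 0.2, seed = 7
))
up <- call_uptake(sim$measurements)
up$calls[, c("transporter", "log2fc_vs_control", "p_value", "direction",
             "significance_stars")]
#>   transporter log2fc_vs_control p_value direction significance_stars
#> 1        Ecm3             3.663 0.01630    import                  *
#> 2       Thi74            -2.749 0.00303    export                 **
#> 3       Sly41            -0.451 0.12328      none                 ns

modes <- call_transport_mode(up)
modes[modes$direction == "import",
      c("transporter", "c_in_mM", "log2fc_vs_medium", "mode")]
#>   transporter c_in_mM log2fc_vs_medium          mode
#> 1        Ecm3    8.96             2.16 concentrative
```

Ecm3 accumulates BXZ to ~9 mM against a 2 mM medium (log2FC = 2.16 versus
the medium), a concentrative importer; Thi74 depletes the endogenous
background (log2FC = −2.7 versus the control), an exporter — which is only
callable because the GFP control itself shows background uptake.

## Scope

The package analyzes response tables; peak picking, compound identification,
UMAP visualization, phylogenetics and everything upstream of a tidy table
are out of scope. See `vignettes/transporter-deorphanization.Rmd` for the
models, assumptions and design decisions.
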