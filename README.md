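# isoflux

Stable-isotope tracer fluxes and carbon budgets for closed-chamber feeding
experiments with benthic suspension feeders.

## What it is for

Cold-water reefs host suspension feeders — bivalves, high- and
low-microbial-abundance sponges, ophiuroids — whose role in the reef carbon
cycle can be measured by feeding them a ^13^C-enriched substrate (dissolved
organic matter, bacteria or diatoms) and tracking where the labelled carbon
goes: tissue growth, respiration, particulate waste (POC, including bivalve
(pseudo-)feces) or dissolved organics (DOC). `isoflux` implements the full
analysis chain for such experiments, for ecologists running or re-analysing
pulse-chase incubations.

The core currency is the ^13^C **atom fraction**
F(δ) = ((δ/1000 + 1)·R) / (1 + (δ/1000 + 1)·R), with R = 0.0111802 (VPDB).
Excess ^13^C in a pool of C µmol is E = (F_sample − F_background)·C, and
substrate-derived **tracer carbon** is E / F_substrate. Closed-chamber net
fluxes are (c_end − c_start)·V/Δt (negative = net uptake), respiration is
the OLS slope of the O₂ log times a respiratory quotient (default 1),
animal rates are corrected against parallel no-organism controls and
standardized to tissue organic carbon: µmol C (mol OC)⁻¹ h⁻¹.

The package contains, module by module:

* **Isotope core** — δ¹³C ↔ atom fraction conversions, excess ¹³C, tracer
  carbon (`delta_to_atom_fraction()`, `excess_carbon13()`,
  `tracer_carbon()`).
* **Specimen tissue** — sponge OC-from-volume allometry, tissue
  incorporation rates, percent-of-provided with depletion warning.
* **Incubation fluxes** — net release rates, refill-dilution correction,
  O₂ regression respiration, tracer release, control correction, biomass
  standardization.
* **Budget** — per-animal total-C/tracer-C budget rows, tissue-POC
  turnover, areal scalings, food-chain transfer efficiency.
* **Nonparametric statistics** — Wilcoxon rank sum with exact small-sample
  enumeration, Kruskal-Wallis, Dunn post-hoc with Holm adjustment.
* **Synthetic experiments** — `simulate_experiment()` and
  `simulate_food_chain()` generate complete campaigns from known ground
  truth, so every stage is verifiable by parameter recovery.
* **I/O and pipeline** — validated CSV schemas, YAML config,
  `run_pipeline()`, provenance headers on every output file.

## Worked example

```r
library(isoflux)

cfg <- sim_config(seed = 1, n_animals_per_group = 3)
sim <- simulate_experiment(cfg)   # specimens, batches, incubations, O2 logs
out <- run_pipeline(sim)

head(out$budget[, c("specimen_id", "respiration_total", "poc_total",
                    "doc_total", "total_turnover", "frac_incorporation")])
#>     specimen_id respiration_total poc_total doc_total total_turnover frac_incorporation
#> 1 bivalve_dom_1          153.7936  45.29493  63.49894       262.5875          0.8990917
#> 2 bivalve_dom_2          152.6862  44.99010  59.47133       257.1477          0.8994108
#> 3 bivalve_dom_3          152.2178  44.53463  58.31370       255.0661          0.8981934

max(abs(recovery_table(out$budget, sim$ground_truth)$rel_error))
#> [1] 0.06458264
```

Each budget row is one animal: total respiration, POC and DOC release sum
to its total-C turnover (all µmol C (mol OC)⁻¹ h⁻¹), and
`frac_incorporation` says which share of the utilized substrate carbon went
into tissue (here ~0.90, with the rest respired or released as POC). The
recovery line compares every recovered rate with the generator's ground
truth — at 3 animals per condition and default measurement noise the worst
single condition mean deviates ~6% from truth (averaging across conditions
or using more chambers tightens this well below 5%), and with noise set to
zero it drops to ~10⁻¹⁴.

The numbered scripts under `analysis/` run the same steps as a workflow
(simulate → fluxes → budget → statistics → food chain) and write their
tables under `results/`.

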