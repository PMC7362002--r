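# netquant

Quantification of neutrophil extracellular traps (NETs) in three-channel
epifluorescence micrographs, with the companion assay analyses used to
score NETosis on biomaterial surfaces.

## What it does, and for whom

When neutrophils encounter a surface they cannot phagocytose — an
electrospun tissue-engineering template, for instance — they can undergo
NETosis, ejecting decondensed chromatin laced with granule proteins.
Laboratories scoring this response image fields stained with DAPI (blue,
intact nuclei), sytox orange (red, extracellular and permeable-cell DNA)
and an anti-neutrophil-elastase immunostain (green), then reduce each field
to a handful of numbers. `netquant` implements that reduction as a tested,
configurable pipeline for R:

* **Percent area NETs** — `100 · |red ∧ ¬blue| / |image|`: the fraction of
  pixels carrying extracellular-DNA signal without intact-nucleus signal.
* **Per-cell census** — discrete cells identified on the blue∨red mask
  union by size (equivalent diameter 4–30 µm) and circularity
  (`4πA/P² ≥ 0.5`), then classified: *NETosing* if blue, red and green
  colocalize over the footprint; otherwise *viable* when the blue/red
  mean-intensity ratio is ≥ 1:3 and *necrotic* when below.
* **Release quantification** — 340 nm absorbance standard curve
  (least-squares), inverse prediction of honey % v/v in releasates, and
  cumulative release over the 14-point, 21-day sampling schedule.
* **Percent NETosis response** — MPO concentrations normalized within
  experiment to the 100 nM PMA positive control, plus the heparin
  background check that validates MPO as a NET readout.
* **Gated statistics** — Shapiro–Wilk-and-replicate-gated choice between
  one-way ANOVA with Holm–Šidák post hoc and Kruskal–Wallis with
  Mann–Whitney post hoc.
* **Synthetic ground truth** — seeded generators for micrographs (viable /
  NETosing / necrotic cells, NET strands, noise) and assay tables, so every
  stage is verifiable against known truth without any donor data.

The methods vignette (`vignettes/netosis-quantification.Rmd`) documents the
model, all defaults and the design decisions.

## Worked example

Generate a synthetic 20× field (1024×1360 px at 0.5 µm/px) with known
content — 5 viable, 3 NETosing, 2 necrotic cells and 2 NET strands — and
quantify it:

```r
library(netquant)
spec <- field_spec(n_viable = 5, n_netosing = 3, n_necrotic = 2,
                   n_net_strands = 2, seed = 42)
sim <- generate_field(spec)
q <- quantify_field(sim$field)
print(q)
#> NET quantification [synthetic(seed=42)]
#>   percent area NETs: 0.38%
#>   cells: 10 (viable 5, NETosing 3, necrotic 2)
#>   thresholds: blue 48.5, red 50.97, green 48.17
true_percent_area_nets(sim$truth)
#> [1] 0.345
```

All ten cells are recovered with their true classes; the measured percent
area NETs (0.38%) sits within a few hundredths of a point of the
ground-truth NET-pixel percentage (0.345%). The per-cell table shows the
quantities behind each call — note the necrotic cell's ratio near 0.1, the
viable cells near 3, and the NETosing cell flagged by green colocalization
despite its red-dominant ratio:

```r
head(q$cells[, c("area_um2", "circularity", "blue_red_ratio",
                 "green_positive", "cell_class")], 4)
#>   area_um2 circularity blue_red_ratio green_positive cell_class
#> 1    59.25   0.9892074      0.1130670          FALSE   necrotic
#> 2    63.25   0.9830216      2.9399283          FALSE     viable
#> 3   285.50   0.8695324      0.3155068           TRUE   netosing
#> 4    74.25   0.9804316      2.9632360          FALSE     viable
```

A release standard curve and a gated group comparison:

```r
cal <- fit_standard_curve(c(0, 0.625, 1.25, 2.5, 5, 10),
                          c(0.041, 0.072, 0.101, 0.165, 0.29, 0.538))
print(cal)
#> Standard curve (340 nm, n = 6): A = 0.049777 * conc + 0.0404286, r^2 = 0.99998
absorbance_to_concentration(cal, 0.2)
#> [1] 3.205729

set.seed(1)
cmp <- compare_groups(c(rnorm(6, 12, 2), rnorm(6, 2, 2)),
                      rep(c("SD blank", "SD 0.1% honey"), each = 6))
print(cmp)
#> Group comparison (parametric branch, alpha = 0.05)
#>   procedure: Shapiro-Wilk gate -> one-way ANOVA omnibus -> all-pairs pooled-SD t tests, Holm-Sidak adjusted
#>   omnibus one-way ANOVA: statistic 94.38, p = 2.071e-06
#>   ...
```

Both groups pass normality with six replicates each, so the parametric
branch runs and flags the pair as significant.

Batch workflows (`run_simulate()`, `run_quantify()`, `run_release()`,
`run_mpo()`, `run_compare()`) consume CSV manifests and YAML configs and
write CSV reports plus a JSON run log; a thin command-line wrapper ships in
`inst/cli/netquant.R`.

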