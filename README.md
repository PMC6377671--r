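# meminsert

Trajectory- and structure-level analysis of the early stage of small-molecule
insertion into phospholipid bilayers, built around the four anthracycline
chemotherapeutics (doxorubicin DOX, epirubicin EPI, idarubicin IDA,
daunorubicin DAU) in POPC and DMPC membranes. It is aimed at computational
chemists and modellers who post-process membrane-permeation trajectories and
want the insertion-rate, orientation and localisation metrics in one tested,
scriptable package — without re-running any molecular dynamics.

## What it computes

**Insertion kinetics.** The insertion association constant

```
K_in = A · L_z / ⟨W⟩     [M⁻¹ s⁻¹]
```

with `A` the lateral membrane area (Å²), `L_z` the water-layer thickness
(Å) and `⟨W⟩` the mean first passage time (ns) of the solute to the membrane
surface (the proximal phosphate plane, with a configurable persistence
criterion to reject grazing contacts). Comparison operations give percent
differences between analogues, rank orders, and per-analogue ratios between
lipids.

**Orientation.** Per-frame tilt angles θ = arccos(v̂·ẑ) of named molecular
vectors against the bilayer normal, classified horizontal (within 10° of
0°/180°), perpendicular (within 10° of 90°) or unclassified, and summarised
into H / P / H/P preference labels from the insertion time onward.

**Localisation.** Heavy-atom contact counts between the solute and the lipid
component bins (choline head, phosphate, glycerol/ester, tail) at a 4 Å
minimum-image cutoff, reported as occurrence percentages, with a first-60-ns
control window.

**Molecular properties.** Point-charge dipole moments (1 e·Å = 4.80321 D),
intramolecular H-bond distances, the rigidity metric (number of IR modes
with ε > 200 M⁻¹cm⁻¹ in 0–600 cm⁻¹), small-integer absorbance ratios, and
the Spearman correlation between rigidity and insertion order.

**Synthetic generator.** A drift–diffusion trajectory generator emulating the
study geometry (128-lipid bilayer, solute started 29 Å above the bilayer
center, 12 × 100 ns design) with exactly known ground truth, so the whole
pipeline is validated by parameter recovery. See the methods vignette
(`vignettes/membrane-insertion-analysis.Rmd`) for the model and every
default.

## Worked example

Twelve synthetic repeats of a fast inserter in POPC, from trajectory to
association constant:

```r
library(meminsert)

popc <- build_bilayer_model("POPC")
popc
#> <bilayer_model> POPC
#>   lipids:      128 (64 per leaflet)
#>   box:          64.50 x 64.50 x 65.62 A
#>   phosphate planes: +/- 18.50 A
#>   hydration:    31.0 waters/lipid, 0.10 M salt

kp <- kinetic_params(v = 3, D = 2, n_replicates = 12, max_time = 40, seed = 101)
fp <- purrr::map_dfr(1:12, function(r) {
  tr <- simulate_insertion_trajectory(popc, kp, seed = 101 + r)
  detect_insertion(tr, replicate_id = paste0("rep", r))
})
head(fp, 3)
#>   replicate_id inserted     W censored
#> 1 rep1         TRUE       7.8 FALSE
#> 2 rep2         TRUE       3.8 FALSE
#> 3 rep3         TRUE       3.1 FALSE

est <- kin_estimate(fp, A = lateral_area(popc),
                    L_z = water_layer_thickness(popc),
                    analogue = "DOX", lipid = "POPC")
est
#> <kin_estimate> DOX in POPC: K_in = 8.05e+09 M^-1 s^-1 (<W> = 4.45 ns, n = 12 + 0 censored)
```

Each replicate's `W` is the first time the solute stays below the phosphate
plane for 0.5 ns; the twelve times average to ⟨W⟩ = 4.45 ns, and with
A = 4160 Å² and a one-sided water slab of 14.3 Å the association constant is
8.05 × 10⁹ M⁻¹ s⁻¹ — the same order of magnitude as measured-scale insertion
constants, as the unit conversion should give.

The comparison operations work directly on published association-constant
tables, which ship as a data function:

```r
kin <- published_kin_constants()
rank_analogues(kin[kin$lipid == "POPC", ])
#> [1] "DOX" "DAU" "IDA" "EPI"
percent_slower(3.71e9, 2.75e9)   # EPI vs DOX in POPC
#> [1] 25.87601
```

A full study-shaped run (analogues × lipids × replicates, with orientation
and contact analyses and rendered CSV/Markdown tables):

```r
report <- run_study(study_config(seed = 1))
render_tables(report, "study_out")
```

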