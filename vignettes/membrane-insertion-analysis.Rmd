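---
title: "Membrane insertion kinetics, orientation and localisation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane insertion kinetics, orientation and localisation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meminsert)
```

`meminsert` analyses the early stage of small-molecule insertion into a
phospholipid bilayer: how fast the molecule reaches the membrane surface, what
pose it adopts once inside, which lipid components it sits against, and which
structural properties of the molecule itself (rigidity, dipole moment,
intramolecular hydrogen bonding) track its insertion propensity. The package
was built around the four anthracycline chemotherapeutics (doxorubicin DOX,
epirubicin EPI, idarubicin IDA, daunorubicin DAU) in POPC and DMPC bilayers,
but every operation is generic over labels and geometry.

## The insertion-rate model

The central quantity is the insertion association constant

$$K_{in} = \frac{A\,L_z}{\langle W\rangle},$$

where $A$ is the lateral membrane area (Å²), $L_z$ the thickness of the water
layer the solute diffuses through (Å), and $\langle W\rangle$ the mean first
passage time to the membrane surface (ns). `compute_kin()` converts the
volume $A\,L_z$ from Å³ to M⁻¹ with $N_A/10^{27} = 6.02214\times10^{-4}$ and
$\langle W\rangle$ from ns to s, so $K_{in}$ comes out in M⁻¹ s⁻¹:

```{r}
compute_kin(A = 4160, L_z = 30, W_mean = 20)
```

Three operational definitions are deliberately configurable because the
quantity itself does not pin them down:

* **Surface.** The first-passage target is the proximal-leaflet mean
  phosphate plane from the bilayer model (`detect_insertion(surface_z =)`
  overrides it).
* **Persistence.** A replicate counts as inserted at the earliest time $t$
  such that the solute stays at or below the surface throughout
  $[t, t+\textit{persistence}]$; the default 0.5 ns rejects single-frame
  grazing contacts. `persistence = 0` gives the bare first crossing.
* **$L_z$.** `water_layer_thickness()` returns the one-sided slab by default
  (the solute occupies one side of a symmetric bilayer); `sides = "both"`
  gives the full water thickness for users who read the definition the other
  way.

Censoring: replicates that never satisfy the persistence criterion are
censored at the trajectory end. `mean_first_passage()` averages the inserted
replicates only (policy `"drop"`, warning above 25% censoring) or refuses
censored input (policy `"error"`); dropping censored repeats biases
$\langle W\rangle$ low when censoring is heavy, which is why the censored
count is always carried in the output.

## The synthetic generator

No MD engine is involved. The generator reproduces the *shape* of the study
data — a 128-lipid bilayer (64 per leaflet), the solute started 29 Å above
the bilayer center, repeats of a fixed length — with a drift–diffusion model
whose ground truth is known exactly, so every analysis stage is testable by
parameter recovery.

**Bilayer.** `build_bilayer_model()` stores the lateral area
($n/2 \times$ area per lipid: POPC 65 Å², DMPC 60 Å²), phosphate planes at
± thickness/2 (POPC 37 Å, DMPC 35 Å) and a water slab derived from the
hydration level (POPC 31 waters/lipid, DMPC 26.6) at 30 Å³ per water — the
standard liquid-water volume, needed because hydration is specified per
lipid. Salt content (0.1 M KCl; 9/9 ion pairs for POPC, 7/7 for DMPC) is
stored as metadata only: no electrostatics are modelled, and the convention
that produced those ion counts from the molarity is not reconstructable from
the hydration numbers, so the package does not attempt to re-derive them.

**Kinetics.** The solute's depth follows an Euler–Maruyama drift–diffusion
path (drift $v$ toward the membrane, diffusion $D$), reflected at the far
water boundary and switching to an Ornstein–Uhlenbeck relaxation toward a
settle depth once it first crosses the phosphate plane. The matching
closed-form law is the inverse Gaussian with mean $d/v$ and shape $d^2/2D$
(`sample_first_passage_times()` draws from it directly; the Michael–Schucany–
Haas transform is implemented in-package because no installed package
provides an inverse-Gaussian sampler). The drift-free limit $v=0$ is the Lévy
first-passage law, and $D=0$ the deterministic drift time — both handled as
exact special cases.

**Lipids.** Lipid atoms are pseudo-atoms drawn from per-component Gaussian
z-profiles (choline, phosphate, glycerol/ester, tail), with per-lipid counts
mirroring heavy-atom proportions (5/4/6/14). The lipids are a mean-field
density, not particles: after the first frame each frame redraws the
pseudo-atom positions from the component density (uniform laterally,
Gaussian in z). This stands in for lipid conformational fluctuation and
lateral diffusion, which are fast on the 100 ns scale, and it is what makes
contact statistics converge to the component densities rather than to one
frozen configuration. It also means the generator cannot exhibit lipid-lipid
correlations, headgroup bridging, or solute-induced membrane deformation —
passing tests say nothing about those.

**Orientation.** Each tracked vector's tilt is drawn around a target angle
with concentration $\kappa$ (Gaussian noise of sd $1/\sqrt{\kappa}$ radians,
reflected into [0°, 180°]; $\kappa = 0$ isotropic, $\kappa = \infty$
locked), optionally alternating between two targets with a telegraph process
(`switching_rate` per ns) — the mechanism used to emulate a molecule that
rotates between horizontal and perpendicular poses.

**Seeds.** One base seed per study; replicate $r$ of cell $c$ uses
`seed + 10000 c + r`, giving independent, reproducible streams. The per-frame
lipid resampling derives its stream from the trajectory seed and frame index
and restores the caller's RNG state.

## Orientation classification

`angle_to_normal()` is the arccosine of the normalized z-component of the
head-minus-tail centroid vector. The vectors themselves (for anthracyclines:
the daunosamine sugar arm, the phenyl ring D axis, the tetracyclic ring A
axis) are user-configured atom sets — the package ships no canonical atom
selections because the defining atoms are a modelling choice, not data.

Windows: horizontal within ±10° of 0° or 180°, perpendicular within ±10° of
90°. The horizontal window is the stated convention; the perpendicular
half-width is mirrored at 10° since no number accompanies it. Frames outside
both windows (120 of 180 degrees) are "unclassified" and excluded from the
dominance ratio. A cell is labelled H when the H share of classified frames
is at least 0.7, P when at most 0.3, and H/P between — the threshold that
separates a firm preference from "rotates freely" is a design choice; 0.7
demands a clear 2:1 majority without requiring near-unanimity. Analysis
starts at the detected insertion time (`from_insertion`), matching the
question "what pose does the molecule hold once inside?".

## Localisation histograms

A contact is a (solute heavy atom, lipid heavy atom) pair within 4.0 Å
minimum-image distance — a conventional heavy-atom contact cutoff; the
criterion used for the original histograms is not stated, so the cutoff is a
first-class parameter. Periodicity applies laterally (x, y) only: the normal
is the analysis axis and the synthetic boxes are not periodic in z.
Occurrence percentages are contact-count-weighted
(`weighting = "contacts"`); a frame-presence mode is available behind the
`weighting = "frames"` flag. `windowed_comparison()` repeats the histogram
over the first 60 ns as a control that late-trajectory behaviour (e.g. a
slow descent into the tails) is not an artefact of differing insertion
times. The shipped component maps bin the generator's pseudo-atoms; maps for
real topologies are user-supplied YAML/JSON and the shipped ones are
documented approximations.

## Molecular properties

* **Dipole:** $\mu = \sum_i q_i r_i$ at 1 e·Å = 4.80321 D, from PDB
  structures with partial charges joined from a sidecar CSV. For net-charged
  species the value is origin-dependent; the package uses the center of
  nominal mass and warns.
* **H-bond distance:** plain Euclidean distance between a named donor
  hydrogen and acceptor heavy atom.
* **Rigidity:** the count of vibrational modes with absorbance
  $\varepsilon > 200$ M⁻¹cm⁻¹ (strictly greater, a literal reading) in the
  closed window [0, 600] cm⁻¹. Fewer strong low-frequency modes mean a
  stiffer molecule.
* **Integer ratios:** absorbances divided by their minimum, then scaled by
  the integer $k \in [1, 12]$ minimizing total rounding error. The cap at 12
  reproduces both reported ratio styles (one with minimum entry 2, one with
  minimum 1) deterministically; ties take the smallest $k$.
* **Rank correlation:** Spearman between mode counts and insertion-slowness
  rank, because +1 under Spearman is exactly "same ordering", which is the
  claim being scored; Kendall is available behind `method = "kendall"`.

## Study orchestration and problem sizes

`run_study()` loops analogues × lipids × replicates, logs one line per cell,
confines failures to their cell, and is byte-deterministic for a fixed seed.
The default desk profile is 3 repeats × 20 ns with 0.1 ns frames —
`paper_scale = TRUE` restores the full 12 × 100 ns design. The default
analogue specs order the drift speeds DOX > DAU > IDA > EPI (3.6 to 1.8
Å/ns, D = 2 Å²/ns); the separations are deliberately wider than the ~10–25%
spread in the published constants so that rank recovery at tens of replicates
is a statistically meaningful test of the pipeline rather than a coin flip.
DMPC carries a drift factor of 0.6, encoding its more ordered, saturated
tails; combined with DMPC's smaller $A\,L_z$ this reproduces association
constants about half the POPC values. The test suite's recovery checks run
100 replicates of 40 ns; the acceptance script uses the same sizes.

```{r, eval = FALSE}
cfg <- study_config(seed = 1)
report <- run_study(cfg)
render_tables(report, "study_out")
autoplot(report)
```

## Numerical choices and degenerate inputs

* Insertion detection uses a cumulative-sum window scan; persistence windows
  are rounded up to whole frames.
* The histogram bins of `angle_histogram()` are half-open except the last,
  so 180° is counted once; `bin_width` must divide 180.
* Zero hydration collapses the water slab (box equals the bilayer); default
  headgroup profile means are clamped inside the box in that degenerate case.
* `contact_histogram()` on a zero-contact window returns all-zero
  percentages with an `empty` attribute rather than dividing by zero.
* Zero-length orientation vectors, empty trajectories, solutes starting
  below the surface, overlapping angle windows, inverted spectral intervals
  and duplicate analogue labels all raise immediate errors.
* Ranking ties break lexicographically so reports are deterministic.

## Limitations

The generator validates the *analysis* pipeline, not membrane biophysics: no
force field, no explicit water, no lipid-lipid structure, no energetics. The
published association constants, dipole moments and mode counts derive from
hundred-nanosecond MD and DFT frequency calculations that are not
recomputable here; the package treats them as printed inputs for its
comparison operations and reproduces their *arithmetic* (percent
differences, rank orders, lipid ratios, mode counting and integer ratios)
exactly. Real-topology component maps and orientation vector definitions
must be supplied by the user.
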