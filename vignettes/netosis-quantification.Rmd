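---
title: "Quantifying NETosis from three-channel fluorescence micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NETosis from three-channel fluorescence micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and its readouts

Neutrophils seeded on a biomaterial surface can undergo NETosis, ejecting
decondensed chromatin webbed with granule proteins as neutrophil
extracellular traps (NETs). The staining scheme this package analyses uses
three channels:

* **blue** — DAPI, membrane-permeant, marks intact nuclei;
* **red** — sytox orange, membrane-impermeant, marks extracellular DNA and
  the nuclei of permeabilized (necrotic) cells;
* **green** — immunostained neutrophil elastase, a granule protease that
  decorates NET chromatin.

Two image readouts follow. *Percent area NETs* is the fraction of image
pixels positive in the red mask but not the blue mask, times 100: DNA that
is stained red but carries no intact-nucleus signal is extracellular. The
per-cell readout identifies discrete cells by size and circularity and
classifies each as **viable** (blue/red mean-intensity ratio of 1:3 or
greater), **NETosing** (colocalization of blue, red and green), or
**necrotic** (blue/red ratio below 1:3).

Around the imaging core sit two tabular analyses — honey-release
quantification against a 340 nm absorbance standard curve, and
myeloperoxidase (MPO) concentrations normalized to a 100 nM PMA positive
control as *percent NETosis response* — and a gated group-comparison
procedure. Seeded generators produce synthetic micrographs and assay tables
with exact ground truth, so the whole pipeline is testable without any
donor-derived data.

## Image model

A field (`multichannel_field()`) keeps the three planes on their native
camera scale; 8-bit and 16-bit inputs are not rescaled to $[0, 1]$. The
classification rule is a ratio of mean intensities, so keeping the native
scale makes the result independent of bit depth; tests assert that an 8-bit
and a 16-bit rendering of one scene load proportionally. The default pixel
size is 0.5 µm/px, consistent with a 20× field; it is overridable
everywhere. Coordinates are 0-based with `x` along columns; areas are
reported in µm² via `pixel_size_um^2`.

## Preprocessing

**Background subtraction.** The user supplies a rectangular region of
interest containing no NETs; each channel subtracts the median intensity of
that ROI (clamped below at zero). The median rather than the mean keeps the
estimate robust to stray dim debris inside a nominally empty ROI. One ROI
is shared by all channels, and subtraction is applied per channel. When no
ROI is given, `auto_roi()` proposes the lowest-mean 64×64 tile of a 4×4
grid partition of the channel sum — the darkest tile is the best automatic
proxy for a NET-free region. ROIs smaller than 8×8 are rejected so the
median rests on at least 64 pixels.

**Binarization.** The fixed path (`method = "fixed"`) applies a strict
`intensity > threshold` rule — strict so that background-valued pixels
exactly at the threshold stay off, a convention the exactness tests rely
on. The automatic path selects the threshold that maximizes between-class
variance over a 256-bin histogram (Otsu's criterion), wrapped in a
separation guard: the foreground class mean must exceed the plane median
by more than five robust standard deviations (MAD). Plain
variance-maximization fails on fluorescence fields whose stained structures
occupy a small fraction of the area — with foreground fraction $w$ and
contrast $c$ (object peak over noise SD), the object split scores about
$w\,c^2$ against roughly $0.64$ for splitting the noise mode itself, so at
$c = 10$ any field below ~0.6% foreground gets a threshold inside the
noise. When the guard rejects a split, the criterion is re-applied to the
pixels above the rejected threshold, walking up the histogram until a
separated split appears; if none does (constant planes, pure noise), an
empty mask is returned with a warning. On genuinely bimodal planes the
first split passes and the result is identical to plain Otsu, which is what
the exhaustive-search oracle test checks. Inside `quantify_field()` the
automatic threshold is selected on the *raw* plane and then carried onto
the background-subtracted scale: subtraction is monotone, so the mask is
identical, while the raw histogram keeps the intact noise distribution that
the guard's median/MAD statistics need (the zero-clamp after subtraction
piles up a spike at zero that poisons them). Every mask records the
threshold that produced it, and all thresholds are echoed in downstream
reports.

## Discrete cells: detection and classification

Candidate cells are 8-connected components of the **union** of the blue and
red masks: viable cells can be red-negative and necrotic cells nearly
blue-negative, so neither channel alone suffices. Components are labelled
deterministically by their top-most, then left-most pixel. A component is
kept if

* its equivalent-circle diameter $2\sqrt{A/\pi}$ lies in 4–30 µm
  (defaults bracketing the ~8.5 µm neutrophil), and
* its circularity $4\pi A / P^2$ is at least 0.5.

The perimeter $P$ is estimated by a Moore-neighbour boundary walk on the
8-connected contour, with straight steps counting 1 pixel and diagonal
steps $\sqrt 2$; the walk's (pixel, backtrack) state is iterated until it
repeats, which closes exactly one boundary cycle even when the contour
passes its starting pixel twice. Discretization can push near-circular
regions slightly above 1 and values are reported unclamped; a single pixel
is assigned circularity 1 by convention. Diffuse NET strands form
elongated, ragged components and fail the circularity filter, which is
precisely how the method excludes them from the cell census.

Per-cell measurements are means of the background-subtracted intensities
over the footprint. The blue/red ratio uses intensities, not pixel counts —
count ratios collapse under any single-channel threshold, and intensity is
what the stains report. A cell with zero mean red carries the `inf`
sentinel and classifies as viable. Colocalization is operationalized as at
least half of the footprint lying inside the green mask together with
non-zero blue and red means; NETosing takes precedence over the ratio rule,
since a decondensing NETosing cell is typically red-dominant and would
otherwise be called necrotic. The viable ("1:3 or greater") and necrotic
("1:3 or less") wordings both include equality, so the boundary is resolved
by an explicit `tie_rule` defaulting to viable. All of these knobs live in
`detection_params()` and are echoed into every run log.

*Percent area NETs* uses the full image area as denominator, matching how
per-field percentages are reported for whole 20× frames.

## Release and MPO analyses

`fit_standard_curve()` is an ordinary least-squares line through a serial
dilution read at 340 nm (at least three distinct concentrations);
`absorbance_to_concentration()` inverts it, clamping negative inverse
predictions to zero with a warning — concentrations are physical
quantities. Since the incubation medium is fully replaced at each of the 14
sampling timepoints (15 min to 21 days, `release_schedule_h()`), interval
concentrations are independent measurements and cumulative release is their
running sum per template; both interval and cumulative series are reported.

`percent_netosis_response()` is $100 \times \mathrm{MPO} /
\mathrm{MPO}_{\mathrm{PMA}}$, normalized within experiment against the
heparin-treated 100 nM PMA positive control of the same run (panels carry
an experiment key to enforce the pairing). `heparin_background_check()`
validates the MPO readout: heparin dissociates NET-bound MPO, so replicates
run without heparin report only free MPO; the per-condition ratio of
no-heparin to heparin means must fall below a cutoff (default 0.2) for the
background to be negligible.

## Group statistics

`compare_groups()` reproduces the gated decision procedure: each group is
Shapiro–Wilk tested, and the parametric branch — one-way ANOVA followed by
all-pairs pooled-SD $t$ comparisons under Holm–Šidák step-down adjustment
($\tilde p_{(i)} = 1 - (1 - p_{(i)})^{m - i + 1}$, monotonized) — runs only
when every group is normal at $\alpha$ *and* has at least six replicates.
Otherwise the rank branch runs: Kruskal–Wallis omnibus with all-pairs
Mann–Whitney comparisons. Three open points were settled as follows:
the two-way layout (fiber size × honey level) is reduced to one-way
comparisons within a template type, matching how significance is annotated
per template and timepoint; Mann–Whitney post hoc p-values are reported
unadjusted, because no adjustment is named for the rank branch, and the
report flags this in its procedure string; and the normality gate applies
per group rather than to pooled residuals ("each data set"). Groups too
small to test (n < 3) force the rank branch with a warning, and fully
constant data yield a degenerate report instead of an error.

## The synthetic-data generator

`generate_field()` renders what the stain semantics imply, not what a
microscope produces:

* viable cells — disks (diameter 6–10 µm) with blue:red equal to
  `viable_ratio` (default 3);
* necrotic cells — disks with blue:red equal to `necrotic_ratio`
  (default 0.1);
* NETosing cells — boundary-perturbed blobs (diameter 10–20 µm) with a
  blue+red+green core and a red+green corona spilling beyond the blue core
  with a mild radial falloff, emulating chromatin decondensation;
* NET strands — persistent-random-walk ribbons elevated in red and green
  only.

Objects are placed by rejection sampling with a clearance margin so
components never merge (an error after $10^4$ failures marks an infeasible
spec); channels are summed with a flat background (default 100), additive
Gaussian noise clipped at zero (default SD 10), and object peaks at
`contrast` times the noise SD (default 10; a noiseless spec uses unit noise
scale so objects remain visible). The default frame is 1024×1360 px at
0.5 µm/px, approximating one 20× field. The ground truth records every
object and the exact NET-pixel mask (strands plus coronae), which is the
reference for percent-area error and per-cell accuracy. Every generator is
a pure function of its spec and seed — the RNG state is isolated, and
identical seeds give bit-identical output.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: Poisson–Gaussian camera statistics,
point-spread blur, illumination gradients, overlapping or touching cells,
partially decondensed intermediate morphologies, DAPI-positive NET
remnants, and donor-to-donor variability. Recovery results on synthetic
panels certify the scoring logic, not robustness to those artefacts.

The assay generators mirror the tabular layouts: `generate_release_data()`
adds Gaussian absorbance noise to a true line over the 14-point schedule;
`generate_mpo_panel()` applies lognormal measurement noise at a given CV,
with the no-heparin arm reporting the free fraction
$1 - \mathrm{net\_bound\_fraction}$ of each true concentration.

## Numerical conventions and test scales

Strict `>` in all thresholding; 256 histogram bins over the plane's range
with the first-maximum tie-break; single-pixel circularity 1; `inf` ratio
sentinel serialized literally in CSV; negative inverse predictions and
interval concentrations clamped to zero with warnings; class percentages
all zero for an empty field. The test suite exercises the full-frame
defaults where the claim depends on them (the 20-field recovery panel runs
at 1024×1360) and smaller 256–512 px frames where only the logic is under
test; simulation-based checks use 200–1000 replicates. These sizes are the
package's chosen validation scales and are stated in the tests themselves.

## Known limitations

The pipeline scores 2-D projections of 3-D NET structures; strand networks
are excluded from the cell census but not instance-segmented; cells
touching in the masks merge into one component and may fail the size or
circularity filters; the original study's exact size/circularity cutoffs
and threshold rule were not published, so the defaults here are anchored to
the stated cell size and fully exposed in configuration rather than
asserted as the original values.
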