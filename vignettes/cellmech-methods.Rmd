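---
title: "Methods behind cellmech: track analytics, Hertz fits, gel rheology and ligand densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind cellmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmech)
library(dplyr)
```

cellmech packages the quantitative stages of a substrate-stiffness
mechanosensing experiment: T cells filmed migrating on
ligand-functionalized polyacrylamide (PA) gels, the gels characterized by
shear rheometry, the antigen-presenting cells characterized by cantilever
indentation, and the ligand surface density of the gels estimated from
their chemistry. Each stage is a small, well-defined computation; this
vignette states each model, its assumptions, the tunable parameters, and
the numerical choices made where the design was open.

## Cell-track analytics

Input is a spot table: one row per detection, columns `track_id`,
`time_s`, `x_um`, `y_um`, at a nominally uniform frame interval (5 s by
default in the simulators, matching typical video-microscopy acquisition).
Three per-track statistics drive everything else:

* **Instantaneous speed** of step $i$: Euclidean displacement between
  frames $i$ and $i+1$ divided by the step duration, reported in
  µm/min. Per-step durations are used, so files with occasional dropped
  frames remain valid; a non-uniform interval triggers a warning, not an
  error.
* **Maximum excursion**: the maximum Euclidean distance between *any two
  points* of the track. This is deliberately neither the net
  start-to-end displacement (which can be near zero for a cell that
  loops back) nor the path length (which grows with positional noise).
  It is computed with `stats::dist()` and checked in the test suite
  against an independent $O(n^2)$ double-loop oracle.
* **Arrest call**: a cell is *arrested* when its maximum excursion over a
  5-minute window is strictly below 10 µm — equivalently, below a rate
  of 2 µm/min. The boundary is strict: exactly 10 µm counts as
  migrating. For tracks of non-standard duration the distance threshold
  scales linearly with duration, which preserves the 2 µm/min rate
  criterion; the equivalence of the distance rule and the rate rule on
  arbitrary windows is a property test.

Cohort summaries report the percentage of arrested cells and the mean ±
SEM of per-track mean velocities over **migrating tracks only** (the
default): arrested cells sit at near-zero velocity and would otherwise
turn a shift in arrest fraction into an artefactual shift in "speed".
`velocity_population = "all"` exposes the all-track statistics for
deceleration-style analyses. Tracks with fewer than 3 points are excluded
from velocity statistics (a 2-point track's "mean velocity" is a single
noisy step) and reported via a message; they still count toward the
arrest fraction. A cohort with no migrating tracks reports `NA` velocity
fields and `velocity_defined = FALSE` rather than an error.

Positions are strictly 2D; a z column in an input file is dropped with a
warning. Whether border-touching cells or gap-containing tracks should be
excluded upstream is a tracking-tool question the package does not
answer; the reader applies no such filter beyond the minimum-length rule.

## Hertz indentation fits

A stiffness-calibrated glass cantilever (stiffness $k$ = 3 nN/µm, tip
radius $R$ = 5.7 µm by default) is lowered by a base displacement $D$
onto a cell; the tip moves by $d < D$, the deflection is $D - d$, and the
elastic force is $F = k\,(D - d)$. Because the cell rests on a rigid
support and is indented from above, the indentation depth is identified
with the tip displacement, $\delta = d$; no finite-thickness
(bottom-effect) correction is applied. Curves are assumed pre-zeroed at
contact ($D = d = 0$); an optional `contact_offset_um` shifts both
displacements, and points left with $\delta \le 0$ are dropped with a
message. Automatic contact-point detection is out of scope.

The spherical Hertz contact model with the probe treated as rigid and
the cell taken as incompressible ($\nu_{cell} = 0.5$, absorbing the
$1/(1-\nu^2)$ factor) gives

$$F = \tfrac{16}{9}\sqrt{R}\; E_{cell}\; \delta^{3/2}.$$

The model is *linear* in $E_{cell}$, so the fit is the closed-form
least-squares slope of $F$ against $\tfrac{16}{9}\sqrt{R}\,\delta^{3/2}$,
constrained to $E \ge 0$ (a negative slope is clamped to zero with a
warning). This is exactly the least-squares optimum — there is no
iterative optimizer, hence no initialisation, convergence tolerance or
local-minimum concern. With forces in nN and lengths in µm the slope is
in nN/µm² = kPa; results are reported in Pa. The reduced modulus
$E^* = E_{cell}/(1-\nu_{cell}^2)$ is reported alongside; the full
two-material formula
$1/E^* = (1-\nu_{cell}^2)/E_{cell} + (1-\nu_{probe}^2)/E_{probe}$ is
available, and a test confirms that for a kPa-scale cell against a
GPa-scale glass probe the rigid-probe limit is accurate to better than
$10^{-4}$ relative. Slow indentation justifies the purely elastic model;
viscoelastic fitting is out of scope. The default fit window is all
positive-depth points, with an optional `delta_max_um` cutoff — the depth
range is an analysis choice, not a physical constant.

```{r hertz-example}
raw <- simulate_indentation(fixture = "hela-28kPa", seed = 1)
fit <- fit_hertz(raw_to_force_indentation(raw, k = 3), R = 5.7)
glance(fit)
```

## Gel rheology

A parallel-plate rheometer measures the shear storage modulus $G'$ of a
gel disc while the gap between the plates is stepped down; $G'$ rises as
the sample is progressively loaded and saturates once full contact is
reached. The characteristic modulus of the sample is taken as the
**maximum of $G'$ over the sweep** — the plain maximum, with no smoothing
or plateau-detection heuristic. This estimator is upward-biased in the
presence of noise (the maximum of noisy values exceeds the plateau on
average); it is kept because it is the field's estimator for this
measurement, and the simulator-based tests quantify the bias rather than
hide it.

Young's modulus follows from isotropic elasticity,
$E = 2\,(1+\nu)\,G'$, with $\nu = 0.45$ for polyacrylamide — a
conversion factor of exactly 2.9. Conversion is linear, so converting
per sample and then averaging gives the same mean as converting the
averaged plateau; SEMs scale by the same 2.9, and `summarize_gel()`
reports both the $G'$ and $E$ scales. The stiffest (18% acrylamide)
formulation in the fixture table carries a literature-cited modulus
rather than a sweep-derived one and is flagged `"reported"`.

## Ligand surface density

PA gels are functionalized by copolymerizing a streptavidin–acrylamide
conjugate into the mesh and then coating with biotinylated ligands. The
accessible surface density model rests on three assumptions: all
conjugate in the polymerization mix ends up in the gel; hydration swells
the gel to 1.4× the mix volume, diluting it accordingly; and biotinylated
ligands can only reach streptavidin within the outermost 10 nm of the
gel (about one streptavidin diameter, and below the reported pore size).

The chain is: acrylamide molarity $= 10 \times (\%\,w/v) / 71.08$ mol/L
(molar mass of the acrylamide monomer; the bis-acrylamide crosslinker is
excluded from the monomer molarity); times the conjugate molar ratio
($10^{-5}$); divided by the swelling factor; times Avogadro's number,
converted to molecules/µm³; times the accessible depth. Disc diameter
and gel thickness cancel exactly — the density is a property of the
chemistry, swelling and accessible depth alone — and this invariance is
tested over random geometries. For the 5% formulation the chain gives
≈ 30.3 molecules/µm², inside the published 20–40 range; that printed
range itself cannot be reproduced by propagating the rounded
intermediate volumes (the rounded chain still lands near 29–30, and the
exact chain is volume-invariant), so the package treats the printed
range as bounds to fall within, not as a target interval to re-derive,
and additionally emits the rounded-volume variant for transparency.

When the coating mix contains several biotinylated species at a molar
ratio — e.g. 10 parts anti-CD28 + ICAM-1 per 1 part anti-CD3 — the
minority density is obtained by **dividing the site density by the
majority fold** (30/µm² at 1:10 → 3/µm²). Note this "fold" convention is
not the same as partitioning the total sites 1:(fold), which would give
site_density/11; both values are emitted by `density_report()` and the
fold convention is primary, because it is the arithmetic conventionally
used with such coating recipes.

```{r density-example}
density_report(gel_recipe(acrylamide_pct = 5), gel_geometry())
```

## The synthetic-data generators

Real tracking, indentation and rheometry data for this kind of study are
rarely deposited, so every pipeline stage ships a forward simulator with
known ground truth, and the test suite is largely parameter-recovery:
generate with known parameters, run the pipeline, check the estimate.

**Tracks.** Each cell is independently arrested with probability
`frac_arrested`. Arrested cells take isotropic Gaussian jitter steps
(default SD 0.1 µm/frame, which keeps the 5-min excursion near 1.5 µm,
far below the 10 µm threshold). Migrating cells follow a persistent
random walk: the cell's mean speed is drawn from a zero-truncated
Gaussian (between-cell variability, `speed_sd_um_min`), each step's
speed from a zero-truncated Gaussian around that mean (within-cell
variability, default SD 3 µm/min), and the heading evolves by
wrapped-Gaussian turns whose spread is set so that the mean resultant
length equals `persistence` (default 0.7 — a moderately persistent
walker; this value is a modelling choice, as directional persistence is
not reported per condition). The hierarchical speed model is used —
rather than a single per-step speed distribution — because the published
per-condition numbers are cohort means with SEMs over cells: a
between-cell SD of 4 µm/min reproduces a cohort SEM of ≈ 0.4 µm/min at
n = 100, as printed for the stiffest condition. Sampling is by inverse
CDF, so each simulator consumes a fixed number of uniforms and is
bit-reproducible under a seed.

What the generator does *not* emulate: positional detection noise,
track fragmentation and gaps, border effects, speed autocorrelation
beyond the per-cell mean, and any mechanistic coupling between substrate
stiffness and motility. Passing recovery tests therefore shows the
*analytics* are correct, not that the biological effect sizes are
reproducible from this package — figure-level arrest percentages are
figure-encoded in the source material and are shipped only as
synthetic, ordering-preserving fixture values labelled as such.

**Indentation.** Depth grid linear in (0, `delta_max_um`]; force from the
Hertz forward model times multiplicative Gaussian noise (CV default 3%
in the cell fixtures — a typical force-sensor noise floor, chosen here,
not published); raw pairs emitted as $D = \delta + F/k$, $d = \delta$,
so the raw-to-processed conversion inverts the construction exactly at
zero noise. Multiplicative noise makes the closed-form fit exactly
unbiased, which the replicate tests verify.

**Gap sweeps.** $G'$ follows a saturating exponential in the loading
coordinate (gap decreasing), reaching the true plateau exactly at the
smallest gap, plus additive Gaussian noise clipped at zero. Additive
noise (rather than multiplicative) reflects a torque-resolution-limited
instrument; this is a modelling choice.

## Problem sizes and tolerances

The shipped tests use cohorts of 100–200 tracks, 200 replicate
indentation curves, and 20-point sweeps — sizes at which binomial and
SEM-based bounds (3 SE) are tight enough to catch sign and scale errors
while keeping the whole suite around ten seconds. Noiseless round trips
are asserted at machine precision (the Hertz fit is closed-form; the
simulators are exact inverses by construction); stochastic recoveries at
3 SE of the relevant estimator.

## Known limitations

* 2D tracks only; no MSD/persistence-time modelling.
* No contact-point detection and no bottom-effect correction in the
  Hertz stage; curves from very thin cells will read stiff.
* The plateau estimator inherits the upward noise bias of a maximum.
* The density model is theoretical: it assumes complete conjugate
  incorporation and a sharp 10 nm accessibility cutoff, and is not a
  substitute for fluorescence-based coating quantification.
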