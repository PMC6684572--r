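---
title: "A mass-spring model of lateral-root gravitropic bending"
author: "rootbend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mass-spring model of lateral-root gravitropic bending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(rootbend)
```

## The biological question

Lateral roots (LRs) of *Arabidopsis* emerge from the main root roughly
perpendicular to gravity and then bend downward until they hold a
characteristic gravitropic set-point angle (GSA). During the ~8–9 h
"stage II" window after emergence, cells on the upper flank of the young
organ elongate about three-fold faster than cells on the lower flank
(about 15 µm/h versus 5 µm/h at the epidermis). `rootbend` asks, in
silico, whether that measured elongation asymmetry alone is sufficient to
produce the observed bending — no gravity force, no hormone field, just
differential growth filtered through tissue mechanics.

## The model

The organ is a rectangular grid of quadrilateral cells (default 20
columns × 6 rows of 10 µm × 10 µm cells, a ~200 µm organ). Each cell wall
is a linear spring connecting two vertices. The force a spring exerts on
vertex *u* paired with *v* is

$$F^{u}_{\mathrm{spring}} = k_x\,(L_{u,v} - \lVert p_u - p_v\rVert)\,
\frac{p_u - p_v}{\lVert p_u - p_v\rVert},$$

positive under compression, with stiffness $k_x = 0.9$ for every wall.
Turgor pressure adds, for every wall of every cell, a force of magnitude
$p_{\mathrm{const}}\lVert p_u - p_v\rVert$ along the wall's outward
normal ($p_{\mathrm{const}} = 0.05$), split equally between the wall's
endpoints. Over a closed cell these pressure forces cancel exactly, so
interior walls feel opposing pressure from their two flanking cells;
the pressure's job is to keep cells inflated and protect the lattice from
degenerate shapes. Vertices obey damped Newtonian dynamics

$$\frac{d\,\mathrm{Vel}_u}{dt} = \frac{F^u_{\mathrm{total}}}{m_u}
  - \beta\,\mathrm{Vel}_u, \qquad \frac{d\,p_u}{dt} = \mathrm{Vel}_u,$$

with $m_u = 1$ and $\beta = 0.2$, integrated by forward Euler (the
default variant updates velocity before position; the pure forward
ordering is available via `mechanics_params(euler = "forward")`). The
right-most vertex column is fixed in x, mimicking the attachment to the
main root; gravity is the direction $(0, -1)$ but exerts no force.

Growth extends the *resting lengths* of axial (organ-axis) springs:

$$\frac{dL_{u,v}}{dt} = L_{u,v}\,\rho(d), \qquad
\rho(d) = \frac{r_{\min} + d\,(r_{\max}-r_{\min})}{L_{\mathrm{ref}}},$$

where $d \in [0,1]$ is the wall's *material* flank coordinate (row
index / number of rows, assigned at build time — bending must not feed
back into the rate field) and $r_{\min} = 5$, $r_{\max} = 15$ µm/h are
the measured flank elongation rates. Only axial walls touching at least
one elongating cell grow; transverse walls never do (anisotropic
growth). A run alternates one growth increment of $dt_g = 0.003$ h with
mechanical relaxation to transient equilibrium, for 9 h of model time
(3000 growth steps).

### Dimensional convention and the reference length

The growth law pairs a length-bearing $L_{u,v}$ with rates in
µm/h, so a convention is needed. We read $\rho(d) = r(d)/L_{\mathrm{ref}}$
as a relative elongation rate (h⁻¹). The measured rates refer to real
epidermal cells, which during stage II are an order of magnitude longer
than the 10 µm boxes the model draws, so the default reference length is
$L_{\mathrm{ref}} = 100$ µm — i.e. flank-relative growth of 5–15 % h⁻¹.
This value was calibrated once against the two reported stage II outcomes
(bending to ≈63° by ~8 h; >2-fold flank cell-length asymmetry at 9 h)
and then frozen; the package's tests never re-tune it. An absolute mode
(`growth_field(mode = "absolute")`, $dL/dt = r(d)$ applied directly at
the 10 µm drawing scale) is kept for sensitivity analysis; it bends far
too fast, which is what motivates the relative convention.

### Zones and the tip threshold

The organ splits along its axis into a non-growing tip zone and an
elongation zone, by a threshold on the distance of a cell's centre from
the tip. The threshold value is not fixed by the mechanics; we default to
`tip_zone_length = 180` µm, leaving the two base-proximal cell columns
elongating. That choice mirrors the histology of stage II LRs, where
only the first two cells behind the junction with the parent root have
entered elongation, and it is exposed in `scenario_config()` for anyone
modelling longer elongation zones.

## Numerical choices

* **Mechanics step.** The damped oscillator update is stable for
  $dt < 2\min(\beta m/k_x,\ 1/\beta) \approx 0.44$; the default is
  $dt_{\mathrm{mech}} = 0.2$ model-hours. This is deliberately coarse:
  relaxation is a quasi-static solve whose *fixed point* does not depend
  on the step size, only the (discarded) transient path does. With the
  underdamped constants above, the organ's soft global bending modes
  decay slowly (~0.01 per model-hour), so each of the 3000 relaxations
  needs several hundred model-hours of transient; relaxed configurations
  computed at $dt_{\mathrm{mech}} \in \{0.01, 0.1, 0.2, 0.3\}$ agree to
  within $5\times10^{-6}$ degrees of final angle.
* **Equilibrium criterion.** Both the maximum per-vertex
  $|F|/m$ and the maximum $|\mathrm{Vel}|$ must fall below
  `equilibrium_tol` ($10^{-5}$); the iteration cap ($10^{5}$) turns
  stalls into errors rather than silent drift.
* **Pre-inflation.** Turgor slightly stretches a freshly built lattice.
  Runs relax once *before* the first growth step and treat that state as
  the reference configuration, so the initial angle (90° ± numerical
  noise) is measured at mechanical equilibrium.
* **Boundary handling.** `fixed_x` is enforced by zeroing x-components
  of force and velocity, not by resetting positions after the fact,
  which would inject energy.
* **Degenerate inputs.** Coincident spring endpoints, non-positive cell
  areas, non-finite positions and unreachable tolerances raise typed
  errors naming the failing step; nothing is silently clamped.
* **Tie-breaks.** Angle-category bins are half-open, $(0,30], (30,50],
  \dots, (110,180]$, with 0 assigned to the first bin, so boundary
  angles have a deterministic home.

## Scenarios

`scenario_field()` derives each perturbation from the wild-type field:

| scenario | meaning |
|---|---|
| `wildtype` | measured 5→15 µm/h asymmetry |
| `reduced_upper_elongation` | upper-flank rate × 0.9 (the "10 %" experiment) |
| `fewer_upper_cells` | the k tip-most elongating top-row cells stop growing |
| `graded_cell_number` | silenced cell count graded linearly from top to bottom row |
| `symmetric` | $r_{\max} = r_{\min}$: control that cannot bend |

The "upper flank" for the 10 % scenario is the top cell row by default
(`top_rows` widens it); its axial walls are the two top wall rows of the
lattice. Because the model is deterministic, scenario ordering — less
upper-flank growth ⇒ less bending ⇒ larger final angle — is a sharp
prediction rather than a statistical tendency.

## A worked run

A full 9 h wild-type run takes tens of seconds on one CPU:

```{r run, eval = FALSE}
sim <- run_scenario(scenario_config("wildtype"))
summary(sim)
#> Scenario 'wildtype' over 9 h:
#>   set-point angle: 90.00 deg (t=0) -> 55.31 deg (end); 61.69 deg at ~8 h
#>   upper/lower flank cell-length fold change: 2.09
#>   301 trace records, 1508865 relaxation iterations in total
plot(sim)                 # angle vs time
plot(sim, type = "tissue")  # the bent mesh
```

The recorded angle falls from 90° to ≈62° at 8 h — the organ bends to
the observed set point from growth asymmetry alone — and the top-flank
elongation-zone cells end more than twice as long as their bottom-flank
counterparts, matching the cellular signature seen in vivo.

## The GSA statistics layer

`bin_gsa()` reproduces the phenotyping convention: each LR's angle to
the gravity vector is sorted into the six conventional categories (0–30°,
31–50°, 51–70°, 71–90°, 91–110°, 111–180°), percentages are computed per
plate, and summaries are reported as mean ± SEM *across plates* — the
plate, not the individual LR, is the replicate unit. `ks_two_sample()`
implements the two-sample Kolmogorov–Smirnov comparison used for
genotype-versus-control contrasts: $D$ is the exact supremum of the ECDF
difference over the pooled sample, and the two-sided p-value comes from
the asymptotic Kolmogorov distribution at $\sqrt{n_1 n_2/(n_1+n_2)}\,D$,
the standard choice at the tens-to-hundreds of LRs per group these
experiments produce (an exact permutation null would change little and
is out of scope). `gsa_t_test()` wraps the routine Student's t contrast
of group means.

## The synthetic generator

`generate_accession_angles()` emulates a phenotyping cohort: 5 plates of
16 seedlings, each plate contributing a uniformly drawn 30–120 LRs whose
angles follow a normal distribution truncated to [0°, 180°] (inverse-CDF
sampling, so one integer seed fully determines the dataset). The
truncated normal is the simplest unimodal family on a bounded angle
range consistent with the unimodal category histograms of real
accessions; hypo- and hyper-responsive accessions are planted as
location shifts, and `generate_panel()` adds allele annotations so the
KS and t contrasts can be exercised end to end.

```{r synth}
panel <- generate_panel(list(
  accession_spec("reference", mean_angle = 62, sd_angle = 12, seed = 1),
  accession_spec("hypo", mean_angle = 80, sd_angle = 12, seed = 2)))
compare_groups(panel, "reference", "hypo")
```

What the generator does *not* emulate: plate-level random effects
(angles are i.i.d. within an accession), within-seedling correlation,
measurement error from image tracing, and the multimodality real mutant
panels occasionally show. Tests passing on synthetic cohorts therefore
validate the statistics pipeline's arithmetic and calibration, not any
claim about real accession data.

## Known limitations

* Cells never divide; the 20 × 6 topology is fixed for the whole run,
  which is adequate for the 9 h stage II window but not beyond.
* Growth rates are prescribed, not mechanically regulated — there is no
  stress feedback, hormone transport, or gravity sensing; the model
  tests sufficiency of the measured asymmetry, not its origin.
* The mechanics is 2D; out-of-plane twisting of real LRs is invisible
  here.
* The relative-rate convention ties the measured µm/h rates to a
  reference cell length; conclusions about absolute organ length (as
  opposed to angle and flank asymmetry) should not be read off the mesh.
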