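---
title: "Methods: membrane mechanics and cristae morphometrics in mitoshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane mechanics and cristae morphometrics in mitoshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoshape)
```

## The model

A mitochondrion carries two membranes: the outer membrane (OMM) and the
inner membrane (IMM), whose boundary portion (IBM) runs parallel to the OMM
at an approximately fixed distance $d \approx 10\,$nm, maintained by
OMM–IMM tethering complexes. The rest of the IMM is folded into cristae.
When IBM membrane folds into new cristae, the IBM loses area relative to
the OMM; conversely, retracting cristae return area to the IBM.

`mitoshape` treats the coupled OMM/IBM pair as a single *mid-surface* of
area $A$ lying halfway between them. Because the three surfaces are
parallel, the outer and inner areas follow from the integrated total
curvature $M = \oint J\,\mathrm{d}A$ of the mid-surface
($J = c_1 + c_2$, the sum of principal curvatures):

$$A_\text{out} = A + \tfrac{d}{2} M, \qquad
  A_\text{in}  = A - \tfrac{d}{2} M, \qquad
  \Delta A = A_\text{out} - A_\text{in} = d\,M = d\,\langle J\rangle A .$$

A larger area difference therefore *requires* a larger average curvature:
this is the geometric driving force linking cristae folding to organelle
elongation. The relations hold in the small-curvature regime
$|J|\,d \ll 1$; `membrane_areas()` rejects profiles violating
$\max|J|\,d < 1$. Gaussian-curvature contributions are of order
$|K|d^2 \ll |J|d$ and are neglected throughout; no Gaussian (topological)
energy term is modelled.

Each membrane is a symmetric bilayer with vanishing spontaneous curvature,
and bending is the only elastic contribution (non-stretchable membranes).
With the individual membrane curvatures equal to the mid-surface curvature
to leading order, the total Helfrich energy of the pair is

$$F \;=\; 2 \cdot \frac{\kappa}{2}\oint J^2 \,\mathrm{d}A
      \;=\; \kappa \oint J^2 \,\mathrm{d}A ,$$

which for any sphere equals the Willmore bound $16\pi\kappa$. Energies are
reported in units of $\kappa$; the minimizing shapes do not depend on its
value, so `energy_model()` defaults to $\kappa = 1$.

The optimal shape at a prescribed normalized area difference is

$$\min_{\text{shape}} \; \kappa \oint J^2\,\mathrm{d}A
  \quad \text{s.t.} \quad A = A_0,\;\; \frac{d\,M}{A} = \frac{\Delta A}{A}.$$

This is a bilayer-couple-type constrained minimization. The **enclosed
volume is deliberately unconstrained**: the stated constraints are area and
area difference only, water and solutes exchange freely across
mitochondrial membranes on shape-change timescales, and fixing the volume
at the sphere's value would forbid any shape change at fixed area. This is
a genuinely open modelling choice; reproducing a specific published
silhouette family exactly could in principle require revisiting it, but all
qualitative conclusions (monotone loss of sphericity, prolate-to-peanut
progression, variational bounds) are insensitive to it.

## The solver

Shapes are axisymmetric surfaces of revolution — adequate for the
sphere-to-tubule branch — described by a 1D meridian profile: arclength
$s$, tilt angle $\psi(s)$, radius $r(s)$ with $r' = \cos\psi$,
$z' = \sin\psi$, and $J = \psi' + \sin\psi/r$ (pole limit $2\psi'$).

Rather than discretizing $\psi$ per node, the solver expands the tilt angle
on normalized arclength $u \in [0,1]$ in a sine series,

$$\psi(u) = \pi u + \sum_{k=1}^{K} a_k \sin(2\pi k u), \qquad K = 16
\text{ by default},$$

which *builds in* smooth pole closure ($\psi(0)=0$, $\psi(1)=\pi$), up–down
mirror symmetry ($\psi(1-u) = \pi - \psi(u)$), and — through that symmetry —
exact closure of the radius integral. Derived quantities are evaluated by
composite Simpson quadrature on `n_nodes` (default 201) uniform nodes, with
the cumulative radius integral carrying a fourth-order Hermite correction.

Two properties simplify the constraints. Both $F/\kappa$ and
$d\,M/A$ after rescaling to the target area are invariant under uniform
dilation, so the area constraint is enforced *exactly* by a final rescale
and only one scale-invariant constraint remains. It is handled by an
augmented Lagrangian over the mode amplitudes, minimized with BFGS
(central-difference gradients over the $K$ amplitudes), with multiplier
updates until the relative residual on $\Delta A/A$ is below $10^{-4}$.
The initial penalty weight is stiff ($\mu = 10^6$) — with a weak penalty
the line search can tunnel out of the shallow valley around the constrained
minimum via the linear multiplier term.

Targets are approached by continuation in $\Delta A/A$ steps of 0.01
(halved on failure), warm-starting each solve from the previous solution;
the first start is a sphere plus a seeded symmetry-breaking perturbation of
0.1% of the radius. Because warm-started continuation alone can follow a
metastable branch, every step *also* solves from the prolate spheroid
matched to the same constraint (initialized with its estimated shadow
price $\lambda \approx -t\,\mathrm{d}E/\mathrm{d}c$) and keeps the
lower-energy converged candidate. The spheroid family doubles as an
independent check: `trial_prolate_oracle()` computes, by dense quadrature
of the closed-form parametric curvatures of an ellipse of revolution, the
energy of the constraint-matched spheroid — a rigorous upper bound that
every converged minimizer must respect.

Targets below the sphere's own value $2d/R_0$ (the oblate/stomatocyte
branch) are rejected rather than solved: the model addresses elongation
only. On the 500 nm / $d = 10$ nm reference system the solver produces
necked ("peanut") minimizers from $\Delta A/A \approx 0.09$ onward, with
energies strictly below the prolate-spheroid bound; the two-equal-spheres
limit of this system lies at $\Delta A/A = 0.08\sqrt2 \approx 0.113$, so
dumbbell-like shapes are energetically natural well inside the studied
range. `classify_shape()` labels a solution `sphere` at sphericity
$\ge 0.999$, `peanut` when the radius profile has an interior local
minimum of depth $\ge 2\%$ of the maximal radius, and `elongated`
otherwise; the sphericity used throughout is $36\pi V^2/A^3$, normalized
to one for a sphere.

Mesh-independence (sphericity shift $< 10^{-3}$ between 201 and 401
quadrature nodes) and seed-independence of the continuation are covered by
tests.

## Morphometrics

A tracing is a closed outline polygon (the IBM silhouette) plus open
crista polylines, all in nm. 2D descriptors are standard: shoelace area,
closed perimeter $P$, circularity $4\pi\,\text{area}/P^2$ (1 for a
circle). Circularity can exceed 1 by discretization on coarse polygons;
values are stored as computed and only clipped, with a warning, in
display contexts.

The cristae fraction of total IMM length doubles each traced crista
(a crista is two membrane layers seen edge-on):

$$[\text{cristae/IMM}]\%_{2D}
  = 100\cdot\frac{2\sum_c l_c}{P + 2\sum_c l_c}.$$

The inferred-3D transformation models the mitochondrion as a cylinder with
hemispherical caps of radius $R$ (half the measured diameter). Each axial
ring of width $L_1$ has 3D area $2\pi R L_1$ while contributing $2 L_1$ to
the traced perimeter, so summing rings gives

$$S_\text{boundary} = 2\pi R \cdot \tfrac{P}{2} = \pi R P,$$

with the cap treatment absorbed into this approximation. Each crista is a
flat disk of diameter equal to its traced length $l$, counted on both
faces: $S_c = 2\pi (l/2)^2$ — the 3D counterpart of the 2D doubling rule.
The equations for these two surface contributions appear only as images in
the source material; the forms above are reconstructed from its worded
ring/disk construction, and this reconstruction is the one numerical
convention in the package that could not be verified character-for-
character. Then

$$[\text{cristae/IMM}]\%_{3D}
  = 100\cdot\frac{\sum_c S_c}{\sum_c S_c + S_\text{boundary}}.$$

Because the diameter was measured manually in the source workflow,
`estimate_diameter()` automates it reproducibly: principal axis by
arclength-weighted second moments of the outline, then the median chord
perpendicular to the axis over the middle 80% of its extent. Whether the
manual measurement was a single mid-shape chord or an average is unknown;
the median chord is robust to cap effects and jitter (within 5% of truth
under 2% vertex jitter in tests). Near-circular outlines (extent ratio
< 1.05) have no meaningful axis and fall back to the mean caliper width,
flagged in the output. Cristae longer than 1.5 diameters are flagged as
likely tracing errors but never dropped silently.

Mitochondria without traced cristae are excluded at the *pipeline* level
(`measure_cohort()`, configurable), mirroring the acquisition rule that
such organelles cannot be scored; the morphometric functions themselves
measure them without complaint.

## The synthetic generator

No tracings are deposited with the source study, so the generator is the
package's data supply and defines the study conditions. It emulates manual
tracings of PKMO-stained live-cell STED images: stadium outlines (2D
silhouette of a spherocylinder) with straight length sampled log-uniformly
on 120–2500 nm and cap radius uniformly on 125–250 nm (organelle widths of
250–500 nm and overall lengths up to ~3 µm, the ranges typical of such
recordings), smooth low-order Fourier jitter of 2% of the radius along the
outline normal, and transverse crista segments spanning 80% of the local
width, at least 40 nm apart (a typical crista spacing floor). These
defaults were fixed once from the imaging context; they are exposed in
`cohort_spec()` but not tuned.

The tunable coupling between cristae fraction and circularity is
implemented as a Gaussian linear link: the targeted fraction is
$\mu_F + \sigma_F(\rho z_c + \sqrt{1-\rho^2}\,\varepsilon)$ with $z_c$ the
standardized *realized* circularity of the generated outline
($\mu_F = 30\%$, $\sigma_F = 8\%$), realized by choosing total crista
length against the *realized* perimeter. Coupling to realized rather than
ideal-stadium geometry matters: outline jitter enters both the perimeter
and the circularity, and coupling to the ideal geometry would leak jitter
into a spurious correlation in null cohorts. A linear link is the unique
choice for which `coupling_r = -1` with zero noise yields a measured
Pearson $r$ of exactly $-1$; a purely mechanistic conservation link is
monotone but nonlinear and cannot do so. The conservation mechanism — no
lipid gain or loss, so $P + 2\sum l$ is constant — is instead implemented
where it carries the physics: `generate_timeseries()` holds the total 2D
IMM length fixed (to $10^{-3}$ relative) while cristae retract, so the
straight section shrinks and the cap radius grows until a circle remains.
Capacity limits (per-crista length cap, spacing floor) can truncate
extreme fraction targets; truncations are recorded in the truth table and
the achieved pre-noise correlation is reported.

What the generator does *not* emulate: curved or branched outlines, cristae
that are oblique, curved or out-of-plane, partial labelling, focal-plane
drift, and any photophysics beyond optional Gaussian PSF + Poisson noise in
`rasterize_trace()`. Passing tests therefore demonstrate that the
*measurement and statistics machinery* is correct and well-calibrated on
data with the assumed structure — not that real STED tracings satisfy that
structure.

## Statistics

`correlate_fraction_circularity()` uses the Pearson product-moment
correlation with the exact $t$ transform on $n-2$ degrees of freedom
(two-tailed) — correct at the small per-group $n$ of split analyses, where
a normal approximation would be optimistic — plus the least-squares line
and a pointwise 95% confidence band for the mean response. A permutation
test validates the parametric p-value in the test suite.
`size_split_analysis()` splits at the median 2D area; rows equal to the
median go to `small` (the source rule says strictly below/above and leaves
ties unspecified; a deterministic rule was chosen and documented).
`compare_groups()` is an unpaired two-tailed Student's t-test with box-plot
descriptives (Tukey whiskers at 1.5 IQR). `timeseries_profile()` reports
per-frame morphometrics and Kendall's $\tau$ of fraction against time
($\tau$ is `NA` for constant series). No multiple-testing correction is
applied anywhere: each analysis is a single planned test.

## Problem sizes and numerical conventions

The reference shape family runs on the 500 nm sphere with $d = 10$ nm over
$\Delta A/A \in [0.08, 0.20]$ (201 quadrature nodes, 16 modes). Cohort
analyses use $n = 100$ mitochondria per cohort; calibration sweeps use 200
seeds for the null correlation and 100 seeds for the size-split contrast —
sizes at which the sampling distribution of $r$ (s.d. $\approx 0.09$ at
$n = 100$) makes the pass criteria meaningful. Tolerances: constraint
residuals $\le 10^{-4}$ relative; sphericity comparisons at $10^{-3}$;
quadrature identities at $10^{-6}$. Degenerate inputs (zero-variance
columns, groups below minimum size, self-intersecting outlines, pinched
profiles) raise typed conditions (`mitoshape_*` classes) rather than
propagating NaNs.

## Known limitations

* Axisymmetric, mirror-symmetric shapes only; no oblate branch, no
  topology changes, no area-difference-elasticity generalization, no
  thermal fluctuations.
* Free enclosed volume (see above) is a modelling choice, not a measured
  fact.
* The 3D transformation assumes a straight spherocylinder and flat disk
  cristae; strongly bent organelles violate it.
* The generator's stadium family cannot produce the bent or branched
  morphologies excluded from the source analyses in the first place.
* `estimate_diameter()` automates a manual measurement; its median-chord
  convention is one defensible reading among several.
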