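---
title: "Modeling cochlear-implant stimulation of the auditory nerve with cochstim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cochlear-implant stimulation of the auditory nerve with cochstim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model overview

`cochstim` simulates monopolar electrical stimulation of auditory nerve
fibers (ANFs) by cochlear-implant electrode arrays, using the standard
two-step approach of the field: (1) a volume-conductor computation of the
extracellular potential $V_e$ for a unit current injected at one electrode
contact, and (2) a multi-compartment cable model of the human type I spiral
ganglion cell driven by $V_e$ sampled along its trajectory. On top of these
two engines the package reproduces a family of analyses: excitation
thresholds and spike initiation sites (SIS) per fiber and contact,
comparisons of peri-modiolar (pm) and lateral-wall (lw) arrays inserted in
scala tympani (ST) or scala vestibuli (SV), the effect of neural
degeneration (thinned or absent dendrites), stimulation specificity and
selectivity maps, and the sensitivity of thresholds to tissue conductivity
assumptions including progressive ST ossification.

The original study this pipeline emulates was built on a proprietary
micro-CT segmentation with 25 manually traced fiber trajectories and a
commercial finite-element solver. Neither input is redistributable, so the
package includes a fully synthetic, parametric stand-in (the
`synthetic cochlea` below). Absolute threshold currents in microamperes are
therefore **geometry-specific and not comparable** to the published
medians; the testable surface is the set of structural relations and
directional effects, which the test suite asserts.

## The synthetic cochlea

`build_geometry()` constructs a logarithmic spiral (basal duct-center
radius 2,920 um, halving over the 690 degree span, vertical pitch 1,252 um
per turn) whose duct-center arc length is about 25.5 mm, matching the
~25 mm electrode arrays. Three fluid ducts ride on the spiral as circular
cross-sections in the radial-vertical half-plane: ST below (radius 400 to
260 um), SV above (380 to 240 um) separated by a 700 um partition, and a
small scala media (SM) pocket lateral of the organ-of-Corti position. A
conical modiolus occupies the core, a bony capsule surrounds the ducts, and
everything outside is a bone-conductivity medium standing in for the
grounded far-field sphere.

Fibers (`place_anfs()`) run from a peripheral terminal at the
organ-of-Corti site -- 600 um above the ST roof on an "osseous spiral
lamina" shelf that slopes down toward the modiolus -- inward along the
shelf, then hook down into a Rosenthal's-canal band where the 20 um soma
sits, and continue as a central axon descending through the modiolar core
in a helix. Dendritic arc lengths are **deterministic anatomy, not a
random draw**: a monotone profile over insertion angle, rescaled piecewise
so the default 25-fiber set reproduces the traced-fiber order statistics
exactly (minimum 1,320 um, median 1,732 um, maximum 2,312 um, longest
fibers basal). The eight insertion angles named in the source study's
results (23, 77, 195, 256, 416, 467, 494, 680 degrees) are always present;
the remainder fill an even grid, preserving basal-to-apical coverage.

Geometric parameters worth knowing (all configurable via
`geometry_config()`):

* `terminal_clear` (600 um): height of the terminal above the ST roof.
  This clearance, together with the 700 um partition, controls how closely
  the peri-fiber near field couples to each duct; it was chosen so that an
  SV-facing contact sits adjacent to SV fluid while remaining several
  voxels away from ST perilymph at the shipped map resolutions, which is
  the configuration the ossification analyses presuppose.
* `soma_depth` (200 um): radial depth of Rosenthal's canal below the inner
  ST wall.
* `dendrite_stats`: the three order statistics above; the hook's dip is
  solved by root finding so every fiber's peripheral arc length is exact.

What the stand-in deliberately does **not** emulate: the fan-shaped,
irregular fiber endings of the traced dataset (our fibers are smooth and
regular, so threshold scatter is smaller than in the study), scala
cross-section eccentricity, and any inter-subject variability. Passing
tests therefore demonstrate that the algorithms reproduce the mechanisms
on a clean geometry, not that they predict any individual cochlea.

## Electrode arrays

`fit_centerline()` reconstructs the iterative constrained centerline fit:
control points expressed as radial/vertical offsets from the duct center
are cubic-spline interpolated (C2), the nearest centerline point to each
fiber is projected onto that fiber's 255 um iso-distance surface (the
vertical component following the fiber-derived slope, the radial component
moving the curve laterally), and the under-relaxed, scala-clamped offsets
are re-splined until the largest move is below 1 um (at most 200
iterations, error with per-fiber residuals otherwise). Lateral-wall and
peri-modiolar branches are selected by initialization side; with
`couple_lateral = TRUE` the ST/SV pair shares the radial coordinate
dictated by the narrower canal (SV), as in the source construction, at the
price of larger fiber distances for the ST member of the pair. All four
default centerlines are 23-27 mm long with uncoupled median fiber
distances within a few micrometers of 255 um.

The carrier tapers linearly from 600 um diameter at the base to 300 um at
the apex. Contacts are cylinders (radius 150 um, height 50 um --
unspecified in the source, chosen once and configurable) whose centers sit
on the carrier surface, facing the fibers by default (up in ST, down in
SV) or the cochlear axis in the `alternative` mode. Because the synthetic
fibers run directly above (ST) or below (SV) the lateral-wall curves,
default-mode contact centers end up much closer to their target fibers
(tens of micrometers) than the centerline's 255 um; the analyses only use
distance *relations*, which are preserved (axis-facing contacts are
farther for lw arrays, each contact is nearest to its same-angle fiber).

## Volume conductor

`voxelize()` labels voxel centers in priority order (contact > carrier >
duct fluid > modiolus/lamina > bone > exterior) and assigns the published
domain conductivities: 1.43 S/m perilymph (ST, SV), 1.67 S/m endolymph
(SM), 0.0334 S/m modiolus (including the lamina shelf), 0.016 S/m bone and
surrounding medium, 1,000 S/m contacts. The silicone carrier is an
insulator; the map carries 1e-6 S/m so the discrete operator stays
non-singular. The carrier is rasterized strictly (center-in-solid) so the
perilymph sheath around it survives coarse grids; contacts are rasterized
strictly with a half-spacing dilation fallback so every contact occupies
at least one voxel. Exterior padding is at least one cochlear diameter on
all sides and the box boundary is the monopolar return (Dirichlet 0).

`solve_field()` discretizes div(sigma grad V) with the 7-point stencil and
harmonic-mean face conductivities, injects 1 uA uniformly over the contact
voxels, and solves with matrix-free conjugate gradients under a
modified-incomplete-Cholesky preconditioner to a relative residual of
1e-8; a sparse-Cholesky direct path (`method = "cholesky"`) is provided
and agrees within the residual contract. Fields are computed once per
contact at 1 uA and rescaled during threshold searches (linearity), never
re-solved per amplitude. Sensitivity sweeps warm-start the solver from the
unmodified map's solution.

Two verification modes matter. The production boundary is the grounded
box. For the analytic point-source comparison the solver offers
`boundary = "free"`, which prescribes the monopole's exact values on the
boundary faces: with a grounded boundary the free-space 1/r law is not
recoverable near the box (the induced boundary term is a large fraction of
the potential at a quarter of the box size), whereas exact boundary values
isolate the interior discretization error, which is below 5% outside a
five-voxel radius of the source. Discrete current conservation through
closed boxes holds to 1e-6 relative, and source/probe reciprocity holds to
solver tolerance.

## The cable model

`assemble_chain()` lays the compartments of the human type I spiral
ganglion cell along the fiber polyline by arc length (so internode
curvature is honored): a 10 um unmyelinated terminal, 4-10 myelinated
peripheral internodes whose effective length is chosen closest to the
250 um target given the fiber's dendritic length, 2.5 um nodes of Ranvier,
a 100 um pre-somatic segment, the 20 um spherical soma, a 5 um
post-somatic segment, and ten 500 um central internode/node pairs. The
soma-to-post-somatic center distance of 12.5 um falls out of this layout.
Diameters are 1.3 um (dendrite), 2.6 um (axon), 20 um (soma); the severe
degeneration condition thins all peripheral compartments to 0.5 um, the
complete degeneration condition starts the chain at the soma.

Membrane: internodes are passive with capacitance and conductance divided
by the myelin sheet count (40 dendritic, 80 axonal, 1 uF/cm2 and
0.1 mS/cm2 per sheet); the soma's membrane quantities are divided by its
three surrounding layers; terminal, nodes and peri-somatic segments carry
classic squid-axon Hodgkin-Huxley kinetics (m3h sodium 120 mS/cm2, n4
potassium 36 mS/cm2, leak 0.3 mS/cm2, reduced-voltage convention with rest
at 0 mV) at tenfold channel density. All rate constants are multiplied by
a temperature factor `k_temp = 12`, which yields action potentials of
roughly 0.15 ms width at the central nodes -- sub-millisecond, as reported
for the human cochlea. Intracellular resistivity is 0.1 kOhm cm.

Numerics: anatomical compartments longer than `seg_max = 50` um are split
into equal electrical segments. This matters: with fast (k = 12) kinetics
and single-compartment internodes the depolarization wave cannot charge
the large pre-somatic and internodal capacitances through the full
compartment-to-compartment resistance within an AP's duration, and
propagation across the soma fails artificially; at 50 um segmentation
thresholds are converged (halving `seg_max` changes them by well under
2%, as does halving the 1 us implicit-Euler step). Gating states use the
Rush-Larsen exponential update; the voltage system is tridiagonal and
solved directly each step. Pulses are 50 us monophasic rectangles starting
at 0.1 ms; the 1.5 ms window extends automatically while a spike is still
developing at its end.

Spike criterion and SIS (both ours, both configurable in concept): a trace
spikes when the reduced membrane voltage exceeds +60 mV at either of the
two most central nodes; the SIS is the electrically active compartment
whose voltage peak occurs earliest, ties breaking toward the terminal.
Passive internode segments are excluded from SIS candidacy because the
extracellular gradient can swing them above the criterion directly without
initiating anything.

## Thresholds and analyses

`threshold_search()` brackets from 10 uA by factors of two (down to
0.1 uA, up to 20 mA; non-excitable pairs are returned masked rather than
as errors) and bisects to a 1% relative bracket width; the threshold is
the bracket midpoint and the SIS/latency are read at 1.01 x threshold,
which avoids borderline non-spikes exactly at threshold. Against a 0.5%
step linear amplitude sweep the bisection agrees to well under 1%.

`specificity_map()` and `selectivity_map()` normalize the fiber x contact
threshold matrix by its contact-wise and fiber-wise minima. Summary
medians exclude the structural 0% (argmin) entries by default --
the published summaries plausibly do the same, and a flag restores them.
`conductivity_sensitivity()` (modiolus x10, bone x2, both) and
`ossification_sweep()` (ST sigma 1, 0.65, 0.3, 0.03 S/m) re-solve the
fields per modified map and report per-fiber pairs, median percentage
changes and ordinary-least-squares regressions of new on default
thresholds. Robustness variants rerun healthy thresholds with the
peripheral internode target halved to 125 um and with every dendritic
length fixed at 1,700 um (the course is regenerated between the unchanged
terminal and soma anchors; the source does not state how paths were
adjusted).

## Problem sizes and runtimes

The shipped default `run_config()` is a desk-scale profile chosen to keep
a complete pipeline run (four arrays, 25 fibers, three neural conditions,
robustness, two full 25 x 25 specificity matrices, sensitivity and
ossification sweeps over five fibers per array, carrier-potential
profiles) around ten minutes on one CPU: per-contact field solves at
300 um voxels, conductivity/ossification sweeps at 420 um with solves
warm-started along the conductivity ladder, all cable integration at 1 us
steps. The production-style resolution of 60 um mentioned in the
configuration documentation is reachable by setting `spacing` but is not
exercised by the tests. Voxel volumes converge to the analytic duct
volumes at first order; at 300 um the ST fluid sheath around the carrier
is a few hundred voxels, which is the minimum at which the
ossification physics (a conductive conduit that can be blocked) is
representable -- results at coarser spacings degrade toward no effect.

A note on the geometric robustness variants: with the halved peripheral
internode target and the fixed 1,700 um dendritic length, the mean
threshold of each array shifts by under 3%, but individual fibers can move
by 15-30% and the mean absolute per-fiber change reaches ~7% for the
lateral-wall ST array. The sensitivity is a direct consequence of the very
small contact-to-fiber distances of the synthetic lateral-wall arrays:
re-laying the compartments moves peripheral nodes by up to half an
internode length, which is comparable to the contact distance itself.

## Known limitations

* Absolute currents depend on the synthetic geometry and the coarse maps;
  only orderings and directions are meaningful.
* The coupled ST/SV pairs inherit the narrower canal's lateral track, so
  the ST members sit farther from the fibers than the 255 um target --
  the uncoupled fit is used where that distance itself is under test.
* Biphasic pulses, pulse trains, stochastic channel gating, myelin-loss
  degeneration and frequency-place maps are out of scope.
* The homogeneous-medium point source is exact; the voxel solver's
  near-source values (within ~5 voxels) are first-order accurate only and
  should not be sampled for compartments closer than one voxel to a
  contact at coarse resolutions.
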