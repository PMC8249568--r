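---
title: "Superficial wall strain and stress from dynamic vessel geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superficial wall strain and stress from dynamic vessel geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sws4d)
```

## The inverse problem

Coronary arteries deform continuously through the cardiac cycle: pressure
pulsation changes their diameter by roughly 10–15%, while myocardial
contraction stretches, bends and displaces them. Conventional vascular
biomechanics runs *forward*: assume a pressure load and material law, solve
for the deformation and stress. `sws4d` runs the computation *backward*: the
observed motion of the lumen surface — the kind of motion that can be
reconstructed from routine biplane angiography — is itself the data, and the
mechanical state of the superficial wall layer (the lumen–intima interface,
where plaques rupture and stent struts fracture) is inferred from it. The
pipeline is:

1. **Meshing.** Each cardiac frame's lumen geometry (centerline plus
   per-ring radius) is discretized into a structured quadrilateral surface
   mesh with the same node dimensions `(L, C)` for every frame.
2. **Displacement mapping.** The one-to-one node correspondence between
   consecutive frames is the one minimizing a potential-energy functional;
   propagating it from diastasis around the cycle yields per-node
   displacement fields.
3. **Strain.** Per-element in-plane deformation gradients come from
   element edge-length ratios; principal stretches give the maximum
   principal strain, cumulatively composed from diastasis.
4. **Stress.** An incompressible Mooney–Rivlin membrane in plane stress
   converts stretches into principal Cauchy and von Mises stresses, with
   the material chosen per segment from the percent-diameter-stenosis
   profile (normal vs. diseased wall).

Diastasis (mid-diastole) is the reference configuration: the ventricle is
quiescent there, so kinetic and strain energy are at their cycle minimum and
the configuration is treated as the zero-strain state.

## Geometry and meshing

Cross-sections are modelled as circles (one radius per centerline ring).
Circumferential node placement uses rotation-minimizing frames propagated by
the double-reflection method, so a curved or twisted centerline does not
inject spurious circumferential strain. The seed normal is a fixed world
axis projected off the first tangent, which keeps node labelling nearly
aligned between frames that differ by small rigid motions. Default mesh
density is `L = 101` rings by `C = 32` circumferential nodes for a 50 mm
vessel (≈0.5 mm axial spacing, a factor 2–3 above typical angiographic
resolution); both are configurable everywhere.

The diameter-stenosis profile interpolates a reference (healthy) diameter
linearly between lesion shoulders. Shoulders are found from the global
minimum-diameter ring: on each side, the nearest ring whose diameter
recovers to at least 90% of that side's segmental median, then extended
outward to the local diameter maximum so the reference anchors on the
healthy rim of the taper rather than inside it. Rings above 20% diameter
stenosis are labelled stenotic; with no recovery on either side the maximum
diameter serves as reference (with a warning).

## The matching functional

The energy of a candidate correspondence between configurations `A` and `B`
is

\[
E = \alpha_d \sum_e W\!\left(\lambda_1^e, \lambda_2^e\right) A^e_{\mathrm{ref}}
  \;+\; \alpha_k \, \frac{1}{LC\,d_{\mathrm{nom}}^2} \sum_n \lVert u_n \rVert^2 ,
\]

where `W` is the Mooney–Rivlin energy density at nominal normal-tissue
constants, \(A^e_{\mathrm{ref}}\) the reference element area, and \(u_n\)
the node displacements. Because all meshes share identical node dimensions,
the search space reduces to a continuous axial re-parameterization shift
plus a circumferential twist; an exhaustive pass over all `C` node offsets
crossed with axial offsets within ±2 ring spacings is followed by
Nelder–Mead refinement of both offsets.

Three numerical choices matter here:

* **The kinetic term is a tie-breaker, not a load.** With
  \(\alpha_d = 1, \alpha_k = 10^{-3}\) the deformation term dominates by
  orders of magnitude for any non-isometric candidate; the displacement term
  only selects the physically smallest motion among deformation-equivalent
  (isometric) matches, e.g. relabelling a rotationally symmetric ring. A
  larger \(\alpha_k\) lets large rigid translations buy spurious axial
  sliding; a zero one leaves gauge freedom unresolved.
* **Fractional circumferential offsets preserve ring radius.** Linear
  interpolation between neighbouring nodes traces a chord inside the ring;
  the interpolated radial vector is rescaled to the linearly interpolated
  node-to-centroid distance, so a half-node twist cannot masquerade as
  circumferential compression.
* **Refinement must earn its keep.** The elastic energy of an inhomogeneous
  strain field has shallow minima under small re-parameterization slips
  (order 0.1% of the energy, producing ~0.05 mm drifts near steep radius
  tapers). The continuous refinement is therefore adopted only when it
  lowers the energy by more than 1% (`refine_min_improvement`), extending
  the discrete tie-break rule — prefer the smaller offset among near-ties —
  to the continuous landscape. Genuine sub-node mis-registrations cost far
  more than 1% and are still refined.

Degenerate geometries keep their gauge freedoms: an axially uniform
straight tube cannot distinguish axial sliding from translation, and any
circular ring is insensitive to relabelling; the tie-breaker then picks the
smallest motion. Real vessels (tapered, stenotic, curved) pin both.

Cycle closure (diastasis mapped around the full cycle back onto itself) is
measured and reported as an RMS residual, never corrected — drift is a
diagnostic of mapping quality.

## Strain and stress

Per element, the in-plane deformation gradient `F` is the least-squares
2×2 map sending the four reference edge vectors (in the element's local
tangent basis) to the deformed ones. Principal stretches are the singular
values of `F`; incompressibility fixes the through-thickness stretch
\(\lambda_3 = 1/(\lambda_1\lambda_2)\) (the product
\(\lambda_1\lambda_2\lambda_3 = 1\) holds to 1e-12 by construction).
Cumulative strain composes the per-step gradients from diastasis
(\(F_{\mathrm{tot}} = F_k \cdots F_1\)); the incremental frame-to-frame mode
is also exposed. The reported maximum principal strain is the cumulative
\(\lambda_1 - 1\): a cycle-long maximum needs a fixed reference, and the
per-step element length ratio is exactly what the incremental mode provides.

Under plane stress (\(\sigma_3 = 0\)) the incompressible Mooney–Rivlin
principal Cauchy stresses reduce to

\[
\sigma_k = 2C_1(\lambda_k^2 - \lambda_3^2) - 2C_2(\lambda_k^{-2} - \lambda_3^{-2}),
\qquad k = 1, 2,
\]

and the equivalent stress to
\(\sigma_{vM} = \sqrt{\sigma_1^2 - \sigma_1\sigma_2 + \sigma_2^2}\). The
shipped material table (normal wall \(C_1 = 18.9\), \(C_2 = 2.75\) kPa;
fibrous 2×, calcified 10×, lipid-rich 0.5× the normal constants) is a
placeholder: soft-tissue constants of this form are empirically fitted and
vary widely between studies. Every analysis in the package depends on them
only through ratios and orderings, never through absolute magnitudes, and
the table is overridable in every consumer. Pulse stress — the per-element
absolute von Mises difference between end-systole and end-diastole — is
reported with the arclength of its peak from the ostial end.

## What the synthetic generator emulates

`make_stenosis_model()` builds the idealized stenotic vessel used
throughout: 3 mm nominal lumen, 50 mm long, a 10 mm concentric mid-vessel
lesion cosine-tapered to 50% diameter stenosis, one of three plaque
compositions, plaque burden targets of 50.9, 62.6 or 69.1 percent volume,
and negative/none/positive remodeling. Burden and remodeling jointly
over-determine the external elastic membrane (EEM) with a fixed wall
thickness, so the generator resolves them as: remodeling sets the tapered
lesion-EEM multiplier (0.95 / 1.00 / 1.10), and the normal wall thickness is
solved by root-finding so the achieved burden matches the target within
5e-3 (an unattainable combination raises an error naming the feasible
range). The solved thicknesses (≈0.15–0.6 mm across the burden levels) are
anatomically plausible.

`generate_cardiac_sequence()` composes, per phase and weighted by a smooth
raised-cosine waveform peaking at end-systole: radial pulsation (default
drawn from 10–15%), attenuated inside the lesion by a per-composition
multiplier (calcified 0.2, fibrous 0.5, lipid-rich 0.8 — stiff plaque
distends least); axial stretch about the ostium; Gaussian transverse bending
applied by translating and tilting each ring so cross-sections stay normal
to the bent axis; and rigid-body motion. Ground-truth node grids are stored,
and the cycle closes exactly by construction.

What the generator does *not* emulate, and what passing tests therefore do
not show about real angiography: lumen segmentation error and reconstruction
noise, elliptical or irregular cross-sections, frame-timing jitter,
out-of-plane twisting of the heart, bifurcations, and any real constitutive
heterogeneity beyond the binary normal/lesion segmentation. The validation
design shows the inverse machinery is self-consistent at desk scale, not
that it is robust to imaging physics.

## The force-based comparator

`solve_membrane_equilibrium()` is the conventional counterpart used for
closed-loop validation: per ring, the incompressible Mooney–Rivlin
cylindrical membrane equilibrium \(P\,r_{\mathrm{def}} =
\sigma_\theta\,t_{\mathrm{def}}\) is solved for the circumferential stretch
by bracketed root-finding, with axial stretch fixed (tethered coronary,
\(\lambda_z = 1\) by default) and \(t_{\mathrm{def}} =
t_{\mathrm{ref}}/(\lambda_\theta\lambda_z)\). Its thin-wall limit agrees
with Laplace's law \(\sigma_\theta = Pr/t\) to within 2%.
`forward_pressurized_sequence()` assembles per-phase equilibria into a
motion sequence carrying forward hoop-stress ground truth; the diastasis
phase must carry zero transmural pressure because the inverse pipeline
treats diastasis as the stress-free reference, so all stresses are relative
to the diastasis state. When asked, the waveform is rescaled so the normal
segment pulsates by a target fraction (default 0.12, mid-physiological);
the pressures this implies (~1.5–6 kPa across the burden levels) sit in the
range of coronary pulse pressures.

Ring-decoupled equilibria have no axial coupling, so the stretch field
kinks at the binary material boundary and the deformed surface steepens
there. Two consequences are documented limitations rather than bugs:

* Elements straddling the material boundary mix normal-segment strain with
  plaque constants; for a stiff (calcified) lesion this produces boundary
  stress artifacts that dominate a naive "maximum lesion von Mises stress"
  statistic.
* The robust lesion-stress statistic is evaluated at the **throat** (the
  minimum-diameter ring), where the material is unambiguous and the radius
  profile is stationary, making the ring-circumference stretch ratio
  insensitive to sub-ring matching slip (`ring_stretches()`).

With that statistic, the in-silico experiment reproduces the expected
physics: at fixed burden and motion budget, throat stress orders
lipid-rich > fibrous > calcified (softer plaque stretches more under the
pressure that produces the common normal-segment pulsation), and stress
rises monotonically across the burden levels (thicker normal wall demands
higher driving pressure for the same observed pulsation, and the lesion
bears it). The separations across compositions are small (a few percent) —
a genuine property of membrane equilibrium, where hoop stress is largely
statically determined; the much larger separations reported by full 3D FEA
studies arise from through-wall stress concentration that a membrane cannot
represent.

## Validation experiments and problem sizes

The package ships the two validation designs as runnable experiments, at
sizes chosen to keep a complete run on one CPU in minutes:

* **Centerline prediction** (`run_prediction_experiment()`): 16 seeded
  synthetic sequences (L = 101, C = 32, five cardiac phases), one random
  non-diastasis frame held out per sequence, predicted by propagating the
  mapping around the remaining cycle with piecewise-linear time
  interpolation, and compared to truth by index-corresponded Procrustes
  superimposition. Reflections are excluded (anatomical curves preserve
  chirality); dissimilarity is the standardized residual, bounded in [0,1];
  the scaling factor is the optimal full-Procrustes scale applied to the
  raw centered prediction, so pure size errors appear there and nowhere
  else.
* **Method equivalence** (`run_method_equivalence()`): the 3 compositions ×
  3 burdens grid, forward-pressurized to 12% normal-segment pulsation, then
  run through the inverse pipeline; the inverse principal stress at a
  normal mid-segment ring is compared with the forward hoop-stress ground
  truth (agreement is at numerical precision on straight vessels; the
  acceptance bound is 5%).
* **Peak localization** (`run_peak_location_experiment()`): a 16-sequence
  cohort with bending apices drawn near the proximal lesion shoulder;
  reports where the cycle-maximum von Mises stress falls
  (shoulders/throat/normal).

## Known limitations

* Membrane (plane-stress) idealization: no through-thickness gradients, no
  bending stiffness, no residual stress, no anisotropy or viscoelasticity.
* Circular cross-sections; single-vessel segments without bifurcations.
* The matching search covers axial re-parameterization and circumferential
  twist only — free-form correspondence is out of scope, and symmetric
  geometries retain the gauge freedoms described above.
* Absolute stress magnitudes inherit the placeholder material constants;
  only ratios, orderings and closed-loop recoveries are meaningful.
* Phase labels are inputs: ECG synchronization and frame selection happen
  upstream of this package.
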