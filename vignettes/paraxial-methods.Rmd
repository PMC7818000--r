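---
title: "Paraxial models, stops and vignetting: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paraxial models, stops and vignetting: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraxial)
```

This vignette documents the model the package implements, the conventions
it commits to where the formalism leaves a choice, the numerical decisions
(tolerances, tie-breaks, degenerate inputs), and what the synthetic ray
ensembles used in the tests do and do not establish about real systems.

## The model

A meridional light ray is the state $(y, \theta)$: height above the optical
axis (mm) and angle with it (rad). Under the paraxial approximation
$\sin\theta \approx \theta$, propagation through any element is linear,

$$\begin{pmatrix} y' \\ \theta' \end{pmatrix} =
\begin{pmatrix} A & B \\ C & D \end{pmatrix}
\begin{pmatrix} y \\ \theta \end{pmatrix},$$

and a system is the right-to-left product of its element matrices. The
engine never applies a trigonometric function to $\theta$; the small-angle
regime is assumed throughout, and the only place a sine appears is the
*reported* numerical aperture $\mathrm{NA} = n \sin\theta_a$.

**Angle and index conventions.** Angles are physical angles (not the
"reduced" $n\theta$ convention), so the refractive index appears only in
interface matrices and in the optical invariant; the determinant of any
element or composition is $n_\text{front}/n_\text{back}$, which every
constructor enforces to $10^{-10}$ and the suite re-checks on random
compositions. Light travels toward $+z$; a radius of curvature is positive
when its center lies after the surface; heights are positive above the
axis. Units are millimetres and radians everywhere, including config files.

From the system matrix the standard closed forms follow: $B = 0$ is the
imaging condition (with $|B| < 10^{-9}$ mm as the floating-point criterion,
chosen because exact conjugates accumulate round-off of order machine
epsilon times path length), $-1/C$ is the back effective focal length,
$-(n_1/n_2)/C$ the front one, and the principal planes sit at
$(n_1/n_2 - D)/C$ and $(1 - A)/C$. The front focal distance is reported as
$-D/C$ (the physical distance at which an input point collimates), which
makes $\mathrm{FFD} - L_{PPf} = f_\text{front}$ hold exactly; an afocal
system ($C = 0$) reports infinite focal quantities rather than raising an
error, since "afocal" is a legitimate answer to a design question.

## Apertures, stops and special rays

Blocking is not linear, so it is handled by tracing, not matrices. Each
element carries a clear diameter checked **at its entrance plane**; the
interior of thick elements is not checked (the practical systems this
models check heights at element planes, and a mid-glass vignetting surface
would anyway require a surface model outside first order). A ray at exactly
the clear radius is transmitted — edge-inclusive, so that the solved
marginal, axial and principal rays, *defined* as grazing a stop edge, trace
as transmitted. Numerically the comparison allows a $10^{-9}$ relative
grace above the radius: the solved grazing rays otherwise fall on either
side of the edge by one ulp depending on the order of arithmetic. The grace
is three orders of magnitude below the $1 + 10^{-6}$ margins used by the
blocking property tests, so it cannot mask a real violation.

The stop solvers use linearity instead of literal scanning: the aperture
stop maximizes $|y_k|/(D_k/2)$ for the unit axial test ray $(0, 1)$, the
field stop does the same with the unit chief ray. Equivalence with the
literal procedure — raising the on-axis angle (or chief-ray height) until a
ray blocks and naming the blocking element — is *tested*, on 200 random
systems against an independently coded scan-and-bisect oracle, not assumed.
Ties between equal ratios resolve toward the smallest $z$, consistent with
naming the *first* lens the stop in a symmetric relay: at an angle just
above threshold, the earlier element physically blocks first. Degenerate
geometries are errors with specific messages: no finite aperture ("no
aperture stop"), the stop conjugate to the object (axial/chief rays
undefined), no aperture limiting the chief ray ("infinite field of view",
detected as a maximal ratio below $10^{-9}$). Objects at infinity are not
supported in stop analysis; every worked system here uses finite
conjugates.

Conjugate-plane search exploits that $B$ varies linearly inside free space:
within each space the zero crossing is solved exactly, and other element
boundaries are checked against the imaging tolerance. This matters for the
Köhler fixture, whose source image falls mid-space, not on a boundary.

## Vignetting by invariant decomposition

For two rays, $I_{12} = n(y_1\theta_2 - y_2\theta_1)$ is conserved through
any paraxial system. On the principal/axial basis (invariant $H$, the
Lagrange invariant, reported positive by orientation convention) any ray
decomposes as $a \cdot \text{principal} + b \cdot \text{axial}$ with

$$a = \frac{n(y\,\theta_a - y_a\theta)}{H}, \qquad
  b = \frac{n(y_p\theta - y\,\theta_p)}{H},$$

the Cramer solution of the $2\times2$ reconstruction system. (A formulation
of these weights as ratios $I_{32}/I_{21}$, $I_{13}/I_{21}$ of pairwise
invariants circulates with an index convention that flips the sign of one
coefficient; the package uses the direct linear solution above, whose
defining property — exact reconstruction, verified to $10^{-9}$ on $10^4$
random bases — is unambiguous.) Both coefficients are conserved along
unblocked traces, which the suite checks plane by plane.

Classification of a traced ensemble: a blocked ray with
$\max(|a|,|b|) > 1$ is outside the design envelope — *expected* blocked; a
blocked ray with $\max(|a|,|b|) \le 1$ was inside the envelope and its
blocking element is **vignetting** the system. The threshold is strict
(`> 1`), so boundary rays count as in-envelope. The reported "vignetting
element" is the one blocking the most vignetted rays, a choice the report
format leaves open when several apertures contribute.

## Ray ensembles

Three generators feed the Monte-Carlo machinery: a deterministic grid fan
(single-count axes collapse to the axis maximum, so a one-point height axis
at $y_\text{max} = 0$ is an on-axis fan), uniform random rays, and
Lambertian random rays with density $\propto \cos\theta$ on
$[-\theta_\text{max}, \theta_\text{max}]$, sampled by inverse CDF
$\theta = \arcsin((2u - 1)\sin\theta_\text{max})$ in the 2D meridional
convention (the named distribution fixes neither the sampling scheme nor
the dimensionality; with a planar engine the meridional law is the
consistent choice). Sampling quality is tested by Kolmogorov–Smirnov at
$\alpha = 0.01$ with $n = 10^5$.

Generators accept an integer seed, restore the global RNG state on exit,
and reproduce bitwise-identical ensembles for identical seeds; passing
`seed = NULL` uses the session RNG stream for deliberately unseeded runs.
Reproducibility is the default-documented practice because every
downstream number (efficiencies, tallies) inherits it. Histograms use
equal-width bins over the observed range, 100 by default; the bin policy is
a free parameter and is exposed.

All rays carry unit weight — no wavelength, polarization or radiometric
($\cos^4$) weighting — so "transmission efficiency" is a ray-count
fraction, not a radiometric throughput.

## Fixtures and the choices behind them

**Confocal detection.** Thin-lens objective $f = 5$ mm with the focal spot
at its front focus, an $f = 100$ relay, then 100/75 and 40/50 4f relays to
the pinhole plane: stage magnifications $-20$, $-0.75$, $-1.25$, product
$-18.75$ at $z = 740$ mm. The optimal pinhole exactly fits the magnified
0.5 µm spot: $18.75 \times 0.5\,\mu m = 9.375\,\mu m$. The defocus sweep
displaces the spot by nanometre offsets, reuses one seeded uniform ensemble
(heights within the spot, angles over the full meridional range) at every
position and pinhole size — so the small/ideal/large pinhole curves are
nested deterministically, not merely within noise — and records the
transmitted fraction.

**Scan path.** 40/75 and 100/100 relays then the objective, modeled as a
focal-plane-to-focal-plane box $[[0, f], [-1/f, 0]]$ stretched over its
physical focus-to-focus length with the back aperture as its only clear
diameter. That is the minimal unit-determinant model consistent with the
catalog parameters of a 60×/1.2 water objective ($f = 3$ mm, 40 mm
focus-to-focus, 7 mm back aperture); it is labelled synthetic. Because the
objective's internal construction is a modeling choice, the scan curve is
asserted only for linearity and zero crossing, not for its absolute span.

**Köhler illumination.** The collector/condenser/objective/tube/eyepiece
train with the lamp at $z = 20/3$ mm and the specimen at $z = 120$ mm. The
lamp position is what makes the layout Köhler: the source images to
$z = 60$ mm, the condenser front focal plane, so the source-to-sample block
has $D = 0$ — each lamp point illuminates the specimen as a parallel bundle
— while $B \ne 0$ (the lamp is never in focus on the specimen) and the
source and sample conjugate sets are disjoint ($\{60, 180, 300\}$ vs
$\{240, 304\}$ mm, minimum separation 4 mm).

**Widefield stop-placement study.** A 50/50 4f relay with lens diameters
$(d_1, d_2)$ and a 10 mm camera. The three qualitative layouts are realized
with $(10, 10)$, $(40, 12)$ and $(16, 40)$. The diameters are free
parameters of the study (only the relative-size regimes are prescribed),
and they were chosen by a design rule, not by trial: a layout is strictly
vignetting-free only if every non-stop aperture clears the full envelope
$|y_p(z)| + |y_a(z)|$ at its plane. For this relay the envelope at the
off-stop lens is 16 mm, so mirrored pairs like $(25, 12)/(12, 25)$ vignette
*both* ways and, being symmetric, transmit identical fractions; $(40, 12)$
and $(16, 40)$ clear the envelope (20 mm and 20 mm apertures' radii exceed
16/2 + margin) and differ in aperture-stop size (12 vs 16 mm), so the
well-placed-stop layout transmits strictly more (0.321 vs 0.241 of the
test ensemble) — the qualitative ordering the study is about.

## Problem sizes

The test suite runs the distributional checks at $n = 10^5$ rays,
stop-solver equivalence on 200 random systems, invariant conservation on
1000 random traces, decomposition reconstruction on $10^4$ random bases,
the three-scenario widefield study on one shared $10^5$-ray ensemble, and
the defocus sweep at $10^4$ rays per position over 11 positions. These
sizes put binomial noise near $1.6\times10^{-3}$ on the calibration
fractions, an order below every margin tested.

## What the synthetic ensembles do not show

The generators emulate idealized sources: spatially and angularly uniform
(or Lambertian) emitters with sharp range cutoffs, perfectly aligned to the
axis, monochromatic in the sense that no chromatic information exists at
all. Passing tests therefore establish the *geometry* of stops, fields and
invariants, and the self-consistency of the Monte-Carlo machinery — they do
not validate performance of a real instrument against diffraction,
aberrations, element tilt or decenter, surface losses, or detector
response, all of which are outside first-order optics and outside this
package's scope (as are curved mirrors in folded geometries, which can be
modeled as unfolded equivalent lenses, and wavelength-dependent index
models).

## Gaussian beams

The complex parameter $1/q = 1/R - i\lambda/(\pi n w^2)$ transforms as
$q' = (Aq + B)/(Cq + D)$ through the same matrices; with the physical-angle
convention the index enters through the width-recovery formula and the
interface matrices, a convention documented here because the $q$/index
bookkeeping is a genuine free choice. Beams are not clipped by apertures
(only rays are), and $Cq + D = 0$ — the beam focused to a point exactly at
the exit plane — is rejected rather than propagated to a non-physical
$q' = \infty$. Resonator eigenmodes and $M^2$ beams are out of scope.
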