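# paraxial

Paraxial ray tracing and aperture analysis for optical system design, aimed
at the instrumentation side of microscopy: checking that a detection path,
scan relay or illumination train actually delivers the field of view,
numerical aperture and throughput it was designed for, before (or after) it
is built on the bench.

## What it computes

In the paraxial approximation (`sin θ ≈ θ`) a ray is the column vector
`(y, θ)` — height above the optical axis in mm, angle in rad — and every
element is a 2×2 ray-transfer matrix

```
M = [ A  B ]        y' = A·y + B·θ
    [ C  D ]        θ' = C·y + D·θ
```

with `det M = n₁/n₂` (physical-angle convention). A system is the ordered
product of its element matrices. From that product the package extracts the
classical closed forms: `B = 0` is the imaging condition (then `A` is the
transverse and `D` the angular magnification), the back effective focal
length is `−1/C`, principal planes sit at `(n₁/n₂ − D)/C` and `(1 − A)/C`,
and Gauss's law `1/dₒ + 1/dᵢ = 1/f` and the thick-lens Lensmaker equation
fall out of the matrix product.

What matrices alone cannot describe is the single most important limitation
of real instruments: finite apertures. `paraxial` traces rays through the
element sequence, blocks them where `|y|` exceeds a clear radius, and from
that derives:

- the **aperture stop** (AS) — the element maximizing `|y(z)| / (D(z)/2)`
  for an on-axis test ray — and the **field stop** (FS), found the same way
  with a chief ray;
- the special rays: **axial** (on-axis, grazing the AS; its angle sets the
  object NA), **marginal**, **chief** (through the AS center) and
  **principal** (grazing the FS; its origin height is half the FOV);
- the **Lagrange invariant** `H = n(y_p θ_a − y_a θ_p)`, conserved at every
  plane and the natural currency of throughput;
- **conjugate planes** (`B = 0` planes, solved exactly inside free spaces);
- Monte-Carlo **transmission efficiency** and intensity histograms for
  uniform or Lambertian ray ensembles;
- a **vignetting diagnosis**: any ray decomposes as
  `a·principal + b·axial` with invariant-ratio coefficients; a blocked ray
  with `max(|a|, |b|) ≤ 1` sits inside the design envelope and should have
  been transmitted — the element that stopped it is vignetting the image.

Gaussian beams ride the same matrices through the complex `q` parameter,
`q' = (Aq + B)/(Cq + D)`.

## Worked example

A 4f relay (f = 50 mm twice) built from two 10 mm lenses with a 10 mm
camera — a deliberately under-sized system:

```r
library(paraxial)
path <- widefield_path(d1 = 10, d2 = 10)
aperture_stop(path)
#> <stop> z = 50 mm, diameter = 10 mm, "First lens" (element 2)
field_stop(path)
#> <stop> z = 150 mm, diameter = 10 mm, "Second lens" (element 4)
cat(sprintf("FOV %g mm | NA %.4f | H %g mm rad\n",
            field_of_view(path), object_na(path), lagrange_invariant(path)))
#> FOV 5 mm | NA 0.0998 | H 0.25 mm rad

ens <- random_uniform_rays(y_max = 5, theta_max = 0.5, n = 1e5, seed = 1)
report_efficiency(path, ens)
#> Efficiency report: Widefield 4f (d1=10, d2=10) (100000 rays)
#>   Aperture stop: z = 50 mm, D = 10 mm First lens
#>   Field stop:    z = 150 mm, D = 10 mm Second lens
#>   FOV 5 mm | NA 0.0998334 | Lagrange H 0.25 mm rad
#>   Transmitted 10040 | expected blocked 87491 | vignetted 2469
#>   Vignetting caused by: Second lens
#>   blocked at First lens: 79966
#>   blocked at Second lens: 9994
```

Reading: the first lens is the aperture stop (NA ≈ 0.1), but the field stop
is the *second lens*, not the camera — so only a 5 mm object field is
imaged, and 2,469 of the 100,000 rays that were inside the design envelope
(`|a|, |b| ≤ 1`) are lost at the second lens: classic vignetting, darkening
the edges of the image. Enlarging the second lens
(`widefield_path(16, 40)`) moves the FS to the camera and the vignetted
count to zero.

Built-in fixtures reproduce standard microscopy layouts:
`clsm_detection_path()` (confocal descanned detection; pinhole-plane
magnification −18.75, optimal pinhole 9.375 µm for a 0.5 µm spot, and
`transmission_vs_defocus()` for the axial response), `clsm_scan_path()`
(polygon-to-sample scan relay), `kohler_path()` (Köhler illumination, whose
source and sample conjugate planes are disjoint) and `widefield_path()`.

## Command line

Systems can be described declaratively in YAML and analyzed with the
`exec/raypath` script:

```sh
raypath stops system.yml --json
raypath mc system.yml --n 100000 --seed 1 --ymax 5 --thetamax 0.5 --json
raypath report system.yml --n 100000 --seed 1 --ymax 5 --thetamax 0.5
raypath example widefield-equal --json
```

See `?read_system_config` for the schema and `?raypath_main` for all
subcommands.

## Limitations

First-order (paraxial) optics only: no diffraction, no aberrations, no
interference, no tilted or decentered elements. Apertures are checked at
element entrance planes; rays are meridional (2D). The objective model is a
focal-to-focal black box, not a lens prescription.
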