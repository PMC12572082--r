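# smartegg

Geometric analysis of avian egg profiles with Smart's contour model and
its measurable modifications.

Smart's model describes an egg outline as an ellipse whose minor
semi-axis is tilted by a "tangential-line" slope, mimicking how the
oviduct deforms an ellipsoid into an ovoid. Writing the egg's length as
*L*, its maximum breadth as *B* and the axial offset of the
maximum-breadth section from mid-length as *w* (pointed end at negative
*x*), every member of the family shares one canonical half-contour

```
y(x) = ( B / (2 sqrt(L^2 - 4 w^2)) + tan(theta) (x - w) / L ) * sqrt(L^2 - 4 x^2)
```

on *x* in \[-L/2, L/2\]. The variants differ only in how the single
shape parameter tan θ is obtained:

| variant | tan θ from | measured parameters |
|---|---|---|
| `SM_r`   | quarter-length radii *r*, *R*: tan θ = (4/√3)(R − r)/L | 5 (L, B, w, r, R) |
| `SM_B0`  | mid-length breadth *B₀* | 4 (L, B, w, B₀) |
| `SM_U`   | hybrid using the pointed radius *r* | 4 (L, B, w, r) |
| `SM_B02` | *B₀* replaced by its ovoid bound | 3 (L, B, w) |
| `SM_r2`  | *r*, *R* replaced by their ovoid bounds | 3 (L, B, w) |
| `SM_MA`  | the Main-Axiom constraint (below) | 3 (L, B, w) |

Here *r* and *R* are the half-breadths at one quarter of the length
from the pointed and blunt ends (x = ∓L/4); for an ellipse
r = R = (√3/4)B.

The **Main Axiom** is the geometric requirement that the drawn contour
actually attain the measured maximum breadth at its measured location:
y(w) = B/2 **and** y′(w) = 0. Only the slope
tan θ = 2BLw / (L² − 4w²)^{3/2} satisfies it (`SM_MA`); the package
quantifies every other variant's violation (`axiom_residual`), derives
the pointed radius a five-parameter egg must have to comply
(`axiom_required_r`), and shows that over the empirical elongation band
w/L ∈ \[0, 0.2\] the Axiom-compatible ratio r/B is confined to
0.27…0.43 (`axiom_r_curve`).

The package also provides closed-form volumes of the contour's solid of
revolution (`volume_parts`), the equal-volume ellipsoid length showing
that an egg cannot keep both its length and its volume while deforming
from an ellipsoid, parameter measurement from digitized outlines
(`measure_profile`), the mean-percentage-error fit criterion
(`egg_epsilon`), model fitting and ranking (`egg_fit`,
`compare_variants`), synthetic pixel-sampled profiles spanning the
parabola-to-ovoid pointed-end continuum (`synth_profile`,
`standard_fixtures`), contour CSV I/O and a CLI (`exec/eggsm`).

## Worked example

Fit every variant to a synthetic pyriform (razorbill-like) egg sampled
at 215 pixel-quantized points:

```r
library(smartegg)
p <- standard_fixtures(seed = 1)$pyriform
compare_variants(p)
```

```
Model-variant comparison (ranked by mean percentage error):
 variant n_params epsilon value_residual slope_residual compliant
    SM_U        4   3.729              0      -2.08e-03     FALSE
    SM_r        5   3.763              0      -6.79e-04     FALSE
   SM_MA        3   3.780              0       5.55e-17      TRUE
  SM_B02        3   4.237              0      -3.68e-02     FALSE
   SM_r2        3   6.238              0      -5.71e-02     FALSE
   SM_B0        4   7.319              0       6.05e-02     FALSE
```

`epsilon` is the mean percentage error between the measured and modelled
half-breadths at the profile's own 215 axial positions; the residual
columns quantify Main-Axiom compliance at the measured breadth section —
`SM_MA` is the only variant that is compliant by construction. Volumes
follow directly from the best fit:

```r
egg_volume(compare_variants(p)$fits[[1]])
```

```
Egg volume: V = 1.98985e+06 (pointed 694067 + blunt 1.29579e+06)
  equal-volume ellipsoid: L_el = 222.485, V_el = 1.98985e+06
```

(cubic pixels here; the fixture's scale of 57 mm / 215 px converts to
mm³). The equal-volume ellipsoid is longer than the egg (L = 215 px),
illustrating the volume-conservation analysis.

The same workflows are scriptable:

```sh
exec/eggsm synth --fixture pyriform --seed 1 --out egg.csv
exec/eggsm evaluate --in egg.csv --json
exec/eggsm axiom --curve --tmax 0.2
```

```
Axiom-compatible r/B over w/L in [0, 0.2] (2001 points):
  min = 0.271721 (0.27), max = 0.433013 (0.43)
```

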