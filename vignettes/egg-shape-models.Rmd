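---
title: "Egg-shape models, the Main Axiom, and how smartegg computes them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egg-shape models, the Main Axiom, and how smartegg computes them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartegg)
```

## The model family

Smart's egg-shape model deforms an ellipse of length $L$ and mid-breadth
$B_0$ by tilting its minor semi-axis with a tangential-line slope
$\tan\theta$:

$$y = \pm\frac{B_0 + 2x\tan\theta}{2L}\sqrt{L^2 - 4x^2}.$$

Because the mid-length breadth $B_0$ is awkward to measure on a real
egg, the model is re-anchored at the *maximum* breadth $B$, attained at
the axial offset $w$ from mid-length, giving the canonical form used
throughout this package:

$$y = \pm\left(\frac{B}{2\sqrt{L^2-4w^2}} +
      \frac{\tan\theta\,(x-w)}{L}\right)\sqrt{L^2-4x^2}
    = \pm\,(P + Q(x-w))\sqrt{L^2-4x^2},$$

with $P = B/(2\sqrt{L^2-4w^2})$ and $Q = \tan\theta/L$. Every variant
passes through $(w, B/2)$ by construction and vanishes at the tips
$x = \pm L/2$. The variants (`SM_VARIANTS`) differ only in the
measurements from which $\tan\theta$ is resolved: the quarter-length
radii $r, R$ (five parameters), the mid-breadth $B_0$ (four), the
pointed radius alone (four, the hybrid `SM_U`), or nothing beyond
$L, B, w$ (three, with $B_0$ or $r,R$ replaced by boundary-shape
ratios, or with $\tan\theta$ fixed by the Main Axiom).

Assumptions worth keeping in view: the egg is a solid of revolution
(left–right symmetric about its long axis); all lengths within one call
share one unit (px or mm); and the admissible parameter space requires
$0 \le w < L/2$, with the empirical band for real eggs being
$w/L \le 0.2$ (values above it only warn, to admit super-elongated
eggs).

### A note on conventions

Two conventions are easy to trip over and are fixed package-wide:

* **Orientation.** The canonical family places the pointed end at
  negative $x$; the classical parabola and ovoid
  (Hügelschäffer) boundary forms place it at positive $x$. Every
  profile carries an explicit orientation tag and the flip
  ($x \mapsto -x$, which swaps the roles of $r$ and $R$) is applied
  during normalization, never implicitly.
* **Breadths versus radii.** $B$ and $B_0$ are full breadths
  (diameters); $r$ and $R$ are half-breadths (radii) at $x = \mp L/4$.
  This is the convention under which the slope formula
  $\tan\theta = (4/\sqrt3)(R-r)/L$ exactly recovers the generating
  slope of a family contour (the identity
  $y(L/4)-y(-L/4) = \sqrt3\,Q L^2/4$), and under which an ellipse has
  $r = R = (\sqrt3/4)B$, matching the boundary-ratio expressions.

## The Main Axiom

A contour formula whose interior maximum does not sit at $(w, B/2)$
redraws the egg with a distorted maximum breadth — the measured $B$ no
longer appears in the drawing, and derived quantities (volume, surface)
inherit the distortion. The Main Axiom demands $y(w) = B/2$ and
$y'(w) = 0$. In the canonical family the value condition is automatic,
so the informative residual is the slope

$$y'(w) = Q\sqrt{L^2-4w^2} - \frac{2Bw}{L^2-4w^2},$$

which vanishes only for
$\tan\theta = 2BLw/(L^2-4w^2)^{3/2}$ (`axiom_tan_theta`, the `SM_MA`
variant). Imposing the same condition on the five-parameter variant
ties its radii together
(`axiom_required_r`), and substituting the universal ovoid expression
for the blunt radius leaves a one-variable curve $r/B$ in $t = w/L$
(`axiom_r_curve`), whose $t\to 0$ limit is $\sqrt3/4$ and whose range
over the empirical band rounds to $0.27\ldots0.43$.

Compliance tolerances are engineering choices (the theory gives exact
zeros): $|y(w)-B/2| \le 10^{-12}B$ and $|y'(w)| \le 10^{-9}$. The
analytic derivative is used throughout; central finite differences with
step $10^{-6}L$ serve only as a cross-check in the tests.

## Boundary shapes and atlases

Across real eggs the pointed end lies between a parabola (lower bound)
and the Hügelschäffer ovoid (upper bound), while the blunt end is
always ovoid. Evaluating those two figures at $x=0$ and $x=\mp L/4$
yields closed-form bounds for $B_0/B$, $r/B$ and $R/B$ as functions of
$t = w/L$ (`ratio_bounds`; the "average" rule is their arithmetic
mean). Sweeping $t$ over $\{0, 0.05, \ldots, 0.20\}$ and feeding a
ratio rule into the four- or five-parameter variants reconstructs the
normalized profile atlases (`egg_atlas`). Their diagnostic summary
shows the geometric defect that motivates the Axiom: for every $t>0$
the contour's maximum exceeds $B/2$ (by $5\times10^{-7}B$ at $t=0.05$
up to $4\times10^{-3}B$ at $t=0.2$) and sits away from $x/L = t$ (drift
$-7\times10^{-4}$ to $-5\times10^{-2}$). The overshoots are small in
absolute terms, which is why they are asserted as strict inequalities
rather than visual claims.

The atlas maximum is located by `stats::optimize` (golden-section with
parabolic interpolation) on the smooth contour; the contour has at most
one interior extremum of interest, so no multi-start is needed.

## Volumes

Rotating the contour about the long axis and integrating $\pi y^2$
over each half gives closed forms in the $(L, B_0, \tan\theta)$ frame
(the frame in which the integrals separate):

$$V_{p,b} = \frac{\pi L}{4}\left(\frac{B_0^2}{3} \mp
  \frac{B_0 L\tan\theta}{4} + \frac{L^2\tan^2\theta}{15}\right),\qquad
  V = \frac{\pi L}{6}\left(B_0^2 + \frac{L^2\tan^2\theta}{5}\right).$$

Callers holding $(L, B, w)$ convert with `b0_from_dims`
($B_0 = BL/\sqrt{L^2-4w^2} - 2w\tan\theta$); `egg_volume` does this
for a model object. $V$ exceeds the volume of the same-length ellipsoid
by exactly $\pi L^3\tan^2\theta/30$, so an egg that keeps the
ellipsoid's volume must be shorter than the ellipsoid — the
equal-volume ellipsoid length is
$L_{el} = L(1 + (L/B_0)^2\tan^2\theta/5) \ge L$. The tests verify the
closed forms against adaptive quadrature (`stats::integrate`,
tolerance $10^{-12}$) to better than $10^{-9}$ relative.

## Measuring digitized profiles

`measure_profile` extracts $(L, B, w, B_0, r, R)$ from an ordered
$(x, y)$ half-profile (closed outlines are folded by averaging $|y|$
of the two branches). The frame is set by the tips: $L$ is the
tip-to-tip span and $x=0$ their midpoint.

$B$ and $w$ come from the interior extremum of a smooth fit rather
than from the discrete maximum. The reason is pixel quantization: near
the maximum the contour's curvature is of order $B/L^2$ (a few
thousandths of a pixel per pixel² at typical resolutions), so rounding
$y$ to whole pixels flattens the maximum into a plateau tens of pixels
wide and any purely local refinement of the discrete argmax can miss
$w$ by a large multiple of its true value. Instead the whole profile
is fit by weighted linear least squares in the two-parameter canonical
family $(A + Cx)\sqrt{L^2-4x^2}$ (the radical weights naturally vanish
at the noisy tips), and $(B, w)$ are read off the fitted curve's
extremum. Averaging over ~400 points reduces the quantization error on
$w$ to well under a pixel. $B_0$, $r$ and $R$ use piecewise-linear
interpolation of the raw points at $x = 0, \mp L/4$, where the contour
is steep enough for local interpolation to be accurate. Sub-resolution
$|w| < 10^{-6}L$ snaps to $0$ (symmetric egg); a negative fitted $w$
means the orientation tag was wrong and the profile is re-flipped, with
a provenance note.

The smoother assumes the canonical family; for profiles outside it
(real eggs, blend fixtures) it is a smoothing device and $(B, w)$ are
those of the best-fitting family member, which for moderate shape
mismatch coincides with the geometric extremum to well within the
sampling resolution.

`refit_tan_theta` provides a whole-profile least-squares slope given
$(L, B, w)$ — with those fixed, the canonical form is linear in $Q$,
so the estimate is closed-form, exact on noiseless family profiles and
unbiased under additive noise.

## The fit criterion and model ranking

`egg_epsilon` implements the mean percentage error
$\varepsilon = (100/k)\sum |v_1 - v_2|/|v_1|$ between measured ($v_1$)
and modelled ($v_2$) half-breadths at the profile's own axial
positions. Points with $|v_1| < 10^{-9}B$ — the tips, where the
relative error is undefined — are excluded, and $k$ counts the points
actually summed (the reported `excluded` keeps the bookkeeping
honest). $\varepsilon$ is scale-invariant and zero exactly when the
model matches every included point.

`compare_variants` measures the profile once, fits each variant from
the shared measurement, and reports $\varepsilon$ together with the
Axiom residuals: a model is judged on the *combination* of accuracy
and geometric compliance, since either alone can be gamed (a compliant
model can fit poorly; an accurate one can distort $B$).

One structural fact deserves emphasis. The canonical family has two
free coefficients at fixed $L$, so matching the value *and* slope of a
family contour at one point determines it completely. Re-measured
geometrically (so that $(w, B/2)$ *is* the contour's extremum), any
family member is therefore reproduced **exactly** by `SM_MA` — on
synthetic within-family profiles the three-parameter Axiom variant
ties or beats everything, and rankings among the near-exact variants
are decided by quantization noise. The extra measurements ($r$, $R$,
$B_0$) pay off in two situations: real eggs, which are not family
members (this is the regime where the five-parameter variant is the
reference standard), and the measure-once workflow in which all
variants consume the same nominal parameter set — there the
information ordering 5-parameter $\le$ 4-parameter $\le$ 3-parameter
holds and is what the tests assert in-family. On the out-of-family
blend fixtures the ranking is computed and reported, not asserted.

## Synthetic profiles

`synth_profile` emulates outlines digitized from photographs: uniform
axial sampling tip-to-tip, optional additive Gaussian noise on $y$
(truncated at zero), and optional pixel quantization that rounds full
breadths $2y$ to whole pixels after a seeded sub-pixel offset
$\delta \sim U(-0.5, 0.5)$, representing the egg's arbitrary placement
on the pixel grid. The offset is what makes independent seeds give
distinct noiseless quantized profiles, as in repeated digitizations.
Defaults are noiseless ($\sigma = 0$) with quantization as the only
error source, since pixel rounding is the dominant error of careful
manual tracing.

`standard_fixtures` fixes three reference shapes with the sampling
structure of the package's test conditions: an ovoid egg at 398 points
($L$ = 398 px), and a conical and a pyriform egg at 215 points
($L$ = 215 px, scaled to 57 mm). Their shapes come from the
parabola-to-ovoid blend continuum (`egg_blend`): pointed side
$(1-\lambda)\,\text{parabola} + \lambda\,\text{ovoid}$, blunt side
always ovoid, continuous at the junction where both components equal
$B/2$. The fixture parameters — $B/L$ of 0.74/0.72/0.66, $w/L$ of
0.05/0.10/0.15, $\lambda$ of 0.90/0.50/0.15 — were chosen once as
realistic values for the three shape classes; the true parameters of
any particular real egg are not published, so the fixtures are
stand-ins for the shape *classes*, not reproductions of specific eggs.
What passing tests on them shows is that the pipeline (generate →
measure → fit → rank) is self-consistent on realistic geometry; it
does not validate the models against real eggs, whose pointed ends
need not lie on the linear blend and whose digitization errors are not
purely quantization.

## Numerical choices and degenerate inputs

* $w = 0$ limits: the $B_0$-based slope formulas have $w$ in a
  denominator; at $w = 0$ they are evaluated as their analytic limits
  (0), with the consistency requirement $B_0 = B$ enforced to 0.5%
  relative — loose enough for pixel-quantized measurements, tight
  enough to catch genuinely inconsistent inputs. The Axiom $r/B$ curve
  at $t = 0$ is likewise the limit $\sqrt3/4$.
* Extreme slopes can drive the linear factor $(P + Q(x-w))$ negative
  near a tip; evaluation returns the signed value rather than clamping,
  so non-physical fits stay visible (`summary.egg_fit` flags them).
* $\varepsilon$ is undefined if every point is excluded (a profile of
  zeros); this errors rather than returning 0.
* Profiles need $\ge 7$ points to place all six parameters; a maximum
  on an endpoint is a degenerate profile (no interior extremum) and
  errors.
* All tolerances above are the package's own choices; the underlying
  identities are exact.

## Problem sizes in the test suite

The property-style tests draw 1000 random admissible parameter sets
for the equation-equivalence and Axiom-compliance checks, 100 for the
quadrature comparison, 20 seeds for the quantized round-trip (398
points each, matching the reference sampling), and 200 replicates for
the noise-unbiasedness check at 200 points — sizes at which the
checked tolerances ($10^{-12}$ relative for identities, 1% for
quantization-limited recovery) are meaningful while the whole suite
runs in seconds.

## Known limitations

* No image processing: inputs begin at digitized points; edge
  detection and tracing are upstream of this package.
* No surface-area formula (no closed form exists in this
  parameterization) and no shell-thickness correction; volumes refer
  to the traced contour.
* The within-family exactness of `SM_MA` under geometric re-measurement
  (above) means synthetic family data cannot discriminate the variants'
  practical accuracy on real eggs; only real, out-of-family contours
  can.
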