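---
title: "Wing morphospaces: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wing morphospaces: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

`wingmorph` measures insect wings with a small set of dimensionless
statistics. This vignette is the package's own account of the underlying
models: what each statistic assumes, which tunable parameters matter and
why their defaults are what they are, what the synthetic-wing generator
does and does not emulate, and where the numerical design was genuinely
open.

## The data model

A `SegmentedWing` holds three mutually consistent views of one wing:

* the **domains**: simple polygons (counterclockwise) that tessellate the
  wing membrane, one per vein-bounded cell;
* the **boundary**: the outer contour (clockwise), derived from the domains
  as the closed loop of ring segments used by exactly one domain;
* the **graph**: a planar geometric graph with a vertex at every distinct
  ring coordinate and an edge per unique ring segment, each flagged as
  margin (`isBoundary`) or internal.

Deriving boundary and graph from the domain rings (after snapping vertices
that coincide to within `snapTol`) guarantees that the three views can
never drift apart: the sum of domain areas equals the boundary area
exactly, and the total edge length equals boundary perimeter plus internal
vein length exactly. The class validity checks enforce orientations, the
area-sum identity (1% relative tolerance, which catches overlapping or
missing domains), and — when the `normalized` flag is set — unit boundary
area to 1e-6.

For network analysis a second granularity exists: `collapseChains()`
contracts all degree-2 vertices, leaving a node at every **vein junction**
and one edge per vein with its polyline (and hence length) preserved. The
corner-level graph is the right object for geometry (lengths, radii,
serialization); the junction graph is the venation *network* in the sense
of vein junctions connected by veins, and `buildAdjacency()` uses it by
default when given a wing. Passing a hand-built `VeinGraph` skips the
collapse, so small didactic graphs (a triangle, a single edge) behave
literally.

## Whole-wing statistics

All wings are first rescaled to unit area (`normalizeArea`), which removes
absolute size — wings correlate with body size, and the interesting signal
is shape. Every downstream statistic is therefore dimensionless and
scale-invariant (tested to 1e-9).

**Normalized perimeter.**
$P = \tilde P / \sqrt{A} - 2\sqrt{\pi}$, where $\tilde P$ is the boundary
perimeter and $A$ the area. The offset $2\sqrt{\pi}$ is the circumference
of the unit-area circle, so a circle scores exactly 0 and the isoperimetric
inequality makes $P \ge 0$ with equality only for the circle. $P$ grows
with elongation and boundary complexity.

**Internal vein length.** The venation skeleton's total length minus the
boundary perimeter, computed on the unit-area wing: $L$ sums what is
*inside* the outline. Summing graph edges (adjacent vertex pairs) rather
than all vertex pairs is the only reading under which subtracting the
perimeter is meaningful; the margin edges contribute exactly $\tilde P$ and
cancel. If numerical noise drives the difference below zero it is clamped
at 0 with a warning. `internalVeinLength` also reports $L/\tilde P$, vein
length per unit outline, a useful density measure because it is insensitive
to the boundary-jaggedness bias discussed below.

**Curvature profile.** The boundary is oriented into its principal-axis
frame, clockwise, with arc length $s = 0$ at the base point (leftmost
point; ties broken by lowest y), so $s = 0.5$ falls near the wing tip for
elongated wings. After uniform arc-length resampling
(`max(1000, 3/window)` points), the curvature at each sample is $1/R$ of
the circle through $p_{i-N}, p_i, p_{i+N}$, with $N$ the sample offset
matching an arc distance of `window` times the perimeter. The circle
through three points is the algebraic (Kåsa) least-squares fit, closed-form
and exact here; collinear triples give curvature 0, not an error. Curvature
is reported as an absolute value and, with `scaled = TRUE`, multiplied by
the perimeter (a circle then reads $2\pi$ everywhere).

The default `window = 0.02` follows the convention of fitting over two
percent of the outline. One property worth knowing: the three-point fit
averages curvature over the window, so sharp peaks are biased low by
$O(\mathrm{window}^2)$ — about 2.6% at the tips of a 2:1 ellipse sampled at
2000 points. Checks against closed-form extrema therefore use a smaller
window (0.005), where the bias is an order of magnitude below a 1%
tolerance; for comparative profiles the default is fine because all wings
carry the same bias.

## Domain statistics and the proximal–distal trace

**Circularity** is the isoperimetric quotient $c = 4\pi a / p^2 \in (0,1]$,
1 only for a circle. The older convention — domain perimeter over the
circumference of the equal-area circle, which is $\ge 1$ — is the monotone
transform $c^{-1/2}$ and is available as `perimeterRatio()`; the quotient
form is used throughout so that morphospace axes run 0 to 1 with 1 =
circular. **Fractional area** is the domain area over the wing area;
across a tessellation the fractional areas sum to 1 (a conservation law the
tests enforce to 1e-6).

The **proximal–distal trace** profiles these two quantities along the
span: the principal (long) axis is divided into `nBins = 25` equal
rectangular bins, each encompassing all domains across that chord. For
polygon $j$ and bin $i$ the overlap fraction $f_{ij}$ (exact
Sutherland–Hodgman slab clipping) defines weights $w_{ij} = f_{ij} a_j$,
and each bin carries the weighted means
$\bar a_i = \sum_j w_{ij} a_j / \sum_j w_{ij}$ and
$\bar c_i = \sum_j w_{ij} c_j / \sum_j w_{ij}$. Because the overlaps are
exact, each polygon's area is fully distributed over bins
($\sum_i f_{ij} = 1$) and computing 50 bins then merging adjacent pairs
reproduces the 25-bin trace to rounding. Both series are smoothed with a
discrete Gaussian of standard deviation `sigma = 2/25` in span units,
reflected at the ends; smoothing is a convex combination, so smoothed
series never leave the raw range. Empty bins carry `NA` and are excluded.

Which end of the long axis is the base? By default the end with the denser
vertex cluster, which matches real wings, where venation concentrates at
the hinge. For synthetic wings with a deliberately tip-dense gradient that
heuristic points the wrong way, so `baseEnd = "left"` / `"right"` overrides
it — the generator defines its base at low x. The optional
`rescalePerimeter` flag multiplies the mean-area series by $\tilde P$ and
is off by default.

## Segmentation

The front-propagation model: bright membrane pixels above `threshold`
(default 0.5) form 4-connected components (speckle below `minSize = 25` px
is dropped); each component is seeded at its most interior point (maximum
distance to the component boundary — deterministic, and for a well-walled
domain the result is independent of where in the component the seed sits,
which the arrival-balance test verifies); all fronts then expand
simultaneously with speed

$$v(I) = \varepsilon + (1 - \varepsilon)\, I^{\gamma},$$

computed as a multi-source shortest-path problem on the pixel grid with a
16-neighbourhood stencil (axis, diagonal and knight moves), whose metric
stays within about 3% of Euclidean. Defaults $\varepsilon = 0.001$,
$\gamma = 4$: the floor must make vein crossings far more expensive than
any membrane path (a 3 px vein at $\varepsilon = 0.001$ costs the
equivalent of 3000 px of membrane, so fronts cannot annex a neighbouring
domain), while remaining positive so noise cannot stall a front; $\gamma$
sharpens the membrane/vein contrast for grayscale images. Knight moves are
priced through the two pixels adjacent to their chord, so they cannot jump
a thin vein.

The propagation domain is the wing silhouette: a morphological closing
(exact Euclidean distance transform, radius `closeRadius = 3` px) of the
membrane mask with hole-filling in between, which bridges the dark veins —
including the wing margin, which touches the dark background. The erosion
radius is `closeRadius - marginTrim`: with `marginTrim` set to half the
margin-vein width the recovered outline falls on the vein centerline; the
conservative default 0 stops at the membrane edge.

Polygonization traces each label's boundary on the pixel-corner lattice,
splits the rings at junction corners (three or more regions meeting,
counting the outside, plus checkerboard self-touch corners), simplifies
every shared chain once in a canonical direction (Douglas–Peucker), and
reassembles, so neighbouring domains carry identical chain coordinates and
the tessellation stays exact. Two sub-pixel refinements act before
simplification: interior boundaries are moved along the local chain normal
to the point where the two fronts' arrival times balance (the
arrival-difference across a boundary pixel pair measures the normal
distance of the true meeting line), and rim corners are moved to the
interpolated zero of the signed silhouette distance field. The default
simplification tolerance is 0.6 px — after refinement the rings are already
sub-pixel smooth, and a 1 px tolerance visibly clips the corners of the
smallest domains.

Known limitation: the recovered outline retains pixel-scale jaggedness, so
perimeter-sensitive statistics ($P$, curvature) measured on pixel-derived
wings are biased upward by a few percent; area-based statistics and
$L/\tilde P$ are robust. For curvature, prefer the resampled mask boundary
or polygon wings.

## The synthetic-wing generator

`generateSyntheticWing` emulates the observed range of venation — a single
circular cell through sparse fly-like tessellations to dense
dragonfly-like wings — with exact ground truth. Seeds are placed by
density-weighted rejection sampling with a Poisson-disk-style minimum
separation of 0.7 of the local target spacing (raw Poisson sampling
produces near-degenerate sliver cells; real wing lattices are locally
regular), relaxed by density-weighted Lloyd sweeps, and turned into clipped
Voronoi cells by half-plane clipping with a distance cutoff. Density
gradients multiply seed intensity base-to-tip (`gradSpan`) and
leading-to-trailing (`gradChord`); a 3x tipward gradient reproduces the
dragonfly pattern of small, circular distal domains. Everything is
deterministic per seed, and the global RNG stream is left untouched.

What the generator does *not* emulate: the longitudinal-vein hierarchy
(all synthetic veins are cell walls of one width class), pigmentation,
image noise and illumination gradients, and wing damage. Passing tests on
synthetic wings therefore validates the geometry and the pipeline
plumbing, not robustness to degraded real scans.

`rasterizeWing` renders membrane at intensity 1, veins (all graph edges,
including the margin) at 0.05, background 0, without anti-aliasing, so
thresholding behaviour is exactly predictable. It refuses tessellations
whose smallest domain would keep fewer than 25 membrane pixels at the
requested scale — below that, domains are not reliably detectable, let
alone measurable. The canonical `fixtureBattery()` (12 pinned-seed specs,
1–500 domains, all three boundary families, tipward and trailing-edge
gradients) was additionally designed so that at a 1200 px raster every
domain stays above the quantization floor for 5%-accurate area recovery;
the dense fixtures use aspect ratio 3.5, close to a large dragonfly
forewing. The segmentation round trip over the full battery (count exact,
every domain area within 5%) runs in about a minute.

## Venation networks

Edge weightings: unweighted 0/1; inverse length $1/L^n$ ($n \in \{1,2\}$,
$L$ the vein polyline length); and vein resistance, treating each vein as a
Poiseuille resistor $L/r^4$. The resistance enters the adjacency matrix as
its reciprocal, the conductance $r^4/L$ — adjacency weights conventionally
encode coupling strength, and a short, thick vein couples its junctions
strongly. Parallel veins between the same junction pair add as parallel
conductances. Radii come from the stored edge radii or from
`interpolateRadii`, inverse-distance-weighted (power 2) interpolation of
sparse (position, radius) measurements evaluated at edge midpoints — the
usual situation is a handful of measured cross-vein radii per wing, not a
per-vein census.

Community structure maximizes Newman modularity
$Q = \frac{1}{2m}\sum_{ij}\left(M_{ij} - \frac{k_i k_j}{2m}\right)
\delta(c_i, c_j)$. Graphs with at most 12 nodes are solved exactly by
enumerating all set partitions (restricted-growth strings, in compiled
code), which anchors the oracle tests; larger graphs use deterministic
fast-greedy agglomeration with the dendrogram cut at maximum $Q$. Returned
partitions are relabelled by first appearance and never score below the
single-community partition ($Q = 0$). When the optimum is degenerate
(ties), which partition is returned depends on enumeration order; ties are
real features of small graphs, and the tests compare $Q$, not labels, in
that case. On synthetic wings the junction-graph community count grows
with venation density (4, 8, 12, 16 communities at 10, 50, 200, 500
domains), the qualitative pattern expected of modularity on denser planar
networks.

## Problem sizes and determinism

Default analysis sizes: curvature profiles at 1000–2000 samples; traces at
25 bins; exhaustive modularity up to 12 nodes (about 4.2 million
partitions, under a second); segmentation validated at 1200 px span with
2–3 px veins, where a 500-domain wing segments in about 7 s. Every stage
is deterministic given its inputs and seeds: fixed image plus seeds give
identical label maps; fixed spec gives identical wings; batch tables are
sorted by wing id and reproduce byte-identically.
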