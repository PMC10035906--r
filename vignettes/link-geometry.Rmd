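---
title: "Shaping links in spatial networks: the geometry behind spatnetviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shaping links in spatial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatnetviz)
```

## The problem

In a spatial network — a brain connectome, a metro system, an airline route
map — the node positions carry physical meaning, so the usual remedy for
visual clutter (moving the nodes apart) is off the table. spatnetviz keeps
every node exactly where the data puts it and instead reshapes the *links*:
each one is lifted out of the plane of its neighbors as a smooth arc whose
geometry depends only on the two endpoints, a shared reference point, and
four dimensionless coefficients.

## The link model

Every link between nodes $S_i$ and $S_j$ (Euclidean distance $d_{ij}$) lies
in the plane through $S_i$, $S_j$ and a virtual reference point $C$, by
default the barycenter of all nodes (optionally shifted along the altitude
axis). With $M$ the chord midpoint, the unit chord direction $u$ and the
unit elevation direction $w$ (the component of $M - C$ orthogonal to the
chord), the curve is two cubic Bezier pieces meeting at a summit $U$ placed
on the $C$–$M$ line on the far side of $M$ from $C$, so arcs bulge *away*
from the interior of the network:

* summit height $h = a_1\, d_{ij}$, i.e. $U = M + a_1 d_{ij} w$;
* summit handles $B_2 = U - d_U u$, $B_2' = U + d_U u$ with
  $d_U = a_2\, d_{ij}/2$ — both perpendicular to the reference line $UM$,
  which keeps the two pieces $C^1$-continuous at the summit;
* node handles at distance $d_S = a_4\, d_{ij}/2$ from each endpoint,
  departing at angle $\alpha = a_3 \pi$ measured in the link plane from the
  chord direction toward the summit side.

The first piece has control polygon $(S_i, B_1, B_2, U)$ and the second
$(U, B_2', B_1', S_j)$. Two free interior control points per piece
determine a *cubic*, not a quadratic: a quadratic piece has a single
interior control point and could not honor independent node and summit
handles, so cubic pieces are the only reading under which all eight presets
are realizable. Each piece is sampled at `samples_per_half + 1` uniform
parameter values (default 32, i.e. 65 points per link — a smoothness/cost
trade-off; raise it for very tight arcs).

Since both heights and handle lengths are proportional to $d_{ij}$, the
construction is translation- and scale-equivariant: moving or uniformly
rescaling the data moves or rescales every curve with it, with $\alpha$
unchanged.

### Presets

`shape_preset()` provides eight curated quadruples $(a_1, a_2, a_3, a_4)$:
Default (0.75, 0.5, 0.38, 0), Bell (0.75, 0.5, 0, 0.5),
Triangle (0.75, 0, 0, 0), Circle (0.5, 0.5, 0.5, 0.5),
Circle2 (0.9, 1, 0.8, 1), Square (0.5, 1, 0.5, 1), Peak (0.75, 0, 0, 1),
and Straight (0, 0, 0, 0), which reproduces plain chords exactly (every
control point collapses onto the segment). Note that with $a_4 = 0$ the
node handle sits *on* the endpoint and $a_3$ becomes inert — the Default
preset is such a case; this is by design and no warning is emitted.

### Choices where the construction was open

* **Angle reference.** $\alpha$ is measured from the chord direction,
  rotating toward the summit: $a_3 = 0$ departs along the chord (Bell,
  Peak), $a_3 = 0.5$ departs perpendicular to it (Circle, Square). The
  alternative (measuring from the horizontal plane) would make the
  silhouette depend on the link's orientation in space, which contradicts
  the intent of a per-link, distance-driven shape.
* **Elevation direction.** $w$ uses the component of $M - C$ orthogonal to
  the chord, not the raw direction, so that $u \perp w$ exactly; $h$ is
  then precisely the point-to-chord height and the perpendicularity of the
  summit handles is well defined.
* **Degenerate frames.** When $C$ is collinear with the chord the in-plane
  elevation is undefined; the frame falls back to the global vertical
  (projected orthogonal to the chord), then to the lateral $x$ axis for
  vertical chords. Every link therefore remains drawable.
* **Contralaterality** is enforced for the full reference direction, not
  only its vertical component: $(U - M)\cdot(M - C) \ge 0$ always.

## Size and color conventions

Link *radius* follows $r = \mathrm{clamp}(s / d_{ij},\; r_{min},\,
r_{max}$): long links are thin, so the short local connections they would
otherwise bury stay visible. Link *color* encodes the connection weight,
min–max normalized **over the retained (post-filter) links** — that is
what a viewer of the filtered picture actually perceives; a constant-weight
network degenerates to the colormap midpoint 0.5. Node degree can be shown
as a bar anchored at the node and pointing radially away from $C$, with
length proportional to the degree — on nodes sampled from a sphere around
$C$ the bars are perpendicular to the surface.

## Filtering

Filters run before any geometry and apply, in the pipeline, in a fixed
order (top-degree nodes, then minimum distance, then density, then ECO) so
a configuration always reproduces the same picture. The ECO criterion keeps
the $K = \mathrm{round}(3N/2)$ strongest links — an average degree of 3 —
with $K$'s multiplier exposed for users who want denser defaults; rounding
is half-up (`floor(1.5N + 0.5)`) so half-integer cases are deterministic
across platforms. Ties at the cut weight are broken by ascending $(i, j)$.
ECO does **not** repair connectivity: typical inputs are connected weighted
networks, and silently adding links back would misrepresent the data, so a
disconnected result only triggers a warning. All filters are idempotent
except `density_filter()` with a *proportional* keep, which is relative to
the current link count and therefore composes (`ceil(p L)` applied twice
keeps shrinking); use an absolute count when idempotence matters.

## Scenes and export

`build_scene()` produces a renderer-agnostic list of colored primitives:
one sphere per node, one primitive per retained link — a polyline in
*line* mode, a tube mesh in *volume* mode (rings swept along the curve,
joined by triangles, capped at both ends). Tube ring orientation is
propagated by parallel transport of the initial normal; a Frenet frame
would flip at inflection points and visibly twist the tube. Volume and line
mode share identical centerlines. The default camera looks at the node
barycenter from 2.5 bounding-sphere radii along the horizontal axis.

`export_gltf()` writes standard glTF 2.0 (embedded-buffer `.gltf` or
binary `.glb`) with one named mesh node per primitive and flat
`baseColorFactor` materials, and no timestamp, so identical scenes produce
byte-identical files. `export_raster()` renders offscreen through the
cairo device using a painter's algorithm (primitives depth-sorted and
drawn back to front) — adequate for opaque flat-colored primitives, with
the known painter's limitation that mutually intersecting triangles have
no correct order. Defaults are 6000 × 3500 pixels at 96 DPI in TIFF, the
tool's standard export size; the DPI lands in both TIFF resolution tags
and in the PNG `pHYs` chunk (where pixel-per-metre quantization makes
96 DPI read back as ≈95.99). The projection is serialized to a
`.view.json` sidecar so a render is reproducible. Labels are never
rasterized. The brain-shaped backdrop of connectome figures is not
bundled; `support = "sphere"`, `"cube"` or any OBJ/ASCII-PLY file covers
that role.

## Synthetic networks

The fixture generators emulate the classes of network the tool is
demonstrated on, so everything is testable without external data:

* `sphere_ba_network(n, m, seed)` — nodes area-uniform on the unit sphere
  (uniform azimuth, uniform cos-polar — no polar clustering);
  preferential-attachment topology grown from `m` seed nodes, each
  arriving node attaching `m` distinct links with probability proportional
  to degree + 1, giving exactly `m (n − m)` links. The attachment process
  is implemented directly (urn sampling with resampling of duplicates) so
  the fixture is self-contained and its link count provable.
* `lattice_network(nx, ny, nz, p_extra, seed)` — integer grid,
  6-neighborhood links plus a fraction of random long-range ones; weight
  is 1 + the link's mean elevation (the offset keeps ground-level links at
  nonzero weight, since weight 0 means "no link").
* `complete_network(n, seed)` — all pairs linked with weight $1/d_{ij}$
  (n = 250 gives the 31125-link stress case), so weight- and
  distance-based filters are both exercised.
* `random_geometric_network(n, radius, seed)` — uniform points in the unit
  cube, linked below the connection radius.

All are deterministic under a fixed seed and leave the caller's RNG state
untouched. What they do *not* emulate: the degree–distance correlations,
community structure and measurement noise of real connectomes or transport
networks — passing tests demonstrate geometric and pipeline correctness,
not that any particular real dataset will render legibly at the defaults.

## Problem sizes used in the tests

The suite exercises geometry properties on thousands of random
configurations (cheap, pure arithmetic), filters on hundreds of random
networks of 3–15 nodes, scene/export round-trips on networks of 8–20
nodes, one 250-node complete-network fixture, and one full-size
6000 × 3500 raster export; these sizes keep the full suite fast while
covering every code path at the exact tolerances stated above.

## Known limitations

* Undirected networks only; asymmetric input is an error (or averaged on
  request), never silently reinterpreted.
* No edge bundling or crossing avoidance — the method trades those for
  speed and predictability; links may still cross.
* The raster renderer has no lighting model (flat per-primitive color) and
  no z-buffer; for publication-quality shaded renders export the glTF and
  use a dedicated renderer.
* Very large dense networks are better drawn in line mode; volume mode
  meshes grow as links × samples × tube sides.
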