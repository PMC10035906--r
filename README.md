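# spatnetviz

Visualization of **spatial networks** — graphs whose nodes occupy fixed
positions in 2D/3D space, such as brain connectomes, city transport
systems, airline routes or sensor grids — for scientists who need readable,
reproducible, scriptable renders without rearranging the nodes.

Classical graph-drawing tools gain readability by moving nodes; in a
spatial network the node positions *are* data. spatnetviz therefore keeps
every node fixed and operates on the links instead. Each link between nodes
$S_i$ and $S_j$ (distance $d_{ij}$) is drawn as two cubic Bézier curves in
the plane through $S_i$, $S_j$ and a reference point $C$ (by default the
barycenter of all nodes), meeting at a summit $U$ on the far side of the
chord midpoint $M$ from $C$. Four coefficients control the silhouette:

| quantity | formula | meaning |
|---|---|---|
| height | $h = a_1\,d_{ij}$ | distance from $M$ to the summit $U$ |
| summit handle | $d_U = a_2\,d_{ij}/2$ | control-point distance at $U$, perpendicular to the line $UM$ |
| node angle | $\alpha = a_3\,\pi$ | departure angle of the curve at each node |
| node handle | $d_S = a_4\,d_{ij}/2$ | control-point distance at $S_i$, $S_j$ |

Long links arch higher and are drawn thinner (radius $\propto 1/d_{ij}$),
so short local structure stays visible underneath; color encodes the link
weight. Eight named presets (`Default`, `Bell`, `Triangle`, `Circle`,
`Circle2`, `Square`, `Peak`, `Straight`) cover the useful corner cases.
Scenes export to **glTF 2.0** (for Blender, three.js, Unity, …) and to
high-resolution **TIFF/PNG** rasters (default 6000 × 3500 px at 96 DPI).

## Worked example

```r
library(spatnetviz)

net <- complete_network(60, seed = 42)    # 60 nodes on a sphere, all pairs
net
#> <spatial_network> 60 nodes, 1770 links

filtered <- eco_filter(net)               # keep the round(3N/2) strongest
#> filter eco(3): links 1770 -> 90, nodes 60 -> 60
#> Warning message:
#> ECO-filtered network is disconnected

inspect_network(filtered)
#>  nodes links    density mean_degree max_degree min_weight max_weight
#>     60    90 0.05084746           3          7   2.156457   15.61201
#>  mean_distance
#>      0.3027521

scene <- build_scene(filtered,
                     shape = shape_preset("Peak"),
                     style = style_config(draw_mode = "volume",
                                          show_degree_bars = TRUE))
scene
#> <scene_model> 209 primitives (cylinder: 59, sphere: 60, tube: 90)

export_gltf(scene, "demo.gltf")
export_raster(scene, raster_spec(1200, 700, 96, "png"), "demo.png")
```

Reading the output: ECO keeps `round(3 * 60 / 2) = 90` links, the target
average degree of 3 showing up directly in `mean_degree`. On this fixture
the weight is `1/distance`, so the strongest links are the short local
ones and the filtered network splits into spatial islands — the warning is
informational; no links are added back. The scene holds one sphere per
node (60), one tube per retained link (90), and one degree cylinder per
connected node (59: one node lost all its links). The `.gltf` file is a
standard scene with named nodes (`node_12`, `link_3_7`, `bar_4`); the PNG
is rendered headless with the camera 2.5 bounding-sphere radii from the
barycenter.

The same pipeline runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "spatnetviz.R", package = "spatnetviz"))')
Rscript $CLI fixtures --kind sphere_ba --n 100 --m 2 --seed 7 --out bundle.json
Rscript $CLI render --bundle bundle.json --preset Circle \
        --gltf scene.gltf --image scene.tiff
Rscript $CLI inspect --bundle bundle.json
```

`render` accepts CSV inputs too (`--coords`, `--adjacency`, optional
`--labels`), with the data-file axis convention `xzy` by default
(`--axis-order xyz` to override), filters
(`--no-eco`, `--density`, `--min-distance`, `--top-k`), shape
(`--preset` or `--shape a1,a2,a3,a4`, mutually exclusive), style
(`--draw-mode volume|line`, `--colormap`, `--degree-bars`,
`--support none|sphere|cube|mesh.obj`) and raster options (`--width`,
`--height`, `--dpi`). A JSON config file (`--config`) provides defaults
that explicit flags override, and every run writes a manifest JSON
recording the resolved parameters and per-filter reports; identical
configurations produce byte-identical artifacts.

### Input formats

* coordinates: headerless CSV, one node per row, three numeric columns in
  `xzy` order (column 2 = depth, column 3 = altitude);
* adjacency: headerless square numeric CSV, symmetric, zero diagonal,
  non-negative (directed networks are not supported);
* labels: optional, one per line;
* or a single JSON bundle: `{"axis_order": "xzy", "coordinates": [[...]],
  "matrix": [[...]], "labels": [...]}` — written by
  `write_network_bundle()`, read by `read_network_bundle()`.

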