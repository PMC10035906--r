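Package: spatnetviz
Title: Geometric Visualization of Spatial Networks with Curved Links
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Renders spatial networks (graphs whose nodes occupy fixed
    positions in 2D/3D space, such as brain connectomes, transport systems
    or airline routes) without moving the nodes. Each link is reshaped as a
    two-piece cubic Bezier curve whose height, handle lengths and departure
    angle are driven by the Euclidean internode distance through four shape
    coefficients, with eight named presets. Includes density filters (ECO
    criterion, explicit density, minimum physical distance, top-degree
    subnetworks), degree glyphs, synthetic fixture networks, a
    renderer-agnostic scene model with line and volume draw modes, export
    to glTF 2.0 scenes and to high-resolution TIFF/PNG rasters, and a
    command-line interface chaining import, filtering, geometry, scene
    assembly and export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    grDevices,
    graphics,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
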