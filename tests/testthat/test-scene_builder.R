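path3 <- function() {
  # 3-node path graph: 1-2-3 along x
  spatial_network(cbind(0:2, 0, 0),
                  matrix(c(0, 1, 0, 1, 0, 3, 0, 3, 0), 3, 3))
}

test_that("scenes contain one sphere per node and one primitive per link", {
  sc <- build_scene(path3(), style = style_config(draw_mode = "line"))
  kinds <- vapply(sc$primitives, `[[`, "", "kind")
  expect_identical(sum(kinds == "sphere"), 3L)
  expect_identical(sum(kinds == "polyline"), 2L)
  expect_identical(length(sc$primitives), 5L)

  scv <- build_scene(path3(), geometry_config(samples_per_half = 32),
                     style = style_config(draw_mode = "volume",
                                          tube_sides = 8))
  kinds <- vapply(scv$primitives, `[[`, "", "kind")
  expect_identical(sum(kinds == "tube"), 2L)
  # 65 polyline points -> 65 rings x 8 vertices, + 2 cap centers
  tube <- scv$primitives[[which(kinds == "tube")[1]]]
  expect_identical(nrow(tube$vertices), 65L * 8L + 2L)
  expect_error(build_scene(path3(),
                           style = style_config(colormap = "nosuchmap")),
               "valid names")
})

test_that("link colors are the colormap at min-max normalized weights", {
  sc <- build_scene(path3(), style = style_config(draw_mode = "line"))
  tags <- vapply(sc$primitives, `[[`, "", "tag")
  w1 <- sc$primitives[[which(tags == "link_1_2")]]$color   # weight 1 -> 0
  w3 <- sc$primitives[[which(tags == "link_2_3")]]$color   # weight 3 -> 1
  expect_equal(w1, map_colors(c(1, 3))[1, ], tolerance = 1e-12)
  expect_equal(w3, map_colors(c(1, 3))[2, ], tolerance = 1e-12)
  # extremes of the ramp itself
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, "viridis"))
  expect_equal(w1, as.numeric(ramp(0) / 255), tolerance = 1e-12)
  expect_equal(w3, as.numeric(ramp(1) / 255), tolerance = 1e-12)
  # constant weights degrade to the colormap midpoint
  const <- map_colors(c(2, 2, 2))
  expect_equal(const[1, ], as.numeric(ramp(0.5) / 255), tolerance = 1e-12)
  expect_true(all(const[1, ] == t(const)))
})

test_that("volume and line modes share identical link centerlines", {
  net <- sphere_ba_network(15, 2, seed = 21)
  geom <- geometry_config(samples_per_half = 8)
  line <- build_scene(net, geom, style = style_config(draw_mode = "line"))
  vol <- build_scene(net, geom, style = style_config(draw_mode = "volume",
                                                     tube_sides = 6))
  tags <- vapply(line$primitives, `[[`, "", "tag")
  for (tag in grep("^link_", tags, value = TRUE)) {
    pl <- line$primitives[[which(tags == tag)]]$vertices
    tube <- vol$primitives[[
      which(vapply(vol$primitives, `[[`, "", "tag") == tag)]]$vertices
    sides <- 6
    rings <- matrix(0, nrow(pl), 3)
    for (k in seq_len(nrow(pl)))
      rings[k, ] <- colMeans(tube[(k - 1) * sides + seq_len(sides), ])
    expect_equal(rings, unname(pl), tolerance = 1e-9)
  }
})

test_that("scene assembly is deterministic", {
  net <- sphere_ba_network(10, 2, seed = 5)
  s1 <- build_scene(net, style = style_config(show_degree_bars = TRUE))
  s2 <- build_scene(net, style = style_config(show_degree_bars = TRUE))
  expect_identical(s1, s2)
})

test_that("tube meshes have the predicted size and constant ring radius", {
  # straight 2-point tube, 4 sides: 8 ring vertices + 2 caps, 16 triangles
  m <- tube_mesh(rbind(c(0, 0, 0), c(0, 0, 2)), radius = 0.5, sides = 4)
  expect_identical(nrow(m$vertices), 10L)
  expect_identical(nrow(m$faces), 16L)
  expect_true(all(m$faces >= 1 & m$faces <= nrow(m$vertices)))
  # ring vertices sit exactly at the radius from their centerline point
  expect_equal(sqrt(rowSums(m$vertices[1:4, 1:2]^2)), rep(0.5, 4),
               tolerance = 1e-12)

  # curved path: every ring stays circular with the input radius
  t <- seq(0, pi, length.out = 20)
  arc <- cbind(cos(t), sin(t), 0)
  ma <- tube_mesh(arc, radius = 0.1, sides = 8)
  for (k in seq_len(20)) {
    ring <- ma$vertices[(k - 1) * 8 + 1:8, ]
    r <- sqrt(rowSums(sweep(ring, 2, arc[k, ])^2))
    expect_equal(r, rep(0.1, 8), tolerance = 1e-9)
  }
  # duplicate points are merged; a degenerate polyline is an error
  md <- tube_mesh(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)), 0.2, 5)
  expect_identical(nrow(md$vertices), 2L * 5L + 2L)
  expect_error(tube_mesh(rbind(c(1, 1, 1)), 0.2, 5), "at least 2")
  expect_error(tube_mesh(rbind(c(1, 1, 1), c(1, 1, 1)), 0.2, 5),
               "at least 2")
})

test_that("support primitives are unit solids under scale-rotate-translate", {
  cube <- support_primitive("cube", list(scale = 2, rotation = c(0, 0, 0),
                                         translation = c(0, 0, 0)))
  expect_true(all(abs(cube$vertices) == 2))
  expect_identical(nrow(cube$faces), 12L)

  sph <- support_primitive("sphere")
  expect_equal(sqrt(rowSums(sph$vertices^2)),
               rep(1, nrow(sph$vertices)), tolerance = 1e-9)

  ident <- support_primitive("cube")
  moved <- support_primitive("cube", list(translation = c(1, 2, 3)))
  expect_equal(moved$vertices, sweep(ident$vertices, 2, -c(1, 2, 3)))

  expect_error(support_primitive("/nonexistent/mesh.obj"), "cannot read")
})

test_that("OBJ and ASCII PLY support meshes load with correct counts", {
  obj <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("# tetrahedron", "v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f 1 2 3", "f 1 2 4", "f 1 3 4", "f 2 3 4"), obj)
  m <- support_primitive(obj)
  expect_identical(dim(m$vertices), c(4L, 3L))
  expect_identical(nrow(m$faces), 4L)

  ply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), ply)
  mp <- support_primitive(ply)
  expect_identical(dim(mp$vertices), c(3L, 3L))
  expect_identical(unname(mp$faces), rbind(c(1L, 2L, 3L)))
})

test_that("the default camera looks at the barycenter from 2.5 radii away", {
  net <- sphere_ba_network(25, 2, seed = 33)
  sc <- build_scene(net, style = style_config(draw_mode = "line"))
  ctr <- barycenter(net$coords)
  rad <- max(sqrt(rowSums(sweep(net$coords, 2, ctr)^2)))
  expect_equal(sc$camera$look_at, ctr, ignore_attr = TRUE)
  expect_equal(sc$camera$position - ctr, c(2.5 * rad, 0, 0),
               ignore_attr = TRUE)
  expect_identical(sc$camera$up, c(0, 1, 0))
})
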