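#' Style configuration for scene assembly
#'
#' @param draw_mode `"volume"` (links as tube meshes built from adjacent
#'   cylindrical segments; the default) or `"line"` (links as thin
#'   polylines, rasterized at 1 px — far cheaper for large networks).
#' @param colormap palette name for link colors, any palette known to
#'   [grDevices::hcl.colors()] (default `"viridis"`).
#' @param node_radius sphere radius for nodes; `NULL` means 2\% of the
#'   network's bounding-sphere radius.
#' @param node_color RGB triple in \[0, 1\] for node spheres.
#' @param link_radius_scale,link_radius_min,link_radius_max parameters of
#'   the distance-dependent link radius law `clamp(scale / d, min, max)`
#'   (see [link_radius()]); `NULL` picks values proportional to the
#'   bounding-sphere radius.
#' @param background_color RGB triple in \[0, 1\].
#' @param show_degree_bars append one cylinder per node, pointing away from
#'   the reference point, with height `degree_bar_scale * degree`.
#' @param degree_bar_scale bar length per unit degree; `NULL` means 1\% of
#'   the bounding-sphere radius.
#' @param support one of `"none"`, `"sphere"`, `"cube"`, or a path to an
#'   OBJ/PLY mesh file, added to the scene as a backdrop solid.
#' @param support_transform list with `scale` (scalar or 3-vector),
#'   `rotation` (XYZ Euler angles, radians) and `translation` (3-vector),
#'   applied in that order to the unit support primitive.
#' @param support_color RGB triple in \[0, 1\].
#' @param tube_sides number of vertices per tube ring (>= 3, default 8).
#' @param sphere_segments longitudinal resolution of node spheres.
#' @return an object of class `style_config`.
#' @export
style_config <- function(draw_mode = c("volume", "line"),
                         colormap = "viridis",
                         node_radius = NULL,
                         node_color = c(0.9, 0.9, 0.9),
                         link_radius_scale = NULL,
                         link_radius_min = NULL,
                         link_radius_max = NULL,
                         background_color = c(0, 0, 0),
                         show_degree_bars = FALSE,
                         degree_bar_scale = NULL,
                         support = "none",
                         support_transform = list(scale = 1,
                                                  rotation = c(0, 0, 0),
                                                  translation = c(0, 0, 0)),
                         support_color = c(1, 1, 0),
                         tube_sides = 8L,
                         sphere_segments = 12L) {
  draw_mode <- match.arg(draw_mode)
  tube_sides <- as.integer(tube_sides)
  if (is.na(tube_sides) || tube_sides < 3L)
    stop("tube_sides must be an integer >= 3", call. = FALSE)
  for (r in list(node_radius, link_radius_scale, link_radius_min,
                 link_radius_max, degree_bar_scale))
    if (!is.null(r) && (!is.finite(r) || r <= 0))
      stop("radii and scales must be positive", call. = FALSE)
  for (col in list(node_color, background_color, support_color))
    if (length(col) != 3L || any(col < 0) || any(col > 1))
      stop("colors must be RGB triples in [0, 1]", call. = FALSE)
  structure(list(draw_mode = draw_mode, colormap = colormap,
                 node_radius = node_radius, node_color = node_color,
                 link_radius_scale = link_radius_scale,
                 link_radius_min = link_radius_min,
                 link_radius_max = link_radius_max,
                 background_color = background_color,
                 show_degree_bars = show_degree_bars,
                 degree_bar_scale = degree_bar_scale,
                 support = support, support_transform = support_transform,
                 support_color = support_color, tube_sides = tube_sides,
                 sphere_segments = as.integer(sphere_segments)),
            class = "style_config")
}

#' Map scalars to colormap RGB
#'
#' Min-max normalizes `values` to \[0, 1\] and looks colors up in an
#' [grDevices::hcl.colors()] palette. A constant vector (degenerate
#' normalization) maps every value to the colormap midpoint 0.5.
#'
#' @param values numeric vector.
#' @param palette palette name; unknown names raise an error listing the
#'   valid ones.
#' @return a `length(values)` x 3 matrix of RGB in \[0, 1\].
#' @export
map_colors <- function(values, palette = "viridis") {
  ok <- tolower(palette) %in% tolower(grDevices::hcl.pals())
  if (!ok)
    stop("unknown colormap ", deparse(palette), "; valid names: ",
         paste(grDevices::hcl.pals(), collapse = ", "), call. = FALSE)
  rng <- range(values)
  t <- if (rng[2] > rng[1]) (values - rng[1]) / (rng[2] - rng[1])
       else rep(0.5, length(values))
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256L, palette))
  ramp(t) / 255
}

new_primitive <- function(kind, vertices, faces = NULL, color, tag) {
  list(kind = kind, vertices = vertices, faces = faces,
       color = as.numeric(color), tag = tag)
}

#' UV sphere mesh
#'
#' @param center 3-vector, @param radius positive length.
#' @param segments longitudes (>= 3), `rings` latitudes (>= 2).
#' @param rings latitude bands.
#' @return list with `vertices` (V x 3) and `faces` (F x 3, 1-based).
#' @keywords internal
sphere_mesh <- function(center, radius, segments = 12L, rings = 8L) {
  segments <- max(3L, as.integer(segments))
  rings <- max(2L, as.integer(rings))
  # pole, interior rings, pole
  verts <- rbind(c(0, radius, 0))
  for (r in seq_len(rings - 1L)) {
    phi <- pi * r / rings
    for (s in seq_len(segments) - 1L) {
      th <- 2 * pi * s / segments
      verts <- rbind(verts, radius * c(sin(phi) * cos(th), cos(phi),
                                       sin(phi) * sin(th)))
    }
  }
  verts <- rbind(verts, c(0, -radius, 0))
  nv <- nrow(verts)
  ring_start <- function(r) 2L + (r - 1L) * segments
  faces <- list()
  for (s in seq_len(segments)) {
    s2 <- s %% segments + 1L
    faces[[length(faces) + 1L]] <- c(1L, ring_start(1L) + s2 - 1L,
                                     ring_start(1L) + s - 1L)
    faces[[length(faces) + 1L]] <- c(nv, ring_start(rings - 1L) + s - 1L,
                                     ring_start(rings - 1L) + s2 - 1L)
  }
  for (r in seq_len(rings - 2L)) {
    a <- ring_start(r); b <- ring_start(r + 1L)
    for (s in seq_len(segments)) {
      s2 <- s %% segments + 1L
      faces[[length(faces) + 1L]] <- c(a + s - 1L, a + s2 - 1L, b + s2 - 1L)
      faces[[length(faces) + 1L]] <- c(a + s - 1L, b + s2 - 1L, b + s - 1L)
    }
  }
  list(vertices = sweep(verts, 2L, -as.numeric(center)),
       faces = do.call(rbind, faces))
}

# parallel-transport an initial normal along the polyline tangents
transport_frames <- function(points) {
  n <- nrow(points)
  tangents <- matrix(0, n, 3)
  seg <- diff(points)
  seg <- seg / sqrt(rowSums(seg^2))
  tangents[1L, ] <- seg[1L, ]
  tangents[n, ] <- seg[n - 1L, ]
  if (n > 2L) for (k in 2L:(n - 1L)) {
    t_mid <- seg[k - 1L, ] + seg[k, ]
    nt <- vnorm(t_mid)
    tangents[k, ] <- if (nt > 1e-12) t_mid / nt else seg[k - 1L, ]
  }
  normals <- matrix(0, n, 3)
  # initial normal: any direction orthogonal to the first tangent
  t1 <- tangents[1L, ]
  ref <- if (abs(t1[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  n0 <- ref - sum(ref * t1) * t1
  normals[1L, ] <- n0 / vnorm(n0)
  if (n > 1L) for (k in 2L:n) {
    prev <- normals[k - 1L, ]
    tk <- tangents[k, ]
    cand <- prev - sum(prev * tk) * tk
    nc <- vnorm(cand)
    if (nc < 1e-12) {               # near-reversal: rebuild from reference
      ref <- if (abs(tk[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
      cand <- ref - sum(ref * tk) * tk
      nc <- vnorm(cand)
    }
    normals[k, ] <- cand / nc
  }
  list(tangents = tangents, normals = normals)
}

#' Tube mesh around a polyline
#'
#' Sweeps a circle of `sides` vertices along the polyline: one ring per
#' point, rings joined by quads split into triangles, both ends closed with
#' a cap fan around a center vertex. Ring orientation is propagated by
#' parallel transport of the initial normal, which avoids the twisting that
#' Frenet frames exhibit at inflection points. Consecutive duplicate points
#' are merged before meshing.
#'
#' @param polyline P x 3 matrix of points along the centerline (P >= 2
#'   after duplicate merging).
#' @param radius tube radius (> 0).
#' @param sides ring vertex count (>= 3).
#' @return list with `vertices` ((P * sides + 2) x 3) and `faces`
#'   (triangles, 1-based indices).
#' @export
tube_mesh <- function(polyline, radius, sides = 8L) {
  polyline <- as.matrix(polyline)
  sides <- as.integer(sides)
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0",
                                              call. = FALSE)
  if (is.na(sides) || sides < 3L) stop("sides must be an integer >= 3",
                                       call. = FALSE)
  if (nrow(polyline) >= 2L) {
    keep <- c(TRUE, rowSums(abs(diff(polyline))) > 1e-12)
    polyline <- polyline[keep, , drop = FALSE]
  }
  p <- nrow(polyline)
  if (p < 2L)
    stop("polyline must contain at least 2 distinct points", call. = FALSE)
  fr <- transport_frames(polyline)
  angles <- 2 * pi * (seq_len(sides) - 1L) / sides
  verts <- matrix(0, p * sides + 2L, 3L)
  for (k in seq_len(p)) {
    nk <- fr$normals[k, ]
    bk <- c(fr$tangents[k, 2] * nk[3] - fr$tangents[k, 3] * nk[2],
            fr$tangents[k, 3] * nk[1] - fr$tangents[k, 1] * nk[3],
            fr$tangents[k, 1] * nk[2] - fr$tangents[k, 2] * nk[1])
    ring <- outer(cos(angles), nk) + outer(sin(angles), bk)
    verts[(k - 1L) * sides + seq_len(sides), ] <-
      sweep(radius * ring, 2L, -polyline[k, ])
  }
  cap1 <- p * sides + 1L
  cap2 <- p * sides + 2L
  verts[cap1, ] <- polyline[1L, ]
  verts[cap2, ] <- polyline[p, ]
  faces <- list()
  for (k in seq_len(p - 1L)) {
    a <- (k - 1L) * sides
    b <- k * sides
    for (s in seq_len(sides)) {
      s2 <- s %% sides + 1L
      faces[[length(faces) + 1L]] <- c(a + s, a + s2, b + s2)
      faces[[length(faces) + 1L]] <- c(a + s, b + s2, b + s)
    }
  }
  for (s in seq_len(sides)) {
    s2 <- s %% sides + 1L
    faces[[length(faces) + 1L]] <- c(cap1, s2, s)
    last <- (p - 1L) * sides
    faces[[length(faces) + 1L]] <- c(cap2, last + s, last + s2)
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  dimnames(v) <- NULL
  # 12 triangles, outward-facing
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z-  (v[,3] = -1 has rows 1:4)
             c(5, 6, 8), c(5, 8, 7),   # z+
             c(1, 2, 6), c(1, 6, 5),   # y-
             c(3, 7, 8), c(3, 8, 4),   # y+
             c(1, 5, 7), c(1, 7, 3),   # x-
             c(2, 4, 8), c(2, 8, 6))   # x+
  list(vertices = v, faces = f)
}

euler_rotation <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

read_mesh_file <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") read_obj(path)
  else if (ext == "ply") read_ply_ascii(path)
  else stop("unsupported mesh format \"", ext, "\" (use OBJ or ASCII PLY)",
            call. = FALSE)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl))
    stop("OBJ file ", path, " has no vertices or faces", call. = FALSE)
  verts <- t(vapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                    function(x) as.numeric(x[1:3]), numeric(3)))
  faces <- lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    idx <- as.integer(vapply(strsplit(x, "/", fixed = TRUE), `[[`, "", 1L))
    # fan-triangulate polygons
    if (length(idx) < 3L) stop("OBJ face with fewer than 3 vertices",
                               call. = FALSE)
    cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  })
  list(vertices = verts, faces = do.call(rbind, faces))
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[[1L]]) != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY file ", path, " has no end_header",
                        call. = FALSE)
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported: ", path, call. = FALSE)
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", header, value = TRUE)[1L]))
  body <- lines[(endh + 1L):length(lines)]
  verts <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                    function(x) as.numeric(x[1:3]), numeric(3)))
  faces <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                  function(x) {
    idx <- as.integer(x[-1L]) + 1L      # PLY indices are 0-based
    cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  })
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Support solid for a scene
#'
#' Builds the backdrop object placed under or around the network: a unit
#' sphere, a unit cube (corners at ±1), or a user mesh loaded from an OBJ
#' or ASCII PLY file. The transform is applied as scale, then rotation
#' (XYZ Euler), then translation.
#'
#' @param kind `"sphere"`, `"cube"`, or a mesh file path.
#' @param transform list with `scale`, `rotation`, `translation` (see
#'   [style_config()]).
#' @return list with `vertices` and `faces`.
#' @export
support_primitive <- function(kind,
                              transform = list(scale = 1,
                                               rotation = c(0, 0, 0),
                                               translation = c(0, 0, 0))) {
  mesh <- if (identical(kind, "sphere"))
    sphere_mesh(c(0, 0, 0), 1, segments = 24L, rings = 16L)
  else if (identical(kind, "cube")) unit_cube_mesh()
  else read_mesh_file(kind)
  s <- transform$scale %||% 1
  if (length(s) == 1L) s <- rep(s, 3L)
  v <- sweep(mesh$vertices, 2L, s, `*`)
  rot <- transform$rotation %||% c(0, 0, 0)
  if (any(rot != 0)) v <- v %*% t(euler_rotation(rot))
  tr <- transform$translation %||% c(0, 0, 0)
  v <- sweep(v, 2L, -as.numeric(tr))
  list(vertices = v, faces = mesh$faces)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bounding_sphere <- function(coords) {
  ctr <- barycenter(coords)
  list(center = ctr,
       radius = max(sqrt(rowSums(sweep(coords, 2L, ctr)^2)), 1e-12))
}

#' Assemble a renderer-agnostic scene
#'
#' Turns a (typically filtered) network into an ordered list of colored
#' primitives plus a camera: one sphere per node at its fixed coordinate,
#' one link primitive per retained link — a polyline in `"line"` mode, a
#' tube mesh in `"volume"` mode — with color looked up in the colormap from
#' the min-max normalized weight over the *retained* links, optional degree
#' bars, and an optional support solid. Link radii follow the inverse-
#' distance law of [link_radius()]. The default camera looks at the node
#' barycenter from 2.5 bounding-sphere radii away along the horizontal x
#' axis, with the vertical y axis up. Scene assembly is fully
#' deterministic: identical inputs give identical scenes.
#'
#' @param net a non-empty `spatial_network` (filter it first; no filtering
#'   happens here).
#' @param geom a [geometry_config()]; its `reference_point` (default: the
#'   barycenter) plus `altitude_offset` give the reference point C shared
#'   by every link curve and degree bar.
#' @param shape a [shape_params()] or preset.
#' @param style a [style_config()].
#' @return an object of class `scene_model`: list with `primitives` (each
#'   with `kind`, `vertices`, optional `faces`, `color`, `tag`), `camera`
#'   (`position`, `look_at`, `up`), `background`, and bookkeeping counts.
#' @export
build_scene <- function(net, geom = geometry_config(),
                        shape = shape_preset("Default"),
                        style = style_config()) {
  stopifnot(inherits(net, "spatial_network"))
  if (n_nodes(net) < 1L) stop("empty network", call. = FALSE)
  bs <- bounding_sphere(net$coords)
  node_r <- style$node_radius %||% (0.02 * bs$radius)
  bar_scale <- style$degree_bar_scale %||% (0.01 * bs$radius)
  r_scale <- style$link_radius_scale %||% (0.02 * bs$radius^2)
  r_min <- style$link_radius_min %||% (0.002 * bs$radius)
  r_max <- style$link_radius_max %||% (0.05 * bs$radius)

  cpt <- geom$reference_point %||% barycenter(net$coords)
  cpt <- cpt + c(0, geom$altitude_offset, 0)

  prims <- list()
  for (v in seq_len(n_nodes(net))) {
    m <- sphere_mesh(net$coords[v, ], node_r,
                     segments = style$sphere_segments,
                     rings = max(2L, style$sphere_segments %/% 2L))
    prims[[length(prims) + 1L]] <- new_primitive(
      "sphere", m$vertices, m$faces, style$node_color, paste0("node_", v))
  }

  lt <- link_table(net)
  if (nrow(lt)) {
    cols <- map_colors(lt$weight, style$colormap)
    for (r in seq_len(nrow(lt))) {
      curve <- link_path(net$coords[lt$i[r], ], net$coords[lt$j[r], ], cpt,
                         shape, geom$samples_per_half,
                         weight = lt$weight[r])
      rad <- link_radius(curve$d, r_scale, r_min, r_max)
      tag <- paste0("link_", lt$i[r], "_", lt$j[r])
      prims[[length(prims) + 1L]] <-
        if (style$draw_mode == "line")
          new_primitive("polyline", curve$polyline, NULL, cols[r, ], tag)
        else {
          m <- tube_mesh(curve$polyline, rad, style$tube_sides)
          new_primitive("tube", m$vertices, m$faces, cols[r, ], tag)
        }
    }
  }

  if (isTRUE(style$show_degree_bars)) {
    deg <- node_degrees(net)
    for (v in seq_len(n_nodes(net))) {
      bar <- degree_bar(net$coords[v, ], cpt, deg[v], bar_scale)
      if (is.null(bar)) next
      m <- tube_mesh(rbind(bar$base, bar$tip), node_r * 0.3,
                     max(6L, style$tube_sides))
      prims[[length(prims) + 1L]] <-
        new_primitive("cylinder", m$vertices, m$faces, style$node_color,
                      paste0("bar_", v))
    }
  }

  if (!identical(style$support, "none")) {
    m <- support_primitive(style$support, style$support_transform)
    prims[[length(prims) + 1L]] <-
      new_primitive("support-mesh", m$vertices, m$faces,
                    style$support_color, "support")
  }

  structure(list(
    primitives = prims,
    camera = list(position = bs$center + c(2.5 * bs$radius, 0, 0),
                  look_at = bs$center, up = c(0, 1, 0)),
    background = style$background_color,
    n_nodes = n_nodes(net), n_links = nrow(lt)),
    class = "scene_model")
}

#' @export
print.scene_model <- function(x, ...) {
  kinds <- vapply(x$primitives, `[[`, "", "kind")
  cat("<scene_model> ", length(x$primitives), " primitives (",
      paste(sprintf("%s: %d", names(table(kinds)), table(kinds)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}
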