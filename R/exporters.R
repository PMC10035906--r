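#' Raster export specification
#'
#' Defaults follow the tool's standard export: a 6000 x 3500 pixel TIFF at
#' 96 DPI. Both dimensions and DPI are configurable; PNG is available as a
#' lighter alternative.
#'
#' @param width,height pixel dimensions (>= 1).
#' @param dpi resolution metadata written into the file (> 0).
#' @param format `"tiff"` or `"png"`.
#' @return an object of class `raster_spec`.
#' @export
raster_spec <- function(width = 6000L, height = 3500L, dpi = 96,
                        format = c("tiff", "png")) {
  format <- match.arg(format)
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("width and height must be positive integers", call. = FALSE)
  if (!is.finite(dpi) || dpi <= 0) stop("dpi must be > 0", call. = FALSE)
  structure(list(width = width, height = height, dpi = dpi, format = format),
            class = "raster_spec")
}

rgb_hex <- function(col) grDevices::rgb(col[1], col[2], col[3])

# ---- glTF 2.0 -------------------------------------------------------------

pack_floats <- function(x) writeBin(as.numeric(x), raw(), size = 4L,
                                    endian = "little")
pack_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                    endian = "little")

# round-trip doubles through float32 so accessor min/max match the buffer
as_float32 <- function(x) readBin(pack_floats(x), "numeric", n = length(x),
                                  size = 4L, endian = "little")

#' Export a scene to glTF 2.0
#'
#' Writes the scene as a standard glTF 2.0 asset with a single embedded
#' (base64 data-URI) buffer, or as binary `.glb`. Each scene primitive
#' becomes one mesh attached to one named node (`node_12`, `link_3_7`,
#' `bar_4`, `support`); triangle meshes use mode `TRIANGLES` with uint32
#' indices, polylines use mode `LINE_STRIP`. Per-primitive flat color is
#' stored as the material `baseColorFactor`. The asset contains no
#' timestamp, so identical scenes export to byte-identical files.
#'
#' @param scene a [build_scene()] result.
#' @param path output path; extension `.glb` selects the binary container.
#' @return `path`, invisibly.
#' @export
export_gltf <- function(scene, path) {
  stopifnot(inherits(scene, "scene_model"))
  if (!length(scene$primitives)) stop("empty scene", call. = FALSE)

  buffer <- raw()
  views <- list(); accessors <- list(); meshes <- list()
  nodes <- list(); materials <- list()

  add_view <- function(data, target = NULL) {
    off <- length(buffer)
    buffer <<- c(buffer, data)
    v <- list(buffer = 0L, byteOffset = off, byteLength = length(data))
    if (!is.null(target)) v$target <- target
    views[[length(views) + 1L]] <<- v
    length(views) - 1L
  }

  for (k in seq_along(scene$primitives)) {
    p <- scene$primitives[[k]]
    verts <- as_float32(t(p$vertices))      # row-major xyz triplets
    vview <- add_view(pack_floats(verts), target = 34962L)
    vm <- matrix(verts, ncol = 3L, byrow = TRUE)
    accessors[[length(accessors) + 1L]] <- list(
      bufferView = vview, componentType = 5126L, count = nrow(p$vertices),
      type = "VEC3", min = apply(vm, 2L, min), max = apply(vm, 2L, max))
    pos_acc <- length(accessors) - 1L

    materials[[length(materials) + 1L]] <- list(
      pbrMetallicRoughness = list(
        baseColorFactor = c(round(p$color, 6L), 1),
        metallicFactor = 0, roughnessFactor = 0.9),
      doubleSided = TRUE)
    mat <- length(materials) - 1L

    prim <- list(attributes = list(POSITION = pos_acc), material = mat)
    if (!is.null(p$faces)) {
      idx <- as.integer(t(p$faces)) - 1L
      iview <- add_view(pack_uint32(idx), target = 34963L)
      accessors[[length(accessors) + 1L]] <- list(
        bufferView = iview, componentType = 5125L, count = length(idx),
        type = "SCALAR")
      prim$indices <- length(accessors) - 1L
      prim$mode <- 4L                       # TRIANGLES
    } else {
      prim$mode <- 3L                       # LINE_STRIP
    }
    meshes[[length(meshes) + 1L]] <- list(primitives = list(prim),
                                          name = p$tag)
    nodes[[length(nodes) + 1L]] <- list(mesh = length(meshes) - 1L,
                                        name = p$tag)
  }

  gltf <- list(
    asset = list(version = "2.0", generator = "spatnetviz"),
    scene = 0L,
    scenes = list(list(nodes = I(seq_along(nodes) - 1L))),
    nodes = nodes,
    meshes = meshes,
    materials = materials,
    accessors = accessors,
    bufferViews = views,
    extras = list(camera = scene$camera, background = scene$background)
  )

  if (tolower(tools::file_ext(path)) == "glb") {
    gltf$buffers <- list(list(byteLength = length(buffer)))
    json <- jsonlite::toJSON(gltf, auto_unbox = TRUE, digits = NA)
    jraw <- charToRaw(json)
    pad <- function(r, fill) c(r, rep(fill, (4L - length(r) %% 4L) %% 4L))
    jraw <- pad(jraw, charToRaw(" "))
    braw <- pad(buffer, as.raw(0L))
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(c(0x46546C67L, 2L, 28L + length(jraw) + length(braw)), con,
             size = 4L, endian = "little")
    writeBin(c(length(jraw), 0x4E4F534AL), con, size = 4L, endian = "little")
    writeBin(jraw, con)
    writeBin(c(length(braw), 0x004E4942L), con, size = 4L, endian = "little")
    writeBin(braw, con)
  } else {
    gltf$buffers <- list(list(
      byteLength = length(buffer),
      uri = paste0("data:application/octet-stream;base64,",
                   jsonlite::base64_enc(buffer))))
    writeLines(jsonlite::toJSON(gltf, auto_unbox = TRUE, digits = NA), path)
  }
  invisible(path)
}

#' Read back a glTF file written by [export_gltf()]
#'
#' Minimal glTF 2.0 reader for embedded-buffer `.gltf` and binary `.glb`
#' files: returns, per node, the primitive name, draw mode, vertex
#' positions, triangle indices (when present) and material base color.
#' Intended for verification and round-trip testing, not as a general glTF
#' loader (only the subset the exporter emits is supported).
#'
#' @param path a `.gltf` or `.glb` file.
#' @return list with `asset` and `primitives` (each: `name`, `mode`,
#'   `vertices`, `faces` or `NULL`, `color`).
#' @export
read_gltf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (tolower(tools::file_ext(path)) == "glb") {
    raw <- readBin(path, "raw", file.size(path))
    u32 <- function(off) readBin(raw[off + 1:4], "integer", size = 4L,
                                 endian = "little")
    if (u32(0L) != 0x46546C67L) stop("not a glb file", call. = FALSE)
    jlen <- u32(12L)
    g <- jsonlite::fromJSON(rawToChar(raw[21:(20 + jlen)]),
                            simplifyVector = FALSE)
    blen <- u32(20L + jlen)
    buffer <- raw[(28L + jlen + 1L):(28L + jlen + blen)]
  } else {
    g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    uri <- g$buffers[[1L]]$uri
    buffer <- jsonlite::base64_dec(sub("^data:[^,]*,", "", uri))
  }
  read_accessor <- function(ai) {
    a <- g$accessors[[ai + 1L]]
    v <- g$bufferViews[[a$bufferView + 1L]]
    off <- v$byteOffset %||% 0L
    bytes <- buffer[(off + 1L):(off + v$byteLength)]
    if (a$componentType == 5126L)
      readBin(bytes, "numeric", n = v$byteLength / 4L, size = 4L,
              endian = "little")
    else readBin(bytes, "integer", n = v$byteLength / 4L, size = 4L,
                 endian = "little")
  }
  prims <- lapply(g$nodes, function(nd) {
    mesh <- g$meshes[[nd$mesh + 1L]]
    pr <- mesh$primitives[[1L]]
    pos <- matrix(read_accessor(pr$attributes$POSITION), ncol = 3L,
                  byrow = TRUE)
    faces <- NULL
    if (!is.null(pr$indices))
      faces <- matrix(read_accessor(pr$indices) + 1L, ncol = 3L,
                      byrow = TRUE)
    col <- unlist(g$materials[[pr$material + 1L]]$
                    pbrMetallicRoughness$baseColorFactor)[1:3]
    list(name = nd$name, mode = pr$mode %||% 4L, vertices = pos,
         faces = faces, color = col)
  })
  list(asset = g$asset, primitives = prims)
}

# ---- raster ---------------------------------------------------------------

# perspective projection of world points for the scene camera.
# Returns image-plane coordinates (x right, y up, in tan-angle units) and
# depth along the view direction.
project_points <- function(pts, camera) {
  fwd <- camera$look_at - camera$position
  fwd <- fwd / vnorm(fwd)
  right <- c(fwd[2] * camera$up[3] - fwd[3] * camera$up[2],
             fwd[3] * camera$up[1] - fwd[1] * camera$up[3],
             fwd[1] * camera$up[2] - fwd[2] * camera$up[1])
  right <- right / vnorm(right)
  up <- c(right[2] * fwd[3] - right[3] * fwd[2],
          right[3] * fwd[1] - right[1] * fwd[3],
          right[1] * fwd[2] - right[2] * fwd[1])
  rel <- sweep(pts, 2L, camera$position)
  depth <- pmax(as.numeric(rel %*% fwd), 1e-9)
  cbind(x = as.numeric(rel %*% right) / depth,
        y = as.numeric(rel %*% up) / depth,
        depth = depth)
}

#' Render a scene to a raster image
#'
#' Offscreen software rendering via the cairo graphics device, so exports
#' work headless: all primitives are projected through the scene camera
#' (perspective, looking at the node barycenter) and drawn back-to-front
#' (painter's algorithm) — triangles as filled polygons, line-mode links as
#' 1-pixel polylines. TIFF output carries the DPI in both resolution tags;
#' PNG in its pHYs chunk. Node labels are never rasterized. The projection
#' parameters are serialized to a `<path>.view.json` sidecar so a render
#' can be reproduced exactly.
#'
#' @param scene a [build_scene()] result.
#' @param spec a [raster_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_raster <- function(scene, spec = raster_spec(), path) {
  stopifnot(inherits(scene, "scene_model"), inherits(spec, "raster_spec"))

  # field of view sized so the projected extent fits with a small margin
  ext <- do.call(rbind, lapply(scene$primitives, function(p)
    project_points(p$vertices, scene$camera)))
  half_w <- max(abs(ext[, "x"]), 1e-6) * 1.05
  half_h <- max(abs(ext[, "y"]), 1e-6) * 1.05
  # match the frame aspect so pixels stay square
  aspect <- spec$width / spec$height
  if (half_w / half_h < aspect) half_w <- half_h * aspect
  else half_h <- half_w / aspect

  if (spec$format == "tiff")
    grDevices::tiff(path, width = spec$width, height = spec$height,
                    res = spec$dpi, type = "cairo", compression = "lzw")
  else
    grDevices::png(path, width = spec$width, height = spec$height,
                   res = spec$dpi, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i", bg = "white")
  graphics::plot.new()
  graphics::plot.window(xlim = c(-half_w, half_w), ylim = c(-half_h, half_h))
  graphics::rect(-half_w * 2, -half_h * 2, half_w * 2, half_h * 2,
                 col = rgb_hex(scene$background), border = NA)

  # collect drawables: triangles and polyline segments with depths
  xs <- list(); ys <- list(); depth <- c(); cols <- c(); kind <- c()
  for (p in scene$primitives) {
    pr <- project_points(p$vertices, scene$camera)
    hex <- rgb_hex(p$color)
    if (!is.null(p$faces)) {
      f <- p$faces
      xs <- c(xs, lapply(seq_len(nrow(f)), function(r) pr[f[r, ], "x"]))
      ys <- c(ys, lapply(seq_len(nrow(f)), function(r) pr[f[r, ], "y"]))
      depth <- c(depth, rowMeans(matrix(pr[t(f), "depth"], ncol = 3L,
                                        byrow = TRUE)))
      cols <- c(cols, rep(hex, nrow(f)))
      kind <- c(kind, rep("tri", nrow(f)))
    } else {
      n <- nrow(pr)
      seg_i <- seq_len(n - 1L)
      xs <- c(xs, lapply(seg_i, function(r) pr[c(r, r + 1L), "x"]))
      ys <- c(ys, lapply(seg_i, function(r) pr[c(r, r + 1L), "y"]))
      depth <- c(depth, (pr[seg_i, "depth"] + pr[seg_i + 1L, "depth"]) / 2)
      cols <- c(cols, rep(hex, n - 1L))
      kind <- c(kind, rep("seg", n - 1L))
    }
  }
  for (r in order(depth, decreasing = TRUE)) {
    if (kind[r] == "tri")
      graphics::polygon(xs[[r]], ys[[r]], col = cols[r], border = NA)
    else
      graphics::lines(xs[[r]], ys[[r]], col = cols[r], lwd = 1)
  }

  sidecar <- list(camera = scene$camera,
                  frame = list(half_width = half_w, half_height = half_h),
                  raster = unclass(spec))
  jsonlite::write_json(sidecar, paste0(path, ".view.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
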