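#' Shape coefficients for link curves
#'
#' Four dimensionless coefficients drive the silhouette of every link. For
#' a link between nodes \eqn{S_i}, \eqn{S_j} at Euclidean distance
#' \eqn{d_{ij}}:
#' \itemize{
#'   \item `a1` — summit height: \eqn{h = a_1 d_{ij}}, the distance from the
#'     chord midpoint M to the summit U along the reference line;
#'   \item `a2` — summit handle: \eqn{d_U = a_2 d_{ij}/2}, the distance from
#'     U to its two control points, which sit perpendicular to the reference
#'     line (the "square angle" at the summit);
#'   \item `a3` — node angle fraction: \eqn{\alpha = a_3 \pi}, the departure
#'     angle of the curve at each node, measured in the link plane from the
#'     chord direction toward the summit side;
#'   \item `a4` — node handle: \eqn{d_S = a_4 d_{ij}/2}, the distance from
#'     each node to its first control point.
#' }
#' All are scale-free: doubling every coordinate doubles h, d_U and d_S and
#' leaves the silhouette unchanged.
#'
#' @param a1,a2,a4 non-negative reals.
#' @param a3 real in \[0, 1\].
#' @return an object of class `shape_params`.
#' @seealso [shape_preset()] for the eight named presets.
#' @export
shape_params <- function(a1, a2, a3, a4) {
  v <- c(a1 = a1, a2 = a2, a3 = a3, a4 = a4)
  if (!is.numeric(v) || length(v) != 4L || !all(is.finite(v)))
    stop("shape coefficients must be four finite numbers", call. = FALSE)
  if (a1 < 0 || a2 < 0 || a4 < 0)
    stop("a1, a2, a4 must be non-negative", call. = FALSE)
  if (a3 < 0 || a3 > 1)
    stop("a3 must lie in [0, 1]", call. = FALSE)
  structure(as.list(v), class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf("<shape_params> a1=%g a2=%g a3=%g a4=%g\n",
              x$a1, x$a2, x$a3, x$a4))
  invisible(x)
}

.shape_presets <- list(
  Default  = c(0.75, 0.5, 0.38, 0),
  Bell     = c(0.75, 0.5, 0,    0.5),
  Triangle = c(0.75, 0,   0,    0),
  Circle   = c(0.5,  0.5, 0.5,  0.5),
  Circle2  = c(0.9,  1,   0.8,  1),
  Square   = c(0.5,  1,   0.5,  1),
  Peak     = c(0.75, 0,   0,    1),
  Straight = c(0,    0,   0,    0)
)

#' Named shape presets
#'
#' Eight curated coefficient quadruples, each giving a characteristic link
#' silhouette: Default (0.75, 0.5, 0.38, 0), Bell (0.75, 0.5, 0, 0.5),
#' Triangle (0.75, 0, 0, 0), Circle (0.5, 0.5, 0.5, 0.5),
#' Circle2 (0.9, 1, 0.8, 1), Square (0.5, 1, 0.5, 1), Peak (0.75, 0, 0, 1)
#' and Straight (0, 0, 0, 0), which draws plain chords.
#'
#' @param name one of [preset_names()].
#' @return a [shape_params()] object.
#' @export
shape_preset <- function(name) {
  if (length(name) != 1L || !name %in% names(.shape_presets))
    stop("unknown preset ", deparse(name), "; valid presets: ",
         paste(names(.shape_presets), collapse = ", "), call. = FALSE)
  do.call(shape_params, as.list(.shape_presets[[name]]))
}

#' @rdname shape_preset
#' @export
preset_names <- function() names(.shape_presets)

#' Geometry configuration
#'
#' @param reference_point the virtual reference point C that, with each
#'   chord midpoint, defines the elevation direction of every link. `NULL`
#'   (the default) means the barycenter of all node coordinates, resolved
#'   when the scene is built.
#' @param altitude_offset signed value added to the vertical (y) component
#'   of C, letting the reference point slide along the altitude axis.
#' @param samples_per_half number of sampling intervals per Bezier piece
#'   (>= 2, default 32); each link polyline has `2 * samples_per_half + 1`
#'   points.
#' @return an object of class `geometry_config`.
#' @export
geometry_config <- function(reference_point = NULL, altitude_offset = 0,
                            samples_per_half = 32L) {
  if (!is.null(reference_point)) {
    reference_point <- as.numeric(reference_point)
    if (length(reference_point) != 3L || !all(is.finite(reference_point)))
      stop("reference_point must be a finite 3-vector", call. = FALSE)
  }
  if (!is.finite(altitude_offset))
    stop("altitude_offset must be finite", call. = FALSE)
  samples_per_half <- as.integer(samples_per_half)
  if (is.na(samples_per_half) || samples_per_half < 2L)
    stop("samples_per_half must be an integer >= 2", call. = FALSE)
  structure(list(reference_point = reference_point,
                 altitude_offset = altitude_offset,
                 samples_per_half = samples_per_half),
            class = "geometry_config")
}

#' Barycenter of node coordinates
#'
#' @param coords N x 3 numeric matrix.
#' @return the arithmetic mean of the rows, a 3-vector.
#' @export
barycenter <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("empty coordinate set", call. = FALSE)
  colMeans(coords)
}

vnorm <- function(v) sqrt(sum(v * v))

#' Orthonormal frame of a link chord
#'
#' For nodes `si`, `sj` and reference point `C`, builds the in-plane frame
#' every link curve is expressed in: the chord midpoint
#' `M = (si + sj) / 2`, the unit chord direction `u`, and the unit
#' elevation direction `w` — the component of `M - C` orthogonal to the
#' chord, so `w` is perpendicular to `u` and points away from C. When C is
#' collinear with the chord the in-plane elevation is undefined; the frame
#' falls back to the global vertical axis (projected orthogonal to `u`),
#' and to the lateral x axis if the chord itself is vertical.
#'
#' @param si,sj node positions (distinct 3-vectors).
#' @param cpt reference point C (3-vector).
#' @return an object of class `chord_frame` with elements `M`, `u`, `w`,
#'   `d` (the internode distance), the endpoints `si`, `sj`, and
#'   `degenerate` (logical, TRUE when a fallback direction was used).
#' @export
chord_frame <- function(si, sj, cpt) {
  si <- as.numeric(si); sj <- as.numeric(sj); cpt <- as.numeric(cpt)
  d <- vnorm(sj - si)
  if (d == 0)
    stop("coincident nodes at (", paste(format(si), collapse = ", "),
         "): zero-length links cannot be drawn", call. = FALSE)
  m <- (si + sj) / 2
  u <- (sj - si) / d
  v <- m - cpt
  v_perp <- v - sum(v * u) * u
  degenerate <- vnorm(v_perp) < 1e-9 * d
  if (degenerate) {
    for (axis in list(c(0, 1, 0), c(1, 0, 0))) {
      cand <- axis - sum(axis * u) * u
      if (vnorm(cand) > 1e-9) { v_perp <- cand; break }
    }
  }
  w <- v_perp / vnorm(v_perp)
  structure(list(M = m, u = u, w = w, d = d, si = si, sj = sj,
                 degenerate = degenerate),
            class = "chord_frame")
}

#' Summit of a link
#'
#' The apex U of the two-piece curve lies on the reference line through C
#' and M, on the side of M opposite C (contralateral), at height
#' `h = a1 * d` above the chord: `U = M + a1 * d * w`.
#'
#' @param frame a [chord_frame()].
#' @param a1 height coefficient.
#' @return the summit position, a 3-vector.
#' @export
summit <- function(frame, a1) frame$M + a1 * frame$d * frame$w

#' Interior control points of the two Bezier pieces
#'
#' With `alpha = a3 * pi`, `d_S = a4 * d / 2` and `d_U = a2 * d / 2`:
#' \itemize{
#'   \item `B1 = si + d_S (cos(alpha) u + sin(alpha) w)` — the node handle
#'     at `si`, departing at angle alpha from the chord toward the summit
#'     side; `B1p` mirrors it at `sj` (`-cos(alpha) u + sin(alpha) w`);
#'   \item `B2 = U - d_U u` and `B2p = U + d_U u` — the summit handles,
#'     perpendicular to the reference line UM (the square-angle
#'     constraint).
#' }
#' All four lie in the chord plane spanned by `u` and `w`.
#'
#' @param frame a [chord_frame()].
#' @param u_pt the summit from [summit()].
#' @param params a [shape_params()].
#' @return list with elements `B1`, `B2`, `B2p`, `B1p` (3-vectors).
#' @export
control_points <- function(frame, u_pt, params) {
  alpha <- params$a3 * pi
  d_s <- params$a4 * frame$d / 2
  d_u <- params$a2 * frame$d / 2
  si <- frame$si
  sj <- frame$sj
  dir_i <- cos(alpha) * frame$u + sin(alpha) * frame$w
  dir_j <- -cos(alpha) * frame$u + sin(alpha) * frame$w
  list(B1 = si + d_s * dir_i,
       B2 = u_pt - d_u * frame$u,
       B2p = u_pt + d_u * frame$u,
       B1p = sj + d_s * dir_j)
}

# sample one cubic Bezier at parameters t (rows of the 4 control points)
bezier_cubic <- function(p0, p1, p2, p3, t) {
  s <- 1 - t
  outer(s^3, p0) + outer(3 * s^2 * t, p1) +
    outer(3 * s * t^2, p2) + outer(t^3, p3)
}

#' Full curve of one link
#'
#' Builds the two-piece curve for the link between `si` and `sj`: a cubic
#' Bezier with control polygon `(si, B1, B2, U)` followed by its mirror
#' `(U, B2p, B1p, sj)`, each sampled at `samples_per_half + 1` uniformly
#' spaced parameter values and concatenated without duplicating the shared
#' summit. The two interior control points per piece make each piece a
#' cubic; with `a2 = a4 = 0` both pieces degenerate to straight segments,
#' and the Straight preset (`a1 = 0` too) collapses onto the chord.
#'
#' @param si,sj node positions.
#' @param cpt reference point C.
#' @param params a [shape_params()].
#' @param samples_per_half sampling intervals per piece (>= 2).
#' @param weight optional link weight, stored as the color scalar.
#' @param radius optional tube radius, stored for the scene builder.
#' @return an object of class `link_curve`: elements `si`, `sj`, `U`, `B1`,
#'   `B2`, `B2p`, `B1p`, `h`, `d_U`, `d_S`, `alpha`, `d` (internode
#'   distance), `polyline` (a (2 * samples_per_half + 1) x 3 matrix whose
#'   first and last rows are exactly `si` and `sj`), `weight`, `radius`.
#' @export
link_path <- function(si, sj, cpt, params = shape_preset("Default"),
                      samples_per_half = 32L, weight = NA_real_,
                      radius = NA_real_) {
  stopifnot(inherits(params, "shape_params"))
  samples_per_half <- as.integer(samples_per_half)
  if (is.na(samples_per_half) || samples_per_half < 2L)
    stop("samples_per_half must be an integer >= 2", call. = FALSE)
  si <- as.numeric(si); sj <- as.numeric(sj)
  frame <- chord_frame(si, sj, cpt)
  u_pt <- summit(frame, params$a1)
  cp <- control_points(frame, u_pt, params)
  t <- seq(0, 1, length.out = samples_per_half + 1L)
  half1 <- bezier_cubic(si, cp$B1, cp$B2, u_pt, t)
  half2 <- bezier_cubic(u_pt, cp$B2p, cp$B1p, sj, t)
  poly <- rbind(half1, half2[-1L, , drop = FALSE])
  # endpoint interpolation must be exact, not merely within float error
  poly[1L, ] <- si
  poly[nrow(poly), ] <- sj
  structure(list(si = si, sj = sj, U = u_pt,
                 B1 = cp$B1, B2 = cp$B2, B2p = cp$B2p, B1p = cp$B1p,
                 h = params$a1 * frame$d, d_U = params$a2 * frame$d / 2,
                 d_S = params$a4 * frame$d / 2, alpha = params$a3 * pi,
                 d = frame$d, frame = frame, polyline = poly,
                 weight = weight, radius = radius),
            class = "link_curve")
}

#' @export
print.link_curve <- function(x, ...) {
  cat(sprintf(
    "<link_curve> d=%.4g h=%.4g alpha=%.4g rad, %d points\n",
    x$d, x$h, x$alpha, nrow(x$polyline)))
  invisible(x)
}

#' Link radius from internode distance
#'
#' The tube radius decreases with the distance a link covers
#' (`radius = scale / d`), clamped to `[r_min, r_max]`, so the highest
#' (longest) links are also the thinnest and do not hide short ones.
#'
#' @param d internode distance (> 0).
#' @param scale proportionality constant (radius at unit distance).
#' @param r_min,r_max clamp bounds, `0 < r_min <= r_max`.
#' @return the clamped radius.
#' @export
link_radius <- function(d, scale = 1, r_min = 0.01, r_max = 10) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("internode distance must be positive", call. = FALSE)
  if (r_min <= 0 || r_max < r_min)
    stop("need 0 < r_min <= r_max", call. = FALSE)
  pmin(pmax(scale / d, r_min), r_max)
}

#' Color scalar of a link
#'
#' Link color codes the connection weight; this is a passthrough, and the
#' min-max normalization over the retained link set happens when the scene
#' is assembled (see [build_scene()]).
#'
#' @param weight link weight.
#' @return `weight`, unchanged.
#' @export
link_color_scalar <- function(weight) weight

#' Degree bar of a node
#'
#' Node degree is shown as a bar anchored at the node and pointing radially
#' away from the reference point C (for nodes on a sphere around C the bars
#' are perpendicular to the surface). Its length is `bar_scale * degree`.
#' When the node coincides with C the direction falls back to the global
#' vertical.
#'
#' @param node node position (3-vector).
#' @param cpt reference point C.
#' @param degree incident link count.
#' @param bar_scale length per unit degree.
#' @return list with `base` (the node position) and `tip` 3-vectors;
#'   `NULL` for degree 0 (a zero-length bar is omitted from scenes).
#' @export
degree_bar <- function(node, cpt, degree, bar_scale) {
  if (degree == 0) return(NULL)
  node <- as.numeric(node); cpt <- as.numeric(cpt)
  dir <- node - cpt
  if (vnorm(dir) < 1e-12) dir <- c(0, 1, 0)
  dir <- dir / vnorm(dir)
  list(base = node, tip = node + bar_scale * degree * dir)
}
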