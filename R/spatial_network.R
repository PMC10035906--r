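#' Spatial network container
#'
#' A `spatial_network` bundles the three pieces of information every stage of
#' the pipeline consumes: fixed node coordinates, a symmetric non-negative
#' weight matrix (0 means "no link"), and optional node labels. Coordinates
#' are stored internally as columns `x`, `y`, `z` with `y` the vertical
#' (altitude) axis, in a right-handed y-up convention; downstream modules
#' never re-permute axes.
#'
#' Validity requirements, checked at construction:
#' \itemize{
#'   \item `weights` is square with side equal to the number of coordinate rows;
#'   \item `weights` is symmetric within `1e-9` (directed networks are not
#'     supported);
#'   \item the diagonal is all zero (self-loops are never drawn);
#'   \item all weights are non-negative and all coordinates finite;
#'   \item `labels`, when given, has one string per node.
#' }
#'
#' @param coords numeric matrix, one row per node, three columns (x, y, z
#'   with y vertical). A 2-column matrix is accepted and lifted to 3D with
#'   `y = 0` (a flat network on the horizontal plane).
#' @param weights numeric N x N symmetric matrix of connection weights.
#' @param labels optional character vector of length N.
#' @return an object of class `spatial_network` with elements `coords`,
#'   `weights` and `labels`.
#' @examples
#' net <- spatial_network(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)),
#'                        matrix(c(0, 1, 2, 1, 0, 0, 2, 0, 0), 3, 3))
#' n_links(net)
#' @export
spatial_network <- function(coords, weights, labels = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || nrow(coords) < 1L)
    stop("coords must be a non-empty numeric matrix", call. = FALSE)
  if (ncol(coords) == 2L) coords <- cbind(coords[, 1L], 0, coords[, 2L])
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z), got ", ncol(coords),
         call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coords contains non-finite values", call. = FALSE)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")

  weights <- as.matrix(weights)
  n <- nrow(coords)
  if (nrow(weights) != ncol(weights))
    stop("weights must be square, got ", nrow(weights), " x ", ncol(weights),
         call. = FALSE)
  if (nrow(weights) != n)
    stop("weights is ", nrow(weights), " x ", ncol(weights), " but there are ",
         n, " coordinate rows", call. = FALSE)
  if (!all(is.finite(weights)))
    stop("weights contains non-finite values", call. = FALSE)
  if (any(weights < 0))
    stop("negative weights are not allowed", call. = FALSE)
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-9)
    stop("weights is asymmetric (max |A - t(A)| = ", format(asym),
         "); directed networks are not supported", call. = FALSE)
  if (any(diag(weights) != 0))
    stop("weights has a nonzero diagonal; self-loops are not supported",
         call. = FALSE)
  storage.mode(weights) <- "double"
  dimnames(weights) <- NULL

  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n)
      stop("labels has length ", length(labels), " but there are ", n,
           " nodes", call. = FALSE)
  }

  structure(list(coords = coords, weights = weights, labels = labels),
            class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat("<spatial_network> ", n_nodes(x), " nodes, ", n_links(x), " links",
      if (!is.null(x$labels)) ", labelled" else "", "\n", sep = "")
  invisible(x)
}

#' Number of nodes in a spatial network
#' @param net a `spatial_network`.
#' @return integer node count.
#' @export
n_nodes <- function(net) nrow(net$coords)

#' Number of links in a spatial network
#'
#' Counts unordered node pairs with nonzero weight.
#' @param net a `spatial_network`.
#' @return integer link count.
#' @export
n_links <- function(net) sum(net$weights[upper.tri(net$weights)] > 0)

#' Per-link table of a spatial network
#'
#' Enumerates the links (unordered pairs i < j with nonzero weight) in
#' ascending (i, j) order, with their weight and Euclidean internode
#' distance. This ordering is the tie-break order used by all filters.
#'
#' @param net a `spatial_network`.
#' @return a data frame with columns `i`, `j`, `weight`, `distance`.
#' @export
link_table <- function(net) {
  idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(i = integer(), j = integer(),
                      weight = numeric(), distance = numeric()))
  i <- idx[, 1L]; j <- idx[, 2L]
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]
  d <- sqrt(rowSums((net$coords[i, , drop = FALSE] -
                     net$coords[j, , drop = FALSE])^2))
  data.frame(i = i, j = j, weight = net$weights[cbind(i, j)], distance = d)
}

#' Node degrees of a spatial network
#'
#' Degree is the unweighted link count incident on each node.
#' @param net a `spatial_network`.
#' @return integer vector of length N.
#' @export
node_degrees <- function(net) as.integer(colSums(net$weights > 0))

# number of connected components over nonzero links (isolated nodes count)
components_count <- function(weights) {
  n <- nrow(weights)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(weights[v, ] > 0 & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  k
}

axis_permutation <- function(axis_order = c("xzy", "xyz")) {
  axis_order <- match.arg(axis_order)
  # permutation mapping input columns -> internal (x, y, z)
  if (axis_order == "xzy") c(1L, 3L, 2L) else c(1L, 2L, 3L)
}

# strict numeric CSV reader: comma separator, "." decimal, no header.
# Returns a numeric matrix; errors name the offending line.
read_numeric_csv <- function(path, what = "file") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ", what, ": ", path, call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  first <- suppressWarnings(as.numeric(trimws(fields[[1L]])))
  if (anyNA(first))
    stop("line 1 of ", path, " is not numeric; a header row is not ",
         "supported, remove it", call. = FALSE)
  ncols <- length(fields[[1L]])
  out <- matrix(NA_real_, length(fields), ncols)
  for (k in seq_along(fields)) {
    if (length(fields[[k]]) != ncols)
      stop("parse error at line ", k, " of ", path, ": expected ", ncols,
           " fields, found ", length(fields[[k]]), call. = FALSE)
    v <- suppressWarnings(as.numeric(trimws(fields[[k]])))
    if (anyNA(v))
      stop("parse error at line ", k, " of ", path, ": non-numeric field",
           call. = FALSE)
    out[k, ] <- v
  }
  out
}

#' Read node coordinates from CSV
#'
#' Reads a headerless CSV with one row per node and exactly three numeric
#' fields per row. The default `axis_order = "xzy"` follows the convention
#' of the original data files, where the second column is the z (depth)
#' coordinate and the third the vertical one; coordinates are permuted into
#' the internal x, y, z order (y vertical) on read.
#'
#' @param path path to the CSV file.
#' @param axis_order `"xzy"` (default) or `"xyz"` — the order of the three
#'   columns in the file.
#' @return numeric N x 3 matrix in internal (x, y, z) order.
#' @export
read_coordinates <- function(path, axis_order = c("xzy", "xyz")) {
  perm <- axis_permutation(axis_order)
  m <- read_numeric_csv(path, "coordinate file")
  if (ncol(m) != 3L)
    stop("parse error at line 1 of ", path, ": expected 3 coordinate ",
         "fields, found ", ncol(m), call. = FALSE)
  out <- m[, order(perm), drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Read an adjacency matrix from CSV
#'
#' Reads a headerless square numeric CSV. The matrix must be symmetric
#' (within `1e-9`), non-negative, and zero on the diagonal. With
#' `symmetrize = TRUE`, an asymmetric matrix is replaced by `(A + t(A)) / 2`
#' and a nonzero diagonal is zeroed, each with a warning; otherwise both are
#' errors.
#'
#' @param path path to the CSV file.
#' @param symmetrize coerce asymmetric input instead of failing.
#' @return numeric N x N matrix.
#' @export
read_adjacency <- function(path, symmetrize = FALSE) {
  m <- read_numeric_csv(path, "adjacency file")
  if (nrow(m) != ncol(m))
    stop("adjacency matrix in ", path, " is not square: ", nrow(m), " x ",
         ncol(m), call. = FALSE)
  if (any(m < 0))
    stop("adjacency matrix in ", path, " has negative weights", call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-9) {
    if (!symmetrize)
      stop("adjacency matrix in ", path, " is asymmetric (max |A - t(A)| = ",
           format(asym), "); pass symmetrize = TRUE to average with its ",
           "transpose", call. = FALSE)
    warning("symmetrizing asymmetric adjacency matrix: (A + t(A)) / 2")
    m <- (m + t(m)) / 2
  }
  if (any(diag(m) != 0)) {
    if (!symmetrize)
      stop("adjacency matrix in ", path, " has a nonzero diagonal; ",
           "self-loops are not supported", call. = FALSE)
    warning("zeroing nonzero diagonal of adjacency matrix")
    diag(m) <- 0
  }
  m
}

#' Read node labels
#'
#' One label per line; the count is checked against the node count when the
#' network is assembled, not here.
#'
#' @param path path to the label file.
#' @return character vector.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # a trailing newline produces one empty final element; interior blanks stay
  if (length(lines) && !nzchar(lines[[length(lines)]]))
    lines <- lines[-length(lines)]
  trimws(lines)
}

#' Read a spatial network from CSV files
#'
#' Convenience wrapper assembling [read_coordinates()], [read_adjacency()]
#' and optionally [read_labels()] into a validated [spatial_network()].
#'
#' @param coords_path,adjacency_path,labels_path file paths; `labels_path`
#'   may be `NULL`.
#' @inheritParams read_coordinates
#' @inheritParams read_adjacency
#' @return a `spatial_network`.
#' @export
read_network_csv <- function(coords_path, adjacency_path, labels_path = NULL,
                             axis_order = c("xzy", "xyz"),
                             symmetrize = FALSE) {
  spatial_network(
    read_coordinates(coords_path, axis_order),
    read_adjacency(adjacency_path, symmetrize),
    if (!is.null(labels_path)) read_labels(labels_path)
  )
}

#' Read a spatial network from a JSON bundle
#'
#' The bundle is a single JSON object with keys `"coordinates"` (N x 3 array
#' of arrays), `"matrix"` (N x N array of arrays), optional `"labels"`
#' (array of N strings) and optional `"axis_order"` (`"xzy"`, the default,
#' or `"xyz"`). The same validation as the CSV path applies.
#'
#' @param path path to the JSON file.
#' @return a `spatial_network`.
#' @seealso [write_network_bundle()]
#' @export
read_network_bundle <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  b <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  for (key in c("coordinates", "matrix"))
    if (is.null(b[[key]]))
      stop("bundle ", path, " is missing required key \"", key, "\"",
           call. = FALSE)
  axis_order <- if (is.null(b$axis_order)) "xzy" else b$axis_order
  perm <- axis_permutation(axis_order)
  coords <- as.matrix(b$coordinates)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("bundle \"coordinates\" must be an N x 3 numeric array",
         call. = FALSE)
  coords <- coords[, order(perm), drop = FALSE]
  weights <- as.matrix(b$matrix)
  labels <- if (!is.null(b$labels) && length(b$labels)) as.character(b$labels)
  spatial_network(coords, weights, labels)
}

#' Write a spatial network to a JSON bundle
#'
#' Inverse of [read_network_bundle()]: `read_network_bundle(write_network_bundle(net, p))`
#' reproduces `net` exactly. Coordinates are written in `"xzy"` column order
#' with an explicit `"axis_order"` key; empty labels are omitted.
#'
#' @param net a `spatial_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_bundle <- function(net, path) {
  stopifnot(inherits(net, "spatial_network"))
  out <- list(
    axis_order = "xzy",
    coordinates = net$coords[, c(1L, 3L, 2L), drop = FALSE],
    matrix = net$weights
  )
  dimnames(out$coordinates) <- NULL
  if (!is.null(net$labels)) out$labels <- net$labels
  # 17 significant digits: doubles survive the decimal round-trip exactly
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}
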