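#' @name fixtures
#' @title Synthetic spatial networks
#'
#' @description
#' Generators for the demonstration networks used throughout the examples
#' and tests: preferential-attachment topology on a sphere, a 3D lattice
#' with mostly-neighbor links, the complete network, and a random geometric
#' graph. All are deterministic under a fixed seed (R's default
#' Mersenne-Twister stream, isolated from the caller's RNG state) and all
#' satisfy the `spatial_network` validity requirements.
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# area-uniform points on the unit sphere (y vertical): uniform azimuth,
# uniform cos(polar) — avoids polar clustering
runif_sphere <- function(n) {
  cos_pol <- stats::runif(n, -1, 1)
  az <- stats::runif(n, 0, 2 * pi)
  sin_pol <- sqrt(1 - cos_pol^2)
  cbind(x = sin_pol * cos(az), y = cos_pol, z = sin_pol * sin(az))
}

#' Preferential-attachment network on a sphere
#'
#' `n` nodes distributed area-uniformly on the unit sphere, linked by a
#' Barabási–Albert-style preferential-attachment process: growth starts
#' from `m` seed nodes (no links among them), and each arriving node
#' attaches `m` distinct links to existing nodes drawn with probability
#' proportional to degree + 1 (the +1 lets the initially link-less seed
#' nodes be chosen), resampling to avoid duplicate edges. The link count is
#' therefore exactly `m * (n - m)`. All weights are 1.
#'
#' @param n node count (> m).
#' @param m links added per arriving node (>= 1).
#' @param seed RNG seed.
#' @return a `spatial_network`.
#' @rdname fixtures
#' @export
sphere_ba_network <- function(n, m = 1L, seed = 1L) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(m) || m < 1L || is.na(n) || n <= m)
    stop("need n > m >= 1", call. = FALSE)
  with_seed(seed, {
    coords <- runif_sphere(n)
    w <- matrix(0, n, n)
    deg <- integer(n)
    for (v in (m + 1L):n) {
      existing <- seq_len(v - 1L)
      prob <- deg[existing] + 1
      targets <- integer(0)
      while (length(targets) < m) {
        cand <- sample(existing, 1L, prob = prob)
        if (!cand %in% targets) targets <- c(targets, cand)
      }
      w[v, targets] <- 1
      w[targets, v] <- 1
      deg[targets] <- deg[targets] + 1L
      deg[v] <- deg[v] + m
    }
    spatial_network(coords, w)
  })
}

#' 3D lattice network
#'
#' Nodes on the integer grid `nx` x `ny` x `nz` (0-based coordinates, the
#' second dimension vertical), linked along the 6-neighborhood, plus a
#' fraction `p_extra` of additional random long-range links (rounded count
#' `round(p_extra * L_grid)` among non-neighbor pairs). Link weight is
#' `1 + mean elevation of the endpoints`, so color encodes how high a
#' connection sits; the offset keeps ground-level links at a nonzero
#' weight.
#'
#' @param nx,ny,nz grid dimensions (>= 1, at least 2 nodes total).
#' @param p_extra fraction of extra random links (default 0,
#'   deterministic regardless of seed).
#' @rdname fixtures
#' @export
lattice_network <- function(nx, ny, nz, p_extra = 0, seed = 1L) {
  dims <- as.integer(c(nx, ny, nz))
  if (any(is.na(dims)) || any(dims < 1L) || prod(dims) < 2L)
    stop("grid dimensions must be >= 1 with at least 2 nodes",
         call. = FALSE)
  if (p_extra < 0 || p_extra > 1)
    stop("p_extra must lie in [0, 1]", call. = FALSE)
  g <- expand.grid(x = seq_len(dims[1]) - 1L, y = seq_len(dims[2]) - 1L,
                   z = seq_len(dims[3]) - 1L)
  coords <- as.matrix(g)
  n <- nrow(coords)
  w <- matrix(0, n, n)
  link_weight <- function(i, j) 1 + (coords[i, 2] + coords[j, 2]) / 2
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sum(abs(coords[i, ] - coords[j, ])) == 1L)
      w[i, j] <- w[j, i] <- link_weight(i, j)
  }
  n_grid <- sum(w[upper.tri(w)] > 0)
  n_extra <- round(p_extra * n_grid)
  if (n_extra > 0) with_seed(seed, {
    free <- which(upper.tri(w) & w == 0)
    pick <- sample(free, min(n_extra, length(free)))
    for (idx in pick) {
      i <- row(w)[idx]; j <- col(w)[idx]
      w[i, j] <- w[j, i] <- link_weight(i, j)
    }
  })
  spatial_network(coords, w)
}

#' Complete network on a sphere
#'
#' `n` nodes area-uniform on the unit sphere, every pair linked
#' (`n * (n - 1) / 2` links), with weight `1 / d_ij` so that both the
#' weight-based and distance-based filters have something to bite on.
#'
#' @rdname fixtures
#' @export
complete_network <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("need n >= 2", call. = FALSE)
  coords <- with_seed(seed, runif_sphere(n))
  d <- as.matrix(stats::dist(coords))
  w <- 1 / d
  diag(w) <- 0
  w <- (w + t(w)) / 2          # exact symmetry despite float division
  spatial_network(coords, w)
}

#' Random geometric network in the unit cube
#'
#' Uniform points in the unit cube; nodes closer than `radius` are linked
#' with weight `1 - d_ij / radius` (strong short links fading to 0 at the
#' connection radius).
#'
#' @param radius connection radius (> 0).
#' @rdname fixtures
#' @export
random_geometric_network <- function(n, radius, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("need n >= 1", call. = FALSE)
  if (!is.finite(radius) || radius <= 0)
    stop("radius must be > 0", call. = FALSE)
  coords <- with_seed(seed, matrix(stats::runif(3L * n), n, 3L))
  colnames(coords) <- c("x", "y", "z")
  d <- as.matrix(stats::dist(coords))
  w <- ifelse(d < radius & d > 0, 1 - d / radius, 0)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  spatial_network(coords, w)
}

#' Build a fixture network by name
#'
#' Dispatcher used by the command-line `fixtures` subcommand.
#'
#' @param kind one of `"sphere_ba"`, `"lattice"`, `"complete"`,
#'   `"random_geometric"`.
#' @param n node count (for the lattice: nodes per side of a cubic grid).
#' @param ... forwarded to the specific generator.
#' @rdname fixtures
#' @export
make_fixture <- function(kind = c("sphere_ba", "lattice", "complete",
                                  "random_geometric"),
                         n, ...) {
  kind <- match.arg(kind)
  switch(kind,
         sphere_ba = sphere_ba_network(n, ...),
         lattice = lattice_network(n, n, n, ...),
         complete = complete_network(n, ...),
         random_geometric = random_geometric_network(n, ...))
}
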