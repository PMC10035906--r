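# shared builders for small in-code fixtures

# complete network on given coordinates with weights 1..L assigned to the
# upper triangle in ascending (i, j) order
complete_weighted <- function(coords) {
  n <- nrow(coords)
  w <- matrix(0, n, n)
  val <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    val <- val + 1
    w[i, j] <- w[j, i] <- val
  }
  spatial_network(coords, w)
}

# star: node 1 is the hub, nodes 2..(k+1) are leaves
star_network <- function(leaves) {
  n <- leaves + 1
  coords <- cbind(c(0, cos(2 * pi * seq_len(leaves) / leaves)),
                  0,
                  c(0, sin(2 * pi * seq_len(leaves) / leaves)))
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- 1
  spatial_network(coords, w)
}

# random spatial network: n nodes in the unit cube, each off-diagonal pair
# linked with probability p, weights uniform (never exactly zero)
random_network <- function(n, p = 0.5) {
  coords <- matrix(runif(3 * n), n, 3)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) w[i, j] <- w[j, i] <- runif(1, 0.1, 10)
  spatial_network(coords, w)
}

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

expect_network_valid <- function(net) {
  w <- net$weights
  expect_true(all(is.finite(net$coords)))
  expect_identical(nrow(w), ncol(w))
  expect_identical(nrow(w), nrow(net$coords))
  expect_lte(max(abs(w - t(w))), 1e-9)
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= 0))
  if (!is.null(net$labels)) expect_length(net$labels, nrow(net$coords))
}
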