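random_pair <- function(span = 10) {
  repeat {
    si <- runif(3, -span, span)
    sj <- runif(3, -span, span)
    cc <- runif(3, -span, span)
    if (sqrt(sum((sj - si)^2)) > 1e-3) return(list(si = si, sj = sj, c = cc))
  }
}

test_that("chord frame is orthonormal, centered, and falls back when degenerate", {
  fr <- chord_frame(c(0, 0, 0), c(2, 0, 0), c(1, -1, 0))
  expect_equal(fr$M, c(1, 0, 0))
  expect_equal(fr$u, c(1, 0, 0))
  expect_equal(fr$w, c(0, 1, 0))
  expect_identical(fr$d, 2)
  expect_false(fr$degenerate)

  # C on the chord (C = M): vertical fallback
  fr2 <- chord_frame(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0))
  expect_true(fr2$degenerate)
  expect_equal(fr2$w, c(0, 1, 0))

  # vertical chord with C = M: secondary (lateral) fallback, still orthonormal
  fr3 <- chord_frame(c(0, 0, 0), c(0, 2, 0), c(0, 1, 0))
  expect_true(fr3$degenerate)
  expect_equal(sqrt(sum(fr3$w^2)), 1, tolerance = 1e-12)
  expect_equal(sum(fr3$w * fr3$u), 0, tolerance = 1e-12)

  expect_error(chord_frame(c(1, 2, 3), c(1, 2, 3), c(0, 0, 0)),
               "coincident")

  set.seed(31)
  for (k in seq_len(200)) {
    p <- random_pair()
    fr <- chord_frame(p$si, p$sj, p$c)
    expect_equal(sqrt(sum(fr$u^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(fr$w^2)), 1, tolerance = 1e-12)
    expect_lt(abs(sum(fr$u * fr$w)), 1e-9)
  }
})

test_that("summit sits on the reference line at height a1 * d, contralateral to C", {
  fr <- chord_frame(c(0, 0, 0), c(2, 0, 0), c(1, -1, 0))
  expect_equal(summit(fr, 0.75), c(1, 1.5, 0))    # h = 0.75 * 2
  expect_equal(summit(fr, 0), fr$M)
  set.seed(37)
  for (k in seq_len(1000)) {
    p <- random_pair()
    a1 <- runif(1, 0, 2)
    fr <- chord_frame(p$si, p$sj, p$c)
    u_pt <- summit(fr, a1)
    expect_equal(sqrt(sum((u_pt - fr$M)^2)) / fr$d, a1, tolerance = 1e-12)
    expect_gte(sum((u_pt - fr$M) * (fr$M - p$c)), 0)
  }
})

test_that("control points follow the printed handle formulas", {
  # Circle preset on a unit chord: alpha = pi/2, d_S = d_U = 0.25
  fr <- chord_frame(c(0, 0, 0), c(1, 0, 0), c(0.5, -1, 0))
  u_pt <- summit(fr, 0.5)
  cp <- control_points(fr, u_pt, shape_preset("Circle"))
  expect_equal(cp$B1, c(0, 0.25, 0), tolerance = 1e-12)    # vertical departure
  expect_equal(cp$B1p, c(1, 0.25, 0), tolerance = 1e-12)
  expect_equal(cp$B2, u_pt - 0.25 * fr$u, tolerance = 1e-12)
  expect_equal(cp$B2p, u_pt + 0.25 * fr$u, tolerance = 1e-12)

  # a4 = 0 pins the node handles onto the endpoints whatever a3 is
  cp0 <- control_points(fr, u_pt, shape_params(0.5, 0.5, 0.38, 0))
  expect_identical(cp0$B1, fr$si)
  expect_identical(cp0$B1p, fr$sj)
  # a2 = 0 collapses the summit handles onto U
  cpU <- control_points(fr, u_pt, shape_params(0.5, 0, 0.5, 0.5))
  expect_identical(cpU$B2, u_pt)
  expect_identical(cpU$B2p, u_pt)
})

test_that("link paths interpolate endpoints, stay planar, and meet smoothly at U", {
  set.seed(43)
  presets <- preset_names()
  for (k in seq_len(1000)) {
    p <- random_pair()
    params <- shape_preset(presets[(k - 1) %% length(presets) + 1])
    lc <- link_path(p$si, p$sj, p$c, params, samples_per_half = 8)
    expect_identical(lc$polyline[1, ], p$si)
    expect_identical(lc$polyline[nrow(lc$polyline), ], p$sj)
    fr <- lc$frame
    if (!fr$degenerate) {
      nrm <- c(fr$u[2] * fr$w[3] - fr$u[3] * fr$w[2],
               fr$u[3] * fr$w[1] - fr$u[1] * fr$w[3],
               fr$u[1] * fr$w[2] - fr$u[2] * fr$w[1])
      dev <- abs(sweep(lc$polyline, 2, p$si) %*% nrm)
      expect_lt(max(dev), 1e-9 * lc$d)
    }
    expect_gte(sum((lc$U - fr$M) * (fr$M - p$c)), 0)
    # shared summit and C1 continuity when the summit handles are live
    expect_equal(lc$polyline[9, ], lc$U, tolerance = 1e-12)
    if (params$a2 > 0) {
      t_in <- (lc$U - lc$B2) / sqrt(sum((lc$U - lc$B2)^2))
      t_out <- (lc$B2p - lc$U) / sqrt(sum((lc$B2p - lc$U)^2))
      expect_equal(sum(t_in * t_out), 1, tolerance = 1e-9)
    }
  }
})

test_that("swapping the endpoints reverses the sampled path exactly", {
  set.seed(47)
  for (preset in preset_names()) {
    p <- random_pair()
    a <- link_path(p$si, p$sj, p$c, shape_preset(preset), 16)
    b <- link_path(p$sj, p$si, p$c, shape_preset(preset), 16)
    expect_equal(a$polyline, b$polyline[nrow(b$polyline):1, ],
                 tolerance = 1e-12)
  }
})

test_that("geometry is equivariant under translation and uniform scaling", {
  set.seed(53)
  for (k in seq_len(50)) {
    p <- random_pair()
    params <- shape_preset(preset_names()[(k - 1) %% 8 + 1])
    lc <- link_path(p$si, p$sj, p$c, params, 8)
    tr <- runif(3, -5, 5)
    lt <- link_path(p$si + tr, p$sj + tr, p$c + tr, params, 8)
    expect_equal(lt$polyline, sweep(lc$polyline, 2, -tr), tolerance = 1e-9)
    expect_equal(lt$U, lc$U + tr, tolerance = 1e-9)
    s <- runif(1, 0.1, 10)
    ls <- link_path(s * p$si, s * p$sj, s * p$c, params, 8)
    expect_equal(ls$polyline, s * lc$polyline, tolerance = 1e-9 * s)
    expect_equal(ls$h, s * lc$h)
    expect_equal(ls$d_U, s * lc$d_U)
    expect_equal(ls$d_S, s * lc$d_S)
    expect_identical(ls$alpha, lc$alpha)      # angles are scale-free
  }
})

test_that("Triangle collapses to two straight segments through U", {
  set.seed(59)
  for (k in seq_len(20)) {
    p <- random_pair()
    lc <- link_path(p$si, p$sj, p$c, shape_preset("Triangle"), 16)
    scale <- max(lc$d, sqrt(sum(p$si^2)), sqrt(sum(p$sj^2)))
    seg_dist <- function(pt, a, b) {
      ab <- b - a
      t <- max(0, min(1, sum((pt - a) * ab) / sum(ab * ab)))
      sqrt(sum((pt - a - t * ab)^2))
    }
    half1 <- lc$polyline[1:17, ]
    half2 <- lc$polyline[17:33, ]
    d1 <- apply(half1, 1, seg_dist, a = p$si, b = lc$U)
    d2 <- apply(half2, 1, seg_dist, a = lc$U, b = p$sj)
    expect_lt(max(d1, d2), 1e-12 * scale)
  }
})

test_that("link radius follows the clamped inverse-distance law", {
  expect_equal(link_radius(2, scale = 1, r_min = 0.01, r_max = 10), 0.5)
  expect_equal(link_radius(1e-9, scale = 1, r_min = 0.01, r_max = 10), 10)
  expect_equal(link_radius(1e9, scale = 1, r_min = 0.01, r_max = 10), 0.01)
  d <- seq(0.01, 100, length.out = 500)
  r <- link_radius(d, scale = 2, r_min = 0.05, r_max = 3)
  expect_true(all(diff(r) <= 0))            # monotone non-increasing
  expect_true(all(r >= 0.05 & r <= 3))
  expect_error(link_radius(0), "positive")
  expect_error(link_radius(-1), "positive")
  expect_identical(link_color_scalar(2), 2)
})

test_that("degree bars point radially away from the reference point", {
  bar <- degree_bar(c(0, 2, 0), c(0, 0, 0), degree = 3, bar_scale = 0.1)
  expect_equal(bar$base, c(0, 2, 0))
  expect_equal(bar$tip, c(0, 2.3, 0))
  expect_null(degree_bar(c(1, 1, 1), c(0, 0, 0), 0, 0.1))
  # nodes on a sphere centered at C: bars perpendicular to the surface
  net <- sphere_ba_network(40, 2, seed = 9)
  ctr <- c(0, 0, 0)
  deg <- node_degrees(net)
  for (v in seq_len(40)) {
    bar <- degree_bar(net$coords[v, ], ctr, deg[v], 0.05)
    dir <- (bar$tip - bar$base)
    dir <- dir / sqrt(sum(dir^2))
    radial <- net$coords[v, ] / sqrt(sum(net$coords[v, ]^2))
    expect_equal(sum(dir * radial), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum((bar$tip - bar$base)^2)), 0.05 * deg[v],
                 tolerance = 1e-12)
  }
})

test_that("barycenter is the row mean and rejects empty input", {
  expect_equal(barycenter(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0),
               ignore_attr = TRUE)
  expect_equal(barycenter(rbind(c(3, -1, 2))), c(3, -1, 2),
               ignore_attr = TRUE)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(barycenter(cube), c(0.5, 0.5, 0.5), ignore_attr = TRUE)
  expect_error(barycenter(matrix(0, 0, 3)), "empty")
})
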