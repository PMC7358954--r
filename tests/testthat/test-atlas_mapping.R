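test_that("plane construction and distance behave analytically", {
  pl <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(pl$normal), c(0, 0, 1))
  expect_equal(pl$offset, 0)
  # axial plane at VERT -4.5: unit normal, sigma = 4.5
  ax <- plane_from_points(c(0, 0, -4.5), c(1, 0, -4.5), c(0, 1, -4.5))
  expect_equal(abs(ax$normal[3]), 1)
  expect_equal(abs(ax$offset), 4.5)
  expect_error(plane_from_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
  # permutation invariance (up to normal sign): same point-set solution
  set.seed(41)
  P <- stats::rnorm(3); Q <- stats::rnorm(3); R <- stats::rnorm(3)
  pl1 <- plane_from_points(P, Q, R)
  pl2 <- plane_from_points(R, P, Q)
  s <- sign(sum(pl1$normal * pl2$normal))
  expect_lt(max(abs(pl1$normal - s * pl2$normal)), 1e-9)
  expect_lt(abs(pl1$offset - s * pl2$offset), 1e-9)
})

cross_prod_helper <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("point-plane distance and projection are mutually consistent", {
  ax <- plane_from_points(c(0, 0, -4.5), c(1, 0, -4.5), c(0, 1, -4.5))
  E <- point3(-4.4, -10.3, -4.2, "anatomical")
  expect_lt(abs(point_plane_distance(ax, E) - 0.3), 1e-12)
  proj <- project_point_to_plane(ax, E)
  expect_point_equal(proj, c(-4.4, -10.3, -4.5), 1e-12)

  set.seed(43)
  for (i in 1:10) {
    pl <- plane(stats::rnorm(3), stats::rnorm(1))
    p <- stats::rnorm(3, sd = 10)
    pr <- as.numeric(project_point_to_plane(pl, p))
    expect_lt(abs(point_plane_distance(pl, pr)), 1e-9)          # on plane
    expect_lt(abs(point_plane_distance(pl, p) -
                  sqrt(sum((p - pr)^2))), 1e-9)                 # zeta = ||E - proj||
    pr2 <- as.numeric(project_point_to_plane(pl, pr))
    expect_lt(max(abs(pr2 - pr)), 1e-9)                         # idempotent
    # displacement parallel to the normal
    disp <- p - pr
    expect_lt(max(abs(cross_prod_helper(disp, pl$normal))), 1e-9)
  }
})

test_that("closest slice matches the worked example and a brute-force scan", {
  stack <- synthetic_axial_stack()
  hit <- closest_slice(stack, point3(-4.4, -10.3, -4.2, "anatomical"))
  expect_identical(hit$slice$id, "axial_-4.5")
  expect_lt(abs(hit$distance - 0.3), 1e-12)
  expect_point_equal(hit$projected, c(-4.4, -10.3, -4.5), 1e-12)

  on_slice <- closest_slice(stack, point3(1, 2, 2.7, "anatomical"))
  expect_identical(on_slice$slice$id, "axial_+2.7")
  expect_lt(on_slice$distance, 1e-12)

  expect_error(closest_slice(list(), point3(0, 0, 0)), "empty")

  set.seed(47)
  for (i in 1:5) {
    verts <- sort(stats::runif(sample(3:50, 1), -20, 20))
    st <- synthetic_axial_stack(verts)
    E <- stats::rnorm(3, sd = 10)
    got <- closest_slice(st, E)
    zetas <- vapply(st, function(s) point_plane_distance(s$plane, E),
                    numeric(1))
    expect_equal(got$distance, min(zetas))
    expect_identical(got$slice$id, st[[which.min(zetas)]]$id)
  }
})

test_that("screen matrix solve satisfies its anchor constraints", {
  # identity-embedding anchors: screen (u, v) is world (u, v, 0)
  sl0 <- atlas_slice("flat", anchors_world = rbind(c(0, 0, 0), c(1, 0, 0),
                                                   c(0, 1, 0)),
                     anchors_screen = rbind(c(0, 0), c(1, 0), c(0, 1)))
  sl0 <- solve_screen_matrix(sl0)
  w <- screen_to_world(sl0, 0.3, 0.6)
  expect_point_equal(w, c(0.3, 0.6, 0), 1e-12)

  set.seed(53)
  for (i in 1:5) {
    # rotated/translated anchors off any coordinate plane
    R <- random_rotation()
    base <- rbind(c(0, 0, 5), c(40, 0, 5), c(0, 40, 5))
    aw <- t(apply(base, 1, function(v) drop(R %*% v) + c(3, -2, 7)))
    as_ <- rbind(c(12, 330), c(410, 330), c(12, 25))
    sl <- atlas_slice(i, anchors_world = aw, anchors_screen = as_)
    sl <- solve_screen_matrix(sl)
    # anchors round-trip both directions
    for (j in 1:3) {
      uv <- world_to_screen(sl, aw[j, ])
      expect_lt(max(abs(uv - as_[j, ])), 1e-6)
      expect_point_equal(screen_to_world(sl, as_[j, 1], as_[j, 2]), aw[j, ],
                         1e-6)
    }
    # oracle: independent least-squares solve of [U V 1] M = world
    M_or <- qr.solve(cbind(as_, 1), aw)
    expect_lt(max(abs(sl$screen_matrix - M_or)), 1e-6)
    # random screen points land on the slice plane; round trip
    for (k in 1:3) {
      uv <- stats::runif(2, 0, 400)
      wpt <- screen_to_world(sl, uv[1], uv[2])
      expect_lt(point_plane_distance(sl$plane, wpt), 1e-8)
      expect_lt(max(abs(world_to_screen(sl, wpt) - uv)), 1e-6)
    }
  }
})

test_that("singular screen matrix falls back to the in-plane 2D solve", {
  # axial slice at z = 0: world third column all zero, M singular
  mk <- function(z) atlas_slice(z,
    anchors_world = rbind(c(0, 0, z), c(50, 0, z), c(0, 50, z)),
    anchors_screen = rbind(c(10, 20), c(210, 20), c(10, 220)))
  s0 <- solve_screen_matrix(mk(0))
  expect_lt(abs(det(s0$screen_matrix)), 1e-9)
  s5 <- solve_screen_matrix(mk(5))
  expect_gt(abs(det(s5$screen_matrix)), 1e-9)

  # both paths agree on anchors and on arbitrary in-plane points
  for (j in 1:3) {
    uv0 <- world_to_screen(s0, s0$anchors_world[j, ])
    expect_lt(max(abs(uv0 - s0$anchors_screen[j, ])), 1e-9)
  }
  for (ap in c(-3.7, 12)) {
    p0 <- c(ap, 4.2, 0); p5 <- c(ap, 4.2, 5)
    uv0 <- world_to_screen(s0, p0)
    uv5 <- world_to_screen(s5, p5)
    expect_lt(max(abs(uv0 - uv5)), 1e-9)   # same in-plane geometry
    expect_point_equal(screen_to_world(s0, uv0[1], uv0[2]), p0, 1e-9)
  }
})

test_that("line-plane intersection solves the parametric substitution", {
  ax <- plane_from_points(c(0, 0, -4.5), c(1, 0, -4.5), c(0, 1, -4.5))
  vline <- parametric_line(c(-4.4, -10.3, 0), c(0, 0, 1))
  expect_point_equal(line_plane_intersection(vline, ax),
                     c(-4.4, -10.3, -4.5), 1e-12)
  inplane <- parametric_line(c(0, 0, -4.5), c(1, 1, 0))
  expect_error(line_plane_intersection(inplane, ax), "in the plane")
  parallel <- parametric_line(c(0, 0, 0), c(1, 1, 0))
  expect_error(line_plane_intersection(parallel, ax), "parallel")

  set.seed(59)
  for (i in 1:10) {
    pl <- plane(stats::rnorm(3), stats::rnorm(1))
    ln <- parametric_line(stats::rnorm(3, sd = 5), stats::rnorm(3))
    got <- tryCatch(line_plane_intersection(ln, pl), error = function(e) NULL)
    if (is.null(got)) next
    g <- as.numeric(got)
    expect_lt(point_plane_distance(pl, g), 1e-9)
    # on the line: 1D root oracle along the parameter
    q <- sum((g - ln$point) * ln$direction) / sum(ln$direction^2)
    expect_lt(max(abs(ln$point + q * ln$direction - g)), 1e-9)
    # when the direction equals the normal, equals the projection
    ln2 <- parametric_line(ln$point, pl$normal)
    expect_point_equal(line_plane_intersection(ln2, pl),
                       project_point_to_plane(pl, ln$point), 1e-9)
  }
})

test_that("AP scaling anchors at the mid-commissural origin", {
  p <- point3(12.23, 3, -4, "anatomical")
  expect_point_equal(ap_scale_to_atlas(p, 24.45, 24.45), p, 1e-12)
  doubled <- ap_scale_to_atlas(point3(12.23, 3, -4, "anatomical"), 10, 20)
  expect_point_equal(doubled, c(24.46, 3, -4), 1e-12)
  # AC and PC map onto the atlas commissures
  for (acpc_pat in c(22, 25.016, 28)) {
    acpc_atl <- 24.0
    ac <- ap_scale_to_atlas(point3(acpc_pat / 2, 0, 0, "anatomical"),
                            acpc_pat, acpc_atl)
    expect_lt(abs(as.numeric(ac)[1] - acpc_atl / 2), 1e-9)
  }
  expect_error(ap_scale_to_atlas(p, 0, 24), "positive")
})

test_that("batch mapping equals per-point calls and preserves order", {
  stack <- synthetic_axial_stack()
  pts <- list(point3(-4.4, -10.3, -4.2, "anatomical"),
              point3(1.2, 0.4, 2.0, "anatomical"),
              point3(-0.5, 3.3, -1.0, "anatomical"))
  res <- map_points_to_stack(pts, stack)
  expect_equal(nrow(res), 3L)
  expect_identical(res$slice_id[1], "axial_-4.5")
  for (i in seq_along(pts)) {
    hit <- closest_slice(stack, pts[[i]])
    uv <- world_to_screen(hit$slice, hit$projected)
    expect_identical(res$slice_id[i], as.character(hit$slice$id))
    expect_lt(abs(res$U[i] - uv[["U"]]), 1e-12)
    expect_lt(abs(res$zeta[i] - hit$distance), 1e-12)
  }
  # shuffling inputs permutes outputs identically
  perm <- c(3, 1, 2)
  res2 <- map_points_to_stack(pts[perm], stack)
  expect_equal(res2$slice_id, res$slice_id[perm])
  expect_equal(res2$U, res$U[perm])
})
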