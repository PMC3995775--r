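test_that("scapular plane contains its three defining landmarks", {
  pts <- list(
    inferior_angle = c(0, 0, 0),
    glenoid_center = c(1, 0, 0),
    medial_point = c(0, 1, 0)
  )
  pl <- scapular_plane(pts)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$origin, c(1, 0, 0))
  for (p in pts) {
    expect_lt(abs(sum((p - pl$origin) * pl$normal)), 1e-6)
  }

  # plane frame is orthonormal
  expect_equal(sum(pl$u^2), 1, tolerance = 1e-9)
  expect_equal(sum(pl$v^2), 1, tolerance = 1e-9)
  expect_lt(abs(sum(pl$u * pl$v)), 1e-9)
  expect_lt(abs(sum(pl$u * pl$normal)), 1e-9)
})

test_that("scapular plane follows rigid motions of the landmarks", {
  set.seed(41)
  for (i in 1:20) {
    pts <- fixture_points(
      vault = runif(1, -20, 60), offset = runif(1, -15, 15),
      inclination = runif(1, 0, 30)
    )
    rot <- rand_rotation()
    tr <- runif(3, -100, 100)
    moved <- sweep(pts %*% t(rot), 2, tr, "+")
    pl <- scapular_plane(moved)
    for (nm in c("inferior_angle", "glenoid_center", "medial_point")) {
      expect_lt(abs(sum((moved[nm, ] - pl$origin) * pl$normal)), 1e-6)
    }
  }
})

test_that("collinear or coincident scapular landmarks raise a degenerate-geometry error", {
  expect_error(
    scapular_plane(list(
      inferior_angle = c(0, 0, 0),
      glenoid_center = c(1, 1, 1),
      medial_point = c(2, 2, 2)
    )),
    class = "gv_degenerate_geometry"
  )
  expect_error(
    scapular_plane(list(
      inferior_angle = c(1, 2, 3),
      glenoid_center = c(1, 2, 3),
      medial_point = c(4, 5, 6)
    )),
    class = "gv_degenerate_geometry"
  )
})

test_that("corrected slice contains the axis, is perpendicular to the scapular plane, and is oriented anatomically", {
  set.seed(42)
  for (i in 1:20) {
    pts <- fixture_points(
      vault = runif(1, -20, 60), offset = runif(1, -15, 15),
      inclination = runif(1, 0, 30),
      side = sample(c("left", "right"), 1)
    )
    rot <- rand_rotation()
    moved <- sweep(pts %*% t(rot), 2, runif(3, -50, 50), "+")
    scap <- scapular_plane(moved)
    sl <- corrected_slice(moved, scap)
    # contains glenoid center (origin) and medial point
    expect_lt(abs(sum((moved["medial_point", ] - sl$origin) * sl$normal)), 1e-6)
    # perpendicular planes: normals orthogonal
    expect_lt(abs(sum(sl$normal * scap$normal)), 1e-9)
    # u points medial -> lateral
    axis <- moved["glenoid_center", ] - moved["medial_point", ]
    expect_gt(sum(sl$u * axis), 0)
    # v oriented anteriorly: anterior rim projects above posterior rim
    pr <- project_to_slice(moved[c("anterior_rim", "posterior_rim"), ], sl)
    expect_gte(pr["anterior_rim", "y"], pr["posterior_rim", "y"])
  }
})

test_that("corrected slice with coincident axis endpoints errors", {
  pts <- fixture_points()
  pts["medial_point", ] <- pts["glenoid_center", ]
  expect_error(
    corrected_slice(pts, scapular_plane(fixture_points())),
    class = "gv_degenerate_geometry"
  )
})

test_that("projection drops the normal component and round-trips in-plane points", {
  pl <- new_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(unname(project_to_slice(c(3, 4, 5), pl)), c(3, 4))

  # in-plane points reconstruct exactly
  xy <- c(-7.25, 11.5)
  p3 <- slice_to_world(xy, pl)
  expect_equal(unname(project_to_slice(p3, pl)), xy, tolerance = 1e-9)
})

test_that("projection matches a least-squares oracle on random planes", {
  set.seed(43)
  for (i in 1:25) {
    o <- rnorm(3, sd = 20)
    r <- rand_rotation()
    pl <- new_plane(o, r[, 1], r[, 2])
    p <- rnorm(3, sd = 30)
    # oracle: least-squares coefficients of (p - o) on the basis [u v]
    basis <- cbind(pl$u, pl$v)
    ls <- qr.solve(basis, p - o)
    expect_equal(unname(project_to_slice(p, pl)), unname(ls), tolerance = 1e-9)
    # reconstructed point is the closest in-plane point
    q <- slice_to_world(ls, pl)
    expect_lt(abs(sum((p - q) * pl$u)), 1e-9)
    expect_lt(abs(sum((p - q) * pl$v)), 1e-9)
  }
})

test_that("signed version angle recovers constructed angles with the retroversion sign", {
  axis_o <- c(-30, 0)
  axis_e <- c(0, 0)
  for (theta in 1:45) {
    th <- theta * pi / 180
    ant <- 14 * c(sin(th), cos(th))
    post <- -ant
    expect_equal(
      signed_version_angle(ant, post, axis_o, axis_e), theta,
      tolerance = 1e-9
    )
    # anatomical mirror image: rims reflected across the axis, then
    # relabelled so the rim now on the anterior side is called anterior
    mirrored_ant <- c(post[1], -post[2])
    mirrored_post <- c(ant[1], -ant[2])
    expect_equal(
      signed_version_angle(mirrored_ant, mirrored_post, axis_o, axis_e),
      -theta,
      tolerance = 1e-9
    )
  }
})

test_that("glenoid line perpendicular to the axis gives zero version", {
  expect_equal(
    signed_version_angle(c(0, 14), c(0, -14), c(-30, 0), c(0, 0)),
    0
  )
})

test_that("the anterior/posterior labels, not the geometry, carry the sign", {
  ant <- 14 * c(sin(0.2), cos(0.2))
  post <- -ant
  v <- signed_version_angle(ant, post, c(-30, 0), c(0, 0))
  # swapping which rim is labelled anterior negates the angle
  expect_equal(signed_version_angle(post, ant, c(-30, 0), c(0, 0)), -v)
  # reflecting the rims across the axis without relabelling keeps the sign:
  # the posterior rim is still the medial one
  expect_equal(
    signed_version_angle(ant * c(1, -1), post * c(1, -1), c(-30, 0), c(0, 0)),
    v,
    tolerance = 1e-9
  )
})

test_that("zero-length glenoid line or axis raises a degenerate-geometry error", {
  expect_error(
    signed_version_angle(c(1, 1), c(1, 1), c(-30, 0), c(0, 0)),
    class = "gv_degenerate_geometry"
  )
  expect_error(
    signed_version_angle(c(0, 14), c(0, -14), c(5, 5), c(5, 5)),
    class = "gv_degenerate_geometry"
  )
})

test_that("measured versions are invariant under rigid motion and uniform scaling", {
  set.seed(44)
  for (i in 1:10) {
    lm <- fixture_shoulder(
      vault = runif(1, -20, 60), offset = runif(1, -15, 15),
      inclination = runif(1, 0, 30),
      side = sample(c("left", "right"), 1)
    )
    base <- measure_version(lm)$version_deg
    moved <- transform_landmarks(lm, rand_rotation(), runif(3, -500, 500))
    expect_equal(measure_version(moved)$version_deg, base, tolerance = 1e-6)
    scaled <- lm
    scaled[, c("x", "y", "z")] <- scaled[, c("x", "y", "z")] * 3.7
    expect_equal(measure_version(scaled)$version_deg, base, tolerance = 1e-9)
  }
})
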