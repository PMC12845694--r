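# Five non-coplanar markers in a calibration-plate-like layout [mm].
plate_points <- function() {
  matrix(c(
    0, 0, 0,
    60, 0, 5,
    60, 60, 0,
    0, 60, 8,
    30, 30, 25
  ), ncol = 3, byrow = TRUE)
}

test_that("identity and constructed transforms are recovered exactly", {
  src <- plate_points()
  fit0 <- umeyama_rigid(src, src)
  expect_equal(fit0$R, diag(3), tolerance = 1e-12)
  expect_equal(fit0$t, rep(0, 3), tolerance = 1e-12)
  expect_equal(fit0$rmse, 0, tolerance = 1e-12)

  # 90 degree z-rotation plus translation, inverted by the fit
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  tv <- c(10, -5, 2)
  dst <- src %*% t(Rz) + rep(1, 5) %o% tv
  fit <- umeyama_rigid(src, dst)
  expect_equal(fit$R, Rz, tolerance = 1e-9)
  expect_equal(fit$t, tv, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)
})

test_that("random rigid transforms are recovered to machine precision", {
  set.seed(100)
  for (i in 1:100) {
    R <- rand_rotation()
    tv <- rnorm(3, sd = 50)
    src <- plate_points() + matrix(rnorm(15, sd = 2), 5, 3)
    dst <- src %*% t(R) + rep(1, 5) %o% tv
    fit <- umeyama_rigid(src, dst)
    expect_lt(fiducial_rmse(fit, src, dst), 1e-9)
    expect_equal(crossprod(fit$R), diag(3), tolerance = 1e-9)
    expect_equal(det(fit$R), 1, tolerance = 1e-9)
  }
})

test_that("noisy correspondences keep residuals small and rotations proper", {
  set.seed(101)
  src <- plate_points()
  dst <- src %*% t(rand_rotation()) + rep(1, 5) %o% c(5, 5, 5) +
    matrix(rnorm(15, sd = 0.1), 5, 3)
  fit <- umeyama_rigid(src, dst)
  expect_lt(fit$rmse, 0.2)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)

  # reflective configuration: mirrored destination still yields det +1
  mirr <- src
  mirr[, 1] <- -mirr[, 1]
  fitm <- umeyama_rigid(src, mirr)
  expect_equal(det(fitm$R), 1, tolerance = 1e-9)
})

test_that("overdetermination: the 5-point fit beats any 3-point subfit", {
  set.seed(102)
  for (trial in 1:5) {
    src <- plate_points()
    dst <- src %*% t(rand_rotation()) + rep(1, 5) %o% rnorm(3, sd = 20) +
      matrix(rnorm(15, sd = 0.3), 5, 3)
    full <- fiducial_rmse(umeyama_rigid(src, dst), src, dst)
    for (sub in utils::combn(5, 3, simplify = FALSE)) {
      subfit <- umeyama_rigid(src[sub, ], dst[sub, ])
      expect_lte(full, fiducial_rmse(subfit, src, dst) + 1e-12)
    }
  }
})

test_that("transform application, inversion and the similarity variant", {
  src <- plate_points()
  ident <- structure(list(R = diag(3), t = c(0, 0, 0), scale = 1),
                     class = "rigid_transform")
  expect_equal(apply_transform(ident, src), src)
  shift <- structure(list(R = diag(3), t = c(1, 2, 2), scale = 1),
                     class = "rigid_transform")
  expect_equal(as.numeric(apply_transform(shift, matrix(0, 1, 3))), c(1, 2, 2))

  R <- rand_rotation()
  fit <- umeyama_rigid(src, src %*% t(R) + rep(1, 5) %o% c(3, -4, 12))
  roundtrip <- apply_transform(invert_transform(fit), apply_transform(fit, src))
  expect_equal(roundtrip, src, tolerance = 1e-9)

  # frame tag flips on point sets
  ps <- point_set(paste0("m", 1:5), src, frame = "ct")
  out <- apply_transform(fit, ps)
  expect_equal(attr(out, "frame"), "world")

  # isotropic scale recovered when allowed, fixed to 1 otherwise
  dst2 <- 2 * (src %*% t(R)) + rep(1, 5) %o% c(1, 1, 1)
  expect_equal(umeyama_rigid(src, dst2, allow_scale = TRUE)$scale, 2,
               tolerance = 1e-9)
  expect_equal(umeyama_rigid(src, dst2)$scale, 1)
})

test_that("point error and fiducial RMSE arithmetic", {
  expect_equal(point_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(point_error(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(point_error(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_error(point_error(c(0, 0), c(1, 1, 1)), "length-3")

  # one pair off by 3 mm among 3 exact pairs: sqrt(9/4) = 1.5
  ident <- structure(list(R = diag(3), t = c(0, 0, 0), scale = 1),
                     class = "rigid_transform")
  src <- plate_points()[1:4, ]
  dst <- src
  dst[4, ] <- dst[4, ] + c(3, 0, 0)
  expect_equal(fiducial_rmse(ident, src, dst), 1.5)
  # RMSE >= any individual residual / sqrt(N)
  expect_gte(fiducial_rmse(ident, src, dst), 3 / sqrt(4) - 1e-12)
})

test_that("degenerate geometry and label mismatches are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(umeyama_rigid(line, line), "collinear")
  dup <- plate_points()
  dup[2, ] <- dup[1, ]
  expect_error(umeyama_rigid(dup, dup), "coincident")
  expect_error(umeyama_rigid(plate_points(), plate_points()[1:4, ]),
               "same number")

  a <- point_set(c("p1", "p2", "p3", "p4"), plate_points()[1:4, ])
  b <- point_set(c("p1", "p2", "p3", "p9"), plate_points()[1:4, ], "world")
  expect_error(umeyama_rigid(a, b), "labels")

  # label permutation is resolved by matching, not row order
  perm <- c(3, 1, 4, 2, 5)
  ps_src <- point_set(paste0("q", 1:5), plate_points())
  ps_dst <- point_set(paste0("q", perm), plate_points()[perm, ], "world")
  fit <- umeyama_rigid(ps_src, ps_dst)
  expect_lt(fit$rmse, 1e-9)
})
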