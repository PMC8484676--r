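test_that("identical uniform frames give a vanishing wave vector", {
  f <- matrix(0.5, 21, 21)
  wf <- wave_vector_field(f, f, params = wave_params(tau_c = 1, T_av = 1))
  # symmetric contributions cancel at interior pixels: flagged invalid
  expect_false(any(wf$valid[5:17, 5:17]))
  expect_equal(max(wf$magnitude[5:17, 5:17]), 0, tolerance = 1e-12)
})

test_that("plane-wave direction is recovered within 10 degrees", {
  wp <- wave_params(w_c = 5, tau_c = 1, n = 5, T_av = 1)
  for (ang in c(0, pi / 4)) {
    mv <- plane_wave_movie(size = 48, n_frames = 3, wavelength = 12,
                           speed = 2, direction = ang)
    wf <- wave_vector_field(mv$movie[, , 1], mv$movie[, , 2], params = wp)
    core <- wf$theta[10:39, 10:39][wf$valid[10:39, 10:39]]
    expect_angle_close(circular_mean(core), ang)
  }
})

test_that("rotating the movie by 90 degrees rotates the estimate", {
  wp <- wave_params(w_c = 5, tau_c = 1, n = 5, T_av = 1)
  mv <- plane_wave_movie(size = 48, n_frames = 3, wavelength = 12,
                         speed = 2, direction = 0)
  rot <- function(m) t(m)[, nrow(m):1]  # 90-degree rotation
  wf <- wave_vector_field(rot(mv$movie[, , 1]), rot(mv$movie[, , 2]),
                          params = wp)
  core <- wf$theta[10:39, 10:39][wf$valid[10:39, 10:39]]
  # this rotation maps (x, y) -> (-y, x): +x propagation becomes +y
  expect_angle_close(circular_mean(core), pi / 2)
})

test_that("running circular mean handles wraparound and equivariance", {
  th1 <- matrix(2 * pi - 0.1, 4, 4)
  th2 <- matrix(0.1, 4, 4)
  out <- running_circular_mean(list(angle_map(th1), angle_map(th2)), 2)
  expect_equal(length(out), 1L)
  expect_equal(out[[1]]$theta, matrix(0, 4, 4), tolerance = 1e-12)
  # constant input is reproduced
  cst <- running_circular_mean(list(angle_map(matrix(1, 4, 4)),
                                    angle_map(matrix(1, 4, 4))), 2)
  expect_equal(cst[[1]]$theta, matrix(1, 4, 4))
  # shifting every angle shifts the mean (mod 2*pi)
  d <- 0.7
  sh <- running_circular_mean(list(angle_map(th1 + d), angle_map(th2 + d)),
                              2)
  expect_equal(sh[[1]]$theta, matrix(d, 4, 4), tolerance = 1e-12)
})

test_that("moving-edge masks restrict the average to their intersection", {
  masks <- moving_edge_masks(size = 20, n_frames = 4, erode_every = 1)
  maps <- lapply(1:4, function(i) angle_map(matrix(0.5, 20, 20)))
  out <- running_circular_mean(maps, 4, masks)
  # valid exactly on the smallest (latest) mask
  expect_equal(out[[1]]$valid, masks[[4]] != 0)
})

test_that("angle-gradient map ridges sit on direction interfaces", {
  th <- matrix(0, 30, 30)
  th[, 16:30] <- pi  # two half-planes with opposite directions
  g <- angle_gradient_map(angle_map(th))
  expect_true(all(g >= 0))
  expect_gt(mean(g[5:25, 15:17]), 10 * mean(g[5:25, 5:10]) + 1e-12)
  # uniform field: no gradient anywhere
  expect_equal(angle_gradient_map(angle_map(matrix(1.2, 30, 30))),
               matrix(0, 30, 30), tolerance = 1e-12)
})

test_that("cyclic colormap wraps and marks invalid pixels", {
  th <- matrix(c(0, 2 * pi - 1e-9, pi, pi / 2), 2, 2)
  valid <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  img <- export_angle_colormap(angle_map(th, valid))
  expect_equal(img[1, 1, ], img[2, 1, ], tolerance = 1e-6)  # 0 == 2*pi
  expect_equal(img[1, 2, ], rep(0.5, 3))                    # neutral invalid
})
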