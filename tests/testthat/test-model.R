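test_that("reaction rate matches hand-evaluated cases and quasi-positivity", {
  p <- model_params(k0 = 0.2, gamma = 1, A0 = 0.4, s1 = 0.5, s2 = 0.8,
                    F0 = 0.5)
  # all Hill terms vanish at A = F = 0: only basal activation survives
  expect_equal(reaction_rate(0, 1, 0, p), 0.2)
  # at A = 0 the rate is k0 * I >= 0 for any I (quasi-positivity)
  for (I in c(0, 0.3, 1, 7))
    expect_equal(reaction_rate(0, I, 0, p), 0.2 * I)
  # half-saturation of both Hill terms: f = (0.2 + 0.5)*1 - (0.5 + 0.4)*0.4
  expect_equal(reaction_rate(0.4, 1, 0.5, p), 0.34)
  # vectorized evaluation agrees with scalar calls
  A <- c(0, 0.4, 1); I <- c(1, 1, 0.5); F <- c(0, 0.5, 2)
  expect_equal(reaction_rate(A, I, F, p),
               vapply(1:3, function(i) reaction_rate(A[i], I[i], F[i], p),
                      numeric(1)))
  expect_error(reaction_rate(-1, 1, 0, p), "nonnegative")
})

test_that("masked Laplacian: constant fields, delta stencil, zero net flux", {
  m <- make_mask("square", 12)
  expect_equal(masked_laplacian(matrix(3.7, 12, 12), m, 0.02),
               matrix(0, 12, 12))
  # interior delta on a full mask reproduces the five-point stencil
  full <- matrix(1L, 9, 9)
  f <- matrix(0, 9, 9); f[5, 5] <- 1
  h <- 0.5
  L <- masked_laplacian(f, full, h)
  expect_equal(L[5, 5], -4 / h^2)
  expect_equal(L[4, 5], 1 / h^2)
  expect_equal(L[6, 5], 1 / h^2)
  expect_equal(L[5, 4], 1 / h^2)
  expect_equal(L[5, 6], 1 / h^2)
  expect_equal(sum(L), 0)
  expect_error(masked_laplacian(matrix(0, 3, 3), matrix(1L, 4, 4)),
               "shape")
})

test_that("noise with repair conserves the A+I pair and clamps F", {
  m <- make_mask("square", 22)
  st <- make_initial_state("homogeneous", m)
  # zero noise leaves the state untouched
  st2 <- apply_noise_with_repair(st, 0, 0, 0.001, m)
  expect_identical(st2$A, st$A)
  expect_identical(st2$I, st$I)
  # strong noise: pairwise mass exactly preserved, no negatives
  st$A[m != 0] <- 1e-20  # essentially every negative draw triggers repair
  st$I[m != 0] <- 1
  set.seed(5)
  st3 <- apply_noise_with_repair(st, 50, 50, 0.001, m)
  expect_equal(st3$A + st3$I, st$A + st$I, tolerance = 1e-14)
  expect_true(all(st3$A[m != 0] >= 0))
  expect_true(all(st3$I[m != 0] >= 0))
  expect_true(all(st3$F[m != 0] >= 0))
  expect_true(any(st3$A[m != 0] == 0))  # repairs actually happened
})

test_that("single-pixel repair arithmetic follows the overshoot rule", {
  # A = 1e-20 receiving increment -1e-3: A -> 0, partner absorbs the deficit
  m <- matrix(0L, 3, 3); m[2, 2] <- 1L
  st <- structure(list(A = matrix(1e-20, 3, 3) * (m == 1),
                       I = matrix(1, 3, 3) * (m == 1),
                       F = matrix(0, 3, 3), t = 0), class = "cw_state")
  # find a seed whose first draw is negative, then trace the rule
  set.seed(2)
  xi <- rnorm(1)
  expect_lt(xi, 0)
  alpha <- 1e-3 / abs(xi) / 0.001  # makes the increment exactly -1e-3
  set.seed(2)
  out <- apply_noise_with_repair(st, alpha, 0, 0.001, m)
  expect_equal(out$A[2, 2], 0)
  # pre-repair I was 1 + 1e-3; the repair adds the overshoot 1e-20 - 1e-3,
  # so the pair sum is exactly the initial 1 + 1e-20
  expect_equal(out$I[2, 2], (1 + 1e-3) + (1e-20 - 1e-3))
  expect_equal(out$A[2, 2] + out$I[2, 2], 1 + 1e-20)
})

test_that("stability ratio arithmetic and the run-time guard", {
  m <- make_mask("square", 10)
  p <- model_params()
  expect_equal(stability_ratio(p, grid_spec(m)), (0.1 / 3) * 0.001 / 0.02^2)
  expect_lt(stability_ratio(p, grid_spec(m)), 0.5)
  expect_equal(stability_ratio(p, grid_spec(m, dt = 0)), 0)
  g_bad <- grid_spec(m, dt = 0.01)
  expect_gt(stability_ratio(p, g_bad), 0.5)
  expect_error(run_simulation(p, g_bad, duration = 1), "unstable")
})

test_that("masks: square padding, rotationally symmetric circle, irregular", {
  sq <- make_mask("square", 202)
  expect_equal(dim(sq), c(202, 202))
  expect_equal(sum(sq), 200^2)
  expect_true(all(sq[1, ] == 0) && all(sq[, 202] == 0))
  ci <- make_mask("circle", 4)
  expect_equal(sum(ci), 4)  # central 2x2 disk approximation
  expect_equal(ci, ci[4:1, ])          # symmetric under flips
  expect_equal(ci, t(ci))              # and under 90-degree rotation
  big <- make_mask("circle", 40)
  expect_equal(unclass(big), unclass(big[40:1, ]))
  # an all-white image reduces to the square case
  irr <- make_mask("irregular", 30, image = matrix(1, 50, 50))
  expect_equal(irr, make_mask("square", 30))
  expect_error(make_mask("irregular", 30, image = "no_such_file.png"))
})

test_that("initial states carry unit mean mass over the mask", {
  m <- make_mask("square", 202)
  hom <- make_initial_state("homogeneous", m)
  expect_equal(sum(hom$A[m != 0] + hom$I[m != 0]), 200^2)
  spk <- make_initial_state("center_spike", m)
  expect_equal(mean(spk$A[m != 0] + spk$I[m != 0]), 1)
  expect_equal(sum(spk$A == 5), 100)
  set.seed(1)
  rp <- make_initial_state("random_perturbation", m, eps = 1e-4)
  expect_equal(rp$A[m != 0] + rp$I[m != 0], rep(1, sum(m)))
  expect_true(all(rp$A[m != 0] >= 0))
  # spike must fit inside the mask
  expect_error(make_initial_state("center_spike", make_mask("square", 8)),
               "spike")
})

test_that("one Euler step on a homogeneous state is the forced update", {
  m <- make_mask("square", 22)
  g <- grid_spec(m)
  p <- model_params(k0 = 0.2, s2 = 0.8, alpha1 = 0, alpha2 = 0)
  st <- make_initial_state("homogeneous", m)
  out <- euler_step(st, p, g)
  # A <- 0 + dt * k0 * I = 0.0002 everywhere on the mask (Laplacian zero)
  expect_equal(out$A[m != 0], rep(2e-4, sum(m)))
  expect_equal(out$I[m != 0], rep(1 - 2e-4, sum(m)))
  expect_equal(out$F[m != 0], rep(0, sum(m)))
  expect_equal(out$A[m == 0], rep(0, sum(m == 0)))  # background untouched
})

test_that("compiled core reproduces the R reference step exactly (no noise)", {
  m <- make_mask("circle", 30)
  g <- grid_spec(m, save_every = 1)
  p <- model_params(k0 = 0.25, s2 = 1.0, alpha1 = 0, alpha2 = 0)
  st <- make_initial_state("center_spike", m)
  ref <- euler_step(st, p, g)
  sim <- run_simulation(p, g, init = st, duration = g$dt,
                        fields = c("A", "I", "F"))
  expect_equal(sim$A[, , 2], ref$A, tolerance = 1e-15)
  expect_equal(sim$I[, , 2], ref$I, tolerance = 1e-15)
  expect_equal(sim$F[, , 2], ref$F, tolerance = 1e-15)
})

test_that("simulations are mass-conserving, positive and deterministic", {
  m <- make_mask("circle", 52)
  g <- grid_spec(m)
  p <- model_params(k0 = 0.2, s2 = 0.8, alpha1 = 1, alpha2 = 0.1)
  sim <- run_simulation(p, g, duration = 30, seed = 42)
  dev <- abs(sim$audit$mass / sim$audit$mass[1] - 1)
  expect_true(all(dev <= 1e-11))
  expect_true(all(sim$audit[, c("min_A", "min_I", "min_F")] >= 0))
  # bit-identical repeat with the same seed
  sim2 <- run_simulation(p, g, duration = 30, seed = 42)
  expect_identical(sim$A, sim2$A)
  expect_identical(sim$audit, sim2$audit)
  # different seed diverges
  sim3 <- run_simulation(p, g, duration = 30, seed = 43)
  expect_false(identical(sim$A, sim3$A))
  # duration 0 keeps only the initial state
  sim0 <- run_simulation(p, g, duration = 0, seed = 1)
  expect_equal(length(sim0$times), 1L)
})

test_that("extend_simulation continues a run bit-exactly", {
  m <- make_mask("square", 32)
  g <- grid_spec(m)
  p <- model_params(k0 = 0.2, s2 = 1.1, alpha1 = 0.5, alpha2 = 0.05)
  whole <- run_simulation(p, g, duration = 10, seed = 9)
  part <- run_simulation(p, g, duration = 4, seed = 9)
  part <- extend_simulation(part, 6)
  expect_equal(part$times, whole$times)
  expect_identical(part$A, whole$A)
  expect_identical(part$audit, whole$audit)
})
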