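make_fake_sim <- function(frames, times = seq_along(frames) - 1,
                          mask = NULL) {
  # wrap a list of matrices as a minimal rd_sim for the analysis functions
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  if (is.null(mask)) mask <- matrix(1L, nr, nc)
  A <- array(0, dim = c(nr, nc, length(frames)))
  for (i in seq_along(frames)) A[, , i] <- frames[[i]]
  amp <- vapply(frames, function(f) max(f[mask != 0]) - min(f[mask != 0]),
                numeric(1))
  audit <- data.frame(t = times, mass = 1,
                      min_A = vapply(frames, function(f) min(f[mask != 0]), numeric(1)),
                      max_A = vapply(frames, function(f) max(f[mask != 0]), numeric(1)),
                      min_I = 0, max_I = 1, min_F = 0, max_F = 0)
  structure(list(times = times, A = A, audit = audit,
                 grid = grid_spec(mask), params = model_params(),
                 scaling = scaling_factors(), fields = "A"),
            class = "rd_sim")
}

test_that("pattern amplitude: flat, binary and exponential traces", {
  m <- matrix(1L, 8, 8)
  flat <- matrix(0.3, 8, 8)
  half <- matrix(rep(c(0, 1), each = 32), 8, 8)
  sim <- make_fake_sim(list(flat, half))
  tr <- pattern_amplitude(sim)
  expect_equal(tr$amp, c(0, 1))
  expect_true(is.na(tr$log_amp[1]) && tr$log_amp[2] == 0)
})

test_that("stage detection recovers the kink of a piecewise trace", {
  t <- seq(0, 1500, by = 10)
  amp <- ifelse(t < 1000, 1e-6 * exp(0.01 * t), 1e-6 * exp(10))
  trace <- data.frame(t = t, amp = amp, log_amp = log(amp))
  st <- detect_stages(trace, smooth_window = 1)
  expect_equal(st$T_g, 1000)
  expect_equal(st$T_g_s, 1000 * 0.83)
  expect_true(all(which(st$stage == "low") < min(which(st$stage == "high"))))
  # positive rescaling of the amplitude shifts the log but not the slope
  trace2 <- transform(trace, amp = 37 * amp, log_amp = log(37 * amp))
  expect_equal(detect_stages(trace2, smooth_window = 1)$T_g, 1000)
  # constant trace: no growth stage
  flat <- data.frame(t = t, amp = 1, log_amp = 0)
  expect_true(is.na(detect_stages(flat)$T_g))
})

test_that("temporal autocorrelation: self, negation, boundedness", {
  set.seed(3)
  base <- matrix(runif(400), 20, 20)
  frames <- list(base, 2 * mean(base) - base, base + 0.1)
  sim <- make_fake_sim(frames)
  ac <- temporal_autocorrelation(sim, t_ref = 0, lags = c(0, 1, 2))
  expect_equal(ac$corr[1], 1)               # tau = 0
  expect_equal(ac$corr[2], -1)              # pixelwise negation about mean
  expect_equal(ac$corr[3], 1)               # affine shift
  expect_true(all(abs(ac$corr) <= 1 + 1e-12))
  # zero-variance frame yields NA with a warning
  sim2 <- make_fake_sim(list(base, matrix(1, 20, 20)))
  expect_warning(ac2 <- temporal_autocorrelation(sim2, 0, 1),
                 "zero-variance")
  expect_true(is.na(ac2$corr))
})

test_that("regime classification by autocorrelation swing", {
  # synthetic series whose autocorrelation is cos(2*pi*tau/P): swing 2
  t <- 0:400
  P <- 40
  nr <- 16
  xy <- outer(seq_len(nr), seq_len(nr), "+")
  frames <- lapply(t, function(tt)
    sin(2 * pi * xy / 8 + 2 * pi * tt / P))
  sim <- make_fake_sim(frames, times = t)
  rc <- classify_regime(sim, T_g = 400)  # window tau in [0, 160] at t = 200
  expect_equal(rc$label, "oscillatory")
  expect_gt(rc$autocorr_swing, 1.5)
  expect_equal(rc$period, P, tolerance = 0.1)
  # static frames stay perfectly correlated: quasi-static
  frames2 <- lapply(t, function(tt) sin(xy) + 0 * tt)
  sim2 <- make_fake_sim(frames2, times = t)
  rc2 <- classify_regime(sim2, T_g = 400)
  expect_equal(rc2$label, "quasi-static")
  expect_lt(rc2$autocorr_swing, 0.1)
  # affine rescaling of the concentrations cannot change the class
  frames3 <- lapply(frames, function(f) 1000 * f + 5)
  rc3 <- classify_regime(make_fake_sim(frames3, times = t), T_g = 400)
  expect_equal(rc3$autocorr_swing, rc$autocorr_swing, tolerance = 1e-10)
  expect_error(classify_regime(sim, T_g = 2000), "beyond")
})

test_that("oscillation period from peak spacing", {
  tau <- seq(0, 200, by = 0.5)
  curve <- data.frame(lag = tau, corr = cos(2 * pi * tau / 40))
  expect_equal(oscillation_period(curve), 40, tolerance = 1e-6)
  mono <- data.frame(lag = tau, corr = exp(-tau / 50))
  expect_true(is.na(oscillation_period(mono)))
  # small ripple below the prominence floor is not counted
  ripple <- data.frame(lag = tau,
                       corr = exp(-tau / 50) + 0.01 * cos(2 * pi * tau / 7))
  expect_true(is.na(oscillation_period(ripple)))
})

test_that("excitation measure counts strictly-above-mean area", {
  m <- matrix(1L, 10, 10)
  expect_equal(excitation_measure(matrix(2, 10, 10), m), 0)
  half <- matrix(rep(c(0, 1), each = 50), 10, 10)
  expect_equal(excitation_measure(half, m), 0.5)
  # masked pixels are excluded from both mean and area
  m2 <- m; m2[, 6:10] <- 0L
  f <- matrix(0, 10, 10); f[, 6:10] <- 100; f[1:2, 1] <- 1
  expect_equal(excitation_measure(f, m2), 2 / 50)
})
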