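test_that("circular statistics: closed form, invariance, cap", {
  expect_equal(circular_std(rep(1.3, 10)), 0)
  # two orthogonal unit vectors: Rbar = sqrt(2)/2
  expect_equal(circular_std(c(0, pi / 2)), sqrt(-2 * log(sqrt(2) / 2)),
               tolerance = 1e-12)
  expect_equal(round(circular_std(c(0, pi / 2)), 4), 0.8326)
  set.seed(7)
  a <- runif(50, 0, 2 * pi)
  expect_equal(circular_std(a), circular_std(a + 2.1), tolerance = 1e-12)
  # antipodal pair: Rbar collapses to rounding noise, std blows up ...
  expect_gt(circular_std(c(0, pi), cap = 100), 8)
  # ... and is limited by the cap
  expect_equal(circular_std(c(0, pi), cap = 5), 5)
  expect_error(circular_std(numeric(0)), "empty")
  expect_equal(circular_mean(c(2 * pi - 0.1, 0.1)), 0, tolerance = 1e-12)
})

test_that("coherence distance matches the brute-force oracle exactly", {
  dp <- domain_params(r_max = 12)
  # uniform field: r_max everywhere
  am <- angle_map(matrix(1, 15, 15))
  cm <- coherence_distance_map(am, dp)
  expect_true(all(cm == 12))
  # structured and random fields on small grids
  set.seed(11)
  fields <- list(
    { th <- matrix(0, 14, 14); th[, 8:14] <- pi; th },          # opposed halves
    { th <- matrix(0, 14, 14); th[, 8:14] <- 0.9; th },         # mild contrast
    matrix(runif(14 * 14, 0, 2 * pi), 14, 14))                  # iid angles
  for (th in fields) {
    valid <- matrix(TRUE, 14, 14)
    valid[2, 3] <- FALSE  # exercise invalid-pixel exclusion
    am <- angle_map(th, valid)
    cm <- coherence_distance_map(am, dp)
    expect_equal(unclass(cm), brute_coherence(th, valid, 0.4, 12))
  }
})

test_that("coherence distance drops at interfaces and for random angles", {
  dp <- domain_params(r_max = 15)
  th <- matrix(0, 30, 30); th[, 16:30] <- pi
  cm <- coherence_distance_map(angle_map(th), dp)
  expect_gt(cm[15, 5], cm[15, 15] + 4)   # deep inside >> at the interface
  set.seed(2)
  rnd <- coherence_distance_map(
    angle_map(matrix(runif(900, 0, 2 * pi), 30, 30)), dp)
  expect_lt(median(rnd), 2)
})

test_that("flat-merging watershed: plateaus never seed their own basins", {
  # constant map: a single region covering everything
  lab <- watershed_flat_merge(matrix(5, 10, 10))
  expect_equal(sort(unique(as.vector(lab))), 1L)
  # two separated bumps split along the valley
  x <- matrix(rep(1:20, each = 20), 20, 20)
  y <- matrix(rep(1:20, 20), 20, 20)
  bumps <- exp(-((x - 5)^2 + (y - 10)^2) / 8) +
           exp(-((x - 15)^2 + (y - 10)^2) / 8)
  lab2 <- watershed_flat_merge(bumps)
  expect_equal(length(unique(as.vector(lab2[lab2 > 0]))), 2L)
  # every valid pixel is labeled (no watershed lines)
  expect_true(all(lab2 > 0))
  # labels split the two bump centers
  expect_false(lab2[10, 5] == lab2[10, 15])
  # masked version tiles exactly the mask
  m <- make_mask("circle", 20)
  lab3 <- watershed_flat_merge(bumps, m)
  expect_true(all((lab3 > 0) == (m != 0)))
})

test_that("direction-similarity merging obeys both criteria", {
  th <- matrix(0, 20, 20)
  lab <- matrix(1L, 20, 20)
  lab[, 11:20] <- 2L
  th[, 11:20] <- 0.2
  class(lab) <- c("label_map", "matrix")
  am <- angle_map(th)
  dp <- domain_params()
  # similar angles (0 vs 0.2) and long interface: merged
  merged <- merge_similar_domains(lab, am, dp)
  expect_equal(length(unique(as.vector(merged[merged > 0]))), 1L)
  # dissimilar angles (0 vs 1.0): never merged
  th2 <- th; th2[, 11:20] <- 1.0
  kept <- merge_similar_domains(lab, angle_map(th2), dp)
  expect_equal(length(unique(as.vector(kept[kept > 0]))), 2L)
  # similar angles but single-pixel contact between large domains: kept
  lab3 <- matrix(0L, 30, 30)
  lab3[1:30, 1:14] <- 1L
  lab3[1:30, 17:30] <- 2L
  lab3[15, 15] <- 1L; lab3[15, 16] <- 1L  # one-pixel bridge toward region 2
  th3 <- matrix(0, 30, 30); th3[lab3 == 2] <- 0.1
  class(lab3) <- c("label_map", "matrix")
  kept3 <- merge_similar_domains(lab3, angle_map(th3), dp)
  expect_equal(length(unique(as.vector(kept3[kept3 > 0]))), 2L)
})

test_that("wrapped angular difference is used when merging", {
  # 0.1 and 2*pi - 0.1 differ by 0.2, not 2*pi - 0.2
  lab <- matrix(1L, 10, 10); lab[, 6:10] <- 2L
  th <- matrix(0.1, 10, 10); th[, 6:10] <- 2 * pi - 0.1
  class(lab) <- c("label_map", "matrix")
  merged <- merge_similar_domains(lab, angle_map(th), domain_params())
  expect_equal(length(unique(as.vector(merged[merged > 0]))), 1L)
})

test_that("domain statistics: areas, physical units, partition", {
  lab <- matrix(1L, 10, 10)
  lab[1:5, ] <- 2L
  stats <- domain_statistics(lab, scaling = scaling_factors(r_sc = 15.93),
                             h = 0.02)
  expect_equal(nrow(stats), 2L)
  expect_equal(sum(stats$area_px), 100)
  # 100-pixel domain at h = 0.02, r_sc = 15.93: (0.3186 um)^2 per pixel
  one <- domain_statistics(matrix(1L, 10, 10))
  expect_equal(one$area_um2, 100 * 0.3186^2, tolerance = 1e-4)
  expect_equal(attr(stats, "counts"), 2L)
})

test_that("multidomain movies are segmented into their planted regions", {
  wp <- wave_params(w_c = 5, tau_c = 1, n = 5, T_av = 10)
  mv <- multidomain_movie(size = 60, n_frames = 12, wavelength = 12,
                          speed = 2, directions = c(0, pi),
                          noise_sigma = 0.05, seed = 4)
  wd <- detect_wave_domains(mv$movie, mask = NULL, wf_params = wp,
                            dom_params = domain_params(min_area = 144))
  counts <- attr(wd$stats, "counts")
  expect_equal(counts[length(counts)], 2L)
  # recovered mean directions match the planted ones
  st <- wd$stats[wd$stats$frame == max(wd$stats$frame), ]
  found <- sort(st$mean_theta)
  expect_angle_close(found[1], 0)
  expect_angle_close(found[2], pi)
})

test_that("a single plane wave yields one domain covering the frame", {
  wp <- wave_params(w_c = 5, tau_c = 1, n = 5, T_av = 8)
  mv <- plane_wave_movie(size = 48, n_frames = 10, wavelength = 12,
                         speed = 2, direction = pi / 2)
  wd <- detect_wave_domains(mv$movie, wf_params = wp,
                            dom_params = domain_params(min_area = 100))
  counts <- attr(wd$stats, "counts")
  expect_true(all(counts == 1L))
})

test_that("spiral waves: all directions on a core ring, low core coherence", {
  mv <- spiral_movie(size = 64, n_frames = 4, wavelength = 16, speed = 2)
  wp <- wave_params(w_c = 5, tau_c = 1, n = 5, T_av = 1)
  wf <- wave_vector_field(mv$movie[, , 1], mv$movie[, , 2], params = wp)
  ctr <- (64 + 1) / 2
  x <- matrix(rep(1:64, each = 64), 64, 64) - ctr
  y <- matrix(rep(1:64, 64), 64, 64) - ctr
  ring <- sqrt(x^2 + y^2) >= 10 & sqrt(x^2 + y^2) <= 14 & wf$valid
  th <- wf$theta[ring]
  # angles on the ring span all four quadrants
  quadrant <- floor(th / (pi / 2)) %% 4
  expect_equal(sort(unique(quadrant)), 0:3)
  # and are far from unimodal: huge circular spread
  expect_gt(circular_std(th), 1)
  # coherence near the core is small compared to a plane wave
  avg <- running_circular_mean(list(wf), 1)[[1]]
  cm <- coherence_distance_map(avg, domain_params(r_max = 20))
  core <- cm[(ctr - 6):(ctr + 6), (ctr - 6):(ctr + 6)]
  expect_lt(median(core), 6)
})
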