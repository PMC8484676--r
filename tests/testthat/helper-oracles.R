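# independent brute-force oracles used to validate the optimized paths

# per-pixel, per-radius full disk scan for the coherence distance
brute_coherence <- function(theta, valid, C_cr = 0.4, r_max = 40,
                            cap = 10) {
  nr <- nrow(theta); nc <- ncol(theta)
  out <- matrix(0, nr, nc)
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (!valid[r0, c0]) next
      best <- 0
      for (rad in seq_len(r_max)) {
        angs <- c()
        for (r in max(1, r0 - rad):min(nr, r0 + rad))
          for (c in max(1, c0 - rad):min(nc, c0 + rad))
            if (valid[r, c] && (r - r0)^2 + (c - c0)^2 <= rad^2)
              angs <- c(angs, theta[r, c])
        if (circular_std(angs, cap) < C_cr) best <- rad else break
      }
      out[r0, c0] <- best
    }
  }
  out
}

# random mask with a guaranteed zero border and at least one active pixel
random_mask <- function(nr, nc, p = 0.7) {
  m <- matrix(as.integer(stats::runif(nr * nc) < p), nr, nc)
  m[1, ] <- 0L; m[nr, ] <- 0L; m[, 1] <- 0L; m[, nc] <- 0L
  if (sum(m) == 0) m[2, 2] <- 1L
  m
}

expect_angle_close <- function(est, truth, tol_deg = 10) {
  d <- abs(est - truth) %% (2 * pi)
  d <- min(d, 2 * pi - d)
  expect_lt(d, tol_deg * pi / 180)
}
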