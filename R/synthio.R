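#' Synthetic plane-wave movie
#'
#' Traveling sinusoidal plane-wave train with known direction:
#' `I(x, y, t) = (1 + sin(2*pi*(k.(x,y) - speed*t)/wavelength))/2 + noise`,
#' with `k = (cos(direction), sin(direction))` in image coordinates
#' (x along columns, y along rows, y increasing downward). With zero noise
#' each frame equals the previous one translated by `speed` pixels along
#' `k`. Ground truth is the constant direction angle.
#'
#' @param size Frame side (pixels).
#' @param n_frames Number of frames.
#' @param wavelength Wavelength (pixels, > 2).
#' @param speed Propagation speed (pixels per frame; must be below
#'   `wavelength / 2` to avoid temporal aliasing).
#' @param direction Propagation angle (radians).
#' @param noise_sigma Additive Gaussian noise level.
#' @param seed Seed for the noise.
#' @return List of class `synthetic_movie`: `movie` (3-d array),
#'   `theta_truth` (`angle_map`), `labels_truth`, and the echoed `spec`.
#' @export
plane_wave_movie <- function(size = 64, n_frames = 20, wavelength = 16,
                             speed = 2, direction = 0, noise_sigma = 0,
                             seed = 1) {
  check_wave_spec(wavelength, speed)
  layout <- matrix(1L, size, size)
  multidomain_movie(size = size, n_frames = n_frames,
                    wavelength = wavelength, speed = speed,
                    directions = direction, layout = layout,
                    noise_sigma = noise_sigma, seed = seed)
}

check_wave_spec <- function(wavelength, speed) {
  if (wavelength <= 2) stop("'wavelength' must exceed 2 pixels")
  if (speed >= wavelength / 2)
    stop("'speed' must be below wavelength/2 per frame (aliasing)")
}

#' Synthetic multi-domain movie with planted ground truth
#'
#' Each region of `layout` carries an independent plane-wave train with its
#' own propagation direction; the planted label map and per-region angles
#' are returned alongside, so segmentation accuracy can be scored without
#' manual annotation. A single-region layout reduces to
#' [plane_wave_movie()].
#'
#' @param size Frame side (pixels); ignored when `layout` is given.
#' @param n_frames Number of frames.
#' @param wavelength,speed Wave train geometry (pixels, pixels/frame).
#' @param directions One angle (radians) per region of `layout`.
#' @param layout Integer label matrix partitioning the frame; `NULL` gives
#'   `length(directions)` vertical bands.
#' @param noise_sigma Additive Gaussian noise level.
#' @param seed Seed for the noise.
#' @return A `synthetic_movie` list (see [plane_wave_movie()]).
#' @export
multidomain_movie <- function(size = 64, n_frames = 20, wavelength = 16,
                              speed = 2, directions = c(0, pi),
                              layout = NULL, noise_sigma = 0, seed = 1) {
  check_wave_spec(wavelength, speed)
  if (is.null(layout)) {
    layout <- matrix(0L, size, size)
    bands <- round(seq(0, size, length.out = length(directions) + 1))
    for (i in seq_along(directions))
      layout[, (bands[i] + 1):bands[i + 1]] <- i
  }
  nreg <- length(unique(as.vector(layout[layout > 0])))
  if (nreg != length(directions))
    stop("need exactly one direction per region (", nreg, " regions, ",
         length(directions), " directions)")
  nr <- nrow(layout); nc <- ncol(layout)
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)  # column coordinate
  y <- matrix(rep(seq_len(nr), nc), nr, nc)         # row coordinate
  theta_truth <- matrix(0, nr, nc)
  for (i in seq_along(directions))
    theta_truth[layout == i] <- directions[i] %% (2 * pi)
  movie <- array(0, dim = c(nr, nc, n_frames))
  set.seed(seed)
  for (t in seq_len(n_frames)) {
    fr <- matrix(0, nr, nc)
    for (i in seq_along(directions)) {
      sel <- layout == i
      phase <- 2 * pi * (x * cos(directions[i]) + y * sin(directions[i]) -
                           speed * (t - 1)) / wavelength
      fr[sel] <- (1 + sin(phase[sel])) / 2
    }
    if (noise_sigma > 0)
      fr <- fr + matrix(rnorm(nr * nc, sd = noise_sigma), nr, nc)
    movie[, , t] <- fr
  }
  structure(list(movie = movie,
                 theta_truth = angle_map(theta_truth, layout > 0),
                 labels_truth = structure(layout,
                                          class = c("label_map", "matrix")),
                 spec = list(kind = if (length(directions) == 1)
                               "plane_wave" else "multidomain",
                             size = c(nr, nc), n_frames = n_frames,
                             wavelength = wavelength, speed = speed,
                             directions = directions,
                             noise_sigma = noise_sigma, seed = seed)),
            class = "synthetic_movie")
}

#' Synthetic rotating spiral movie
#'
#' Archimedean-spiral phase pattern `sin(2*pi*r/wavelength - phi - omega*t)`
#' rotating at constant angular speed, the classic excitable-media control:
#' its wave vectors point radially in all directions away from the core, so
#' a correct coherence analysis must yield small coherence distances near
#' the core rather than one large coherent domain.
#'
#' @param size Frame side (pixels).
#' @param n_frames Number of frames.
#' @param wavelength Radial wavelength (pixels).
#' @param speed Radial propagation speed (pixels per frame); the angular
#'   speed is `2*pi*speed/wavelength` per frame.
#' @param noise_sigma Additive Gaussian noise level.
#' @param seed Seed for the noise.
#' @return A `synthetic_movie` list (no meaningful single ground-truth
#'   angle; `theta_truth` holds the local radial direction).
#' @export
spiral_movie <- function(size = 64, n_frames = 20, wavelength = 16,
                         speed = 2, noise_sigma = 0, seed = 1) {
  check_wave_spec(wavelength, speed)
  ctr <- (size + 1) / 2
  x <- matrix(rep(seq_len(size), each = size), size, size) - ctr
  y <- matrix(rep(seq_len(size), size), size, size) - ctr
  r <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  omega <- 2 * pi * speed / wavelength
  movie <- array(0, dim = c(size, size, n_frames))
  set.seed(seed)
  for (t in seq_len(n_frames)) {
    fr <- (1 + sin(2 * pi * r / wavelength - phi - omega * (t - 1))) / 2
    if (noise_sigma > 0)
      fr <- fr + matrix(rnorm(size^2, sd = noise_sigma), size, size)
    movie[, , t] <- fr
  }
  structure(list(movie = movie,
                 theta_truth = angle_map(phi %% (2 * pi), r > 1),
                 labels_truth = NULL,
                 spec = list(kind = "spiral", size = size,
                             n_frames = n_frames, wavelength = wavelength,
                             speed = speed, noise_sigma = noise_sigma,
                             seed = seed)),
            class = "synthetic_movie")
}

#' Masks with a moving (eroding) cell edge
#'
#' A disk mask whose radius shrinks by one pixel every `erode_every`
#' frames, mimicking a retracting cell edge; exercises the mask
#' intersection rule of [running_circular_mean()].
#'
#' @param size Frame side (pixels).
#' @param n_frames Number of masks.
#' @param erode_every Frames between successive 1-pixel erosions.
#' @return List of binary matrices.
#' @export
moving_edge_masks <- function(size = 64, n_frames = 20, erode_every = 5) {
  ctr <- (size + 1) / 2
  x <- matrix(rep(seq_len(size), each = size), size, size) - ctr
  y <- matrix(rep(seq_len(size), size), size, size) - ctr
  d <- sqrt(x^2 + y^2)
  r0 <- (size - 2) / 2
  lapply(seq_len(n_frames), function(t) {
    (d <= r0 - (t - 1) %/% erode_every) * 1L
  })
}
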