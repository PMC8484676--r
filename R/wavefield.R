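#' Wave-vector estimation parameters
#'
#' @param w_c Side of the square convolution window (pixels; odd, >= 3).
#' @param tau_c Frame lag between the compared snapshots (frames; the
#'   reference setting is 8 au for simulations saved once per au, 1 frame for
#'   the experimental movies).
#' @param n Similarity-sharpening exponent of the weighting; larger values
#'   concentrate weight on the most similar pixels. The segmentation
#'   pipeline is insensitive to it over the range 3-7.
#' @param T_av Running circular-averaging window (frames; 300 au for
#'   simulations, 15 frames for experiments).
#' @return An object of class `cw_waveparams`.
#' @export
wave_params <- function(w_c = 5, tau_c = 8, n = 5, T_av = 300) {
  if (w_c < 3 || w_c %% 2 != 1) stop("'w_c' must be odd and >= 3")
  if (tau_c < 1) stop("'tau_c' must be >= 1 frame")
  if (n <= 0) stop("'n' must be positive")
  if (T_av < 1) stop("'T_av' must be >= 1 frame")
  structure(list(w_c = as.integer(w_c), tau_c = as.integer(tau_c), n = n,
                 T_av = as.integer(T_av)), class = "cw_waveparams")
}

# shift so that out[r, c] = x[r + dr, c + dc], filling with `fill`
shift_mat <- function(x, dr, dc, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- x[rs + dr, cs + dc]
  out
}

# shift with replicated (clamped) borders, for gradient filters
shift_clamp <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  x[ri, ci, drop = FALSE]
}

#' Sobel gradient magnitude
#'
#' `sqrt(gx^2 + gy^2)` with the standard 3x3 Sobel kernels; image borders
#' are handled by replication, so a constant image has zero gradient
#' everywhere.
#'
#' @param img Numeric matrix.
#' @return Matrix of gradient magnitudes (nonnegative).
#' @export
sobel_magnitude <- function(img) {
  s <- function(dr, dc) shift_clamp(img, dr, dc)
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
        (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
        (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Per-pixel wave-propagation vector field
#'
#' For every masked pixel `i`, the wave vector is the weighted sum over the
#' convolution window of offsets to pixels `j` in the later frame,
#' `k(i) = sum_j (r_j - r_i) / (1 + |A_j(t+tau) - A_i(t)| +
#' |grad A_j(t+tau) - grad A_i(t)|)^n`, where `grad` is the Sobel gradient
#' magnitude. Pixels in the later frame most similar to pixel `i` (in value
#' and local gradient) dominate the sum, so `k` points along the local
#' direction of propagation. Window pixels outside the mask or image are
#' excluded. Angles use image coordinates: x along columns, y along rows
#' (increasing downward), `theta = atan2(ky, kx) mod 2*pi`.
#'
#' @param frame_t,frame_tau Snapshots at times `t` and `t + tau`.
#' @param mask Optional binary mask (default: full frame).
#' @param params A [wave_params()] object.
#' @return An object of class `angle_map`: list with matrices `theta`
#'   (radians in `[0, 2*pi)`), `magnitude`, and logical `valid` (FALSE
#'   outside the mask and where the vector sum is numerically zero).
#' @export
wave_vector_field <- function(frame_t, frame_tau, mask = NULL,
                              params = wave_params()) {
  if (!all(dim(frame_t) == dim(frame_tau)))
    stop("frames must have the same shape")
  nr <- nrow(frame_t); nc <- ncol(frame_t)
  m <- if (is.null(mask)) matrix(1, nr, nc) else (mask != 0) * 1
  if (!all(dim(m) == dim(frame_t))) stop("mask shape mismatch")
  g1 <- sobel_magnitude(frame_t)
  g2 <- sobel_magnitude(frame_tau)
  half <- (params$w_c - 1L) %/% 2L
  kx <- matrix(0, nr, nc)
  ky <- matrix(0, nr, nc)
  for (dr in -half:half) {
    for (dc in -half:half) {
      if (dr == 0 && dc == 0) next
      a2 <- shift_mat(frame_tau, dr, dc)
      gg <- shift_mat(g2, dr, dc)
      ms <- shift_mat(m, dr, dc)
      w <- ms / (1 + abs(a2 - frame_t) + abs(gg - g1))^params$n
      kx <- kx + dc * w
      ky <- ky + dr * w
    }
  }
  mag <- sqrt(kx^2 + ky^2)
  valid <- (m != 0) & (mag >= 1e-12 * params$w_c^2)
  theta <- atan2(ky, kx) %% (2 * pi)
  theta[!valid] <- 0
  structure(list(theta = theta, magnitude = mag, valid = valid),
            class = "angle_map")
}

#' Construct an angle map
#'
#' @param theta Matrix of directions (radians; wrapped into `[0, 2*pi)`).
#' @param valid Logical matrix of the same shape (default: all valid).
#' @param magnitude Optional matrix of vector magnitudes.
#' @return An `angle_map` object.
#' @export
angle_map <- function(theta, valid = NULL, magnitude = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(theta), ncol(theta))
  if (is.null(magnitude)) magnitude <- matrix(1, nrow(theta), ncol(theta))
  theta <- theta %% (2 * pi)
  theta[!valid] <- 0
  structure(list(theta = theta, magnitude = magnitude,
                 valid = valid & is.finite(theta)), class = "angle_map")
}

#' Running circular mean of an angle-map sequence
#'
#' Slides a window of `T_av` frames over the sequence and, per pixel,
#' averages the valid directions with the circular mean
#' `atan2(sum sin, sum cos)`. A pixel contributes only in frames where it
#' is valid; with per-frame masks (moving cell edge) the pixel must lie in
#' the intersection of all masks within the window. Pixels with no valid
#' contribution (or cancelling resultant) are flagged invalid.
#'
#' @param maps List of `angle_map` objects.
#' @param T_av Window length in frames.
#' @param masks Optional: a single binary matrix or a list of per-frame
#'   masks.
#' @return List of `angle_map` objects, one per window position (length
#'   `length(maps) - T_av + 1`); each carries attribute `frames`, the index
#'   range averaged.
#' @export
running_circular_mean <- function(maps, T_av, masks = NULL) {
  nmaps <- length(maps)
  if (T_av > nmaps) stop("averaging window exceeds the number of frames")
  nr <- nrow(maps[[1]]$theta); nc <- ncol(maps[[1]]$theta)
  get_mask <- function(i) {
    if (is.null(masks)) return(matrix(1, nr, nc))
    mm <- if (is.list(masks)) masks[[i]] else masks
    (mm != 0) * 1
  }
  sin_f <- lapply(maps, function(a) ifelse(a$valid, sin(a$theta), 0))
  cos_f <- lapply(maps, function(a) ifelse(a$valid, cos(a$theta), 0))
  cnt_f <- lapply(maps, function(a) a$valid * 1)
  ss <- matrix(0, nr, nc); sc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc); msum <- matrix(0, nr, nc)
  for (i in seq_len(T_av)) {
    ss <- ss + sin_f[[i]]; sc <- sc + cos_f[[i]]
    cnt <- cnt + cnt_f[[i]]; msum <- msum + get_mask(i)
  }
  out <- vector("list", nmaps - T_av + 1L)
  for (w in seq_along(out)) {
    inter <- msum == T_av  # pixel inside every mask of the window
    r2 <- ss^2 + sc^2
    valid <- inter & cnt > 0 & r2 > (1e-12)^2
    theta <- atan2(ss, sc) %% (2 * pi)
    theta[!valid] <- 0
    am <- structure(list(theta = theta, magnitude = sqrt(r2) / pmax(cnt, 1),
                         valid = valid), class = "angle_map")
    attr(am, "frames") <- c(w, w + T_av - 1L)
    out[[w]] <- am
    if (w < length(out)) {
      ss <- ss - sin_f[[w]] + sin_f[[w + T_av]]
      sc <- sc - cos_f[[w]] + cos_f[[w + T_av]]
      cnt <- cnt - cnt_f[[w]] + cnt_f[[w + T_av]]
      msum <- msum - get_mask(w) + get_mask(w + T_av)
    }
  }
  out
}

#' Direction-gradient map
#'
#' Sobel gradient magnitude of the image `sin(theta) + cos(theta)`; ridges
#' of high values localize the boundaries between regions of different
#' propagation direction. Invalid pixels enter the image as zero.
#'
#' @param am An `angle_map` object.
#' @return Nonnegative matrix.
#' @export
angle_gradient_map <- function(am) {
  stopifnot(inherits(am, "angle_map"))
  s <- sin(am$theta) + cos(am$theta)
  s[!am$valid] <- 0
  sobel_magnitude(s)
}

#' Render an angle map with a cyclic HSV colormap
#'
#' Hue encodes `theta / (2*pi)`, so 0 and `2*pi` map to the same color;
#' invalid pixels are rendered in neutral gray.
#'
#' @param am An `angle_map` object.
#' @param file Optional PNG path to write.
#' @return Invisibly, an `nr x nc x 3` RGB array in `[0, 1]`.
#' @export
export_angle_colormap <- function(am, file = NULL) {
  stopifnot(inherits(am, "angle_map"))
  h <- (am$theta %% (2 * pi)) / (2 * pi)
  h[h >= 1] <- 0
  cols <- hsv(h = as.vector(h), s = 1, v = 1)
  rgbv <- grDevices::col2rgb(cols) / 255
  nr <- nrow(am$theta); nc <- ncol(am$theta)
  img <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) {
    plane <- matrix(rgbv[ch, ], nr, nc)
    plane[!am$valid] <- 0.5
    img[, , ch] <- plane
  }
  if (!is.null(file)) png::writePNG(img, file)
  invisible(img)
}
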