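#' Z-score standardization of frames
#'
#' Standardizes to zero mean and unit standard deviation over the masked
#' pixels of the whole analysis window, `(A - mean(A)) / sd(A)`, so that
#' patterns of different absolute amplitude (e.g. simulated concentrations
#' versus fluorescence counts) become directly comparable.
#'
#' @param frames Matrix or 3-d array `[rows, cols, frames]`.
#' @param mask Optional binary matrix; statistics and output are restricted
#'   to masked pixels (background is set to 0).
#' @return The standardized array, same shape as the input.
#' @export
zscore_frames <- function(frames, mask = NULL) {
  d <- dim(frames)
  is_stack <- length(d) == 3
  m <- if (is.null(mask)) NULL else mask != 0
  sel <- if (is.null(m)) rep(TRUE, length(frames)) else
    as.vector(if (is_stack) array(m, dim = d) else m)
  v <- frames[sel]
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop("zero variance within the analysis window; cannot standardize")
  out <- frames
  out[sel] <- (v - mean(v)) / s
  out[!sel] <- 0
  out
}

#' Shannon entropy of the intensity histogram
#'
#' Min-max scales the frame to `[0, 1]`, bins it into 256 intensity levels
#' and returns the Shannon entropy of the histogram in bits. Invariant
#' under monotone affine rescaling of the intensities. High-entropy frames
#' are the texturally complex wave-domain patterns; large spirals or flat
#' frames score low.
#'
#' @param frame Numeric matrix (or vector) of finite intensities.
#' @param bins Number of histogram bins.
#' @return Entropy in bits (0 for a constant frame).
#' @export
pattern_entropy <- function(frame, bins = 256) {
  v <- as.vector(frame)
  if (any(!is.finite(v))) stop("frame contains non-finite values")
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  v <- (v - rng[1]) / (rng[2] - rng[1])
  idx <- pmin(floor(v * bins) + 1L, bins)
  p <- tabulate(idx, nbins = bins)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p))
}

#' Gray-level co-occurrence texture features
#'
#' Quantizes the frame into `levels` equal-width gray levels between its
#' minimum and maximum, accumulates the co-occurrence matrix for the
#' single-pixel horizontal offset (optionally symmetrized) and returns the
#' standard descriptors: contrast `sum p(i,j) (i-j)^2`, correlation
#' `sum p(i,j)(i-mu_i)(j-mu_j)/(sigma_i sigma_j)`, energy `sum p^2` and
#' homogeneity `sum p / (1 + |i-j|)`.
#'
#' @param frame Numeric matrix of finite intensities.
#' @param levels Number of gray levels.
#' @param symmetric Count each pair in both directions.
#' @return List of class `texture_features`: `contrast`, `correlation`
#'   (`NA` for a constant frame), `energy`, `homogeneity`, and the matrix
#'   `glcm` of pair probabilities.
#' @export
glcm_features <- function(frame, levels = 8, symmetric = FALSE) {
  if (any(!is.finite(frame))) stop("frame contains non-finite values")
  rng <- range(frame)
  q <- if (rng[1] == rng[2]) {
    matrix(1L, nrow(frame), ncol(frame))
  } else {
    qq <- floor((frame - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
    qq[qq > levels] <- as.integer(levels)
    qq
  }
  a <- as.vector(q[, -ncol(q)])
  b <- as.vector(q[, -1])
  if (symmetric) {
    tmp <- c(a, b); b <- c(b, a); a <- tmp
  }
  counts <- matrix(0, levels, levels)
  for (k in seq_along(a)) counts[a[k], b[k]] <- counts[a[k], b[k]] + 1
  p <- counts / sum(counts)
  i <- row(p); j <- col(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p))
  s_j <- sqrt(sum((j - mu_j)^2 * p))
  correlation <- if (s_i == 0 || s_j == 0) NA_real_ else
    sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
  out <- list(contrast = sum((i - j)^2 * p),
              correlation = correlation,
              energy = sum(p^2),
              homogeneity = sum(p / (1 + abs(i - j))),
              glcm = p)
  class(out) <- "texture_features"
  out
}

#' @export
print.texture_features <- function(x, ...) {
  cat(sprintf("GLCM features: contrast %.4g, correlation %s, energy %.4g, homogeneity %.4g\n",
              x$contrast,
              if (is.na(x$correlation)) "NA" else sprintf("%.4g", x$correlation),
              x$energy, x$homogeneity))
  invisible(x)
}

#' Texture feature table for a movie window
#'
#' Computes [pattern_entropy()], [glcm_features()] and
#' [excitation_measure()] per frame after per-window z-scoring, and
#' averages them over the analysis window.
#'
#' @param frames 3-d array `[rows, cols, frames]`.
#' @param mask Optional binary mask.
#' @param levels,symmetric Passed to [glcm_features()].
#' @return One-row data frame with the window-averaged features.
#' @export
texture_profile <- function(frames, mask = NULL, levels = 8,
                            symmetric = FALSE) {
  z <- zscore_frames(frames, mask)
  nt <- dim(z)[3]
  m <- if (is.null(mask)) matrix(TRUE, dim(z)[1], dim(z)[2]) else mask != 0
  per <- lapply(seq_len(nt), function(i) {
    fr <- z[, , i]
    g <- glcm_features(fr, levels = levels, symmetric = symmetric)
    data.frame(entropy = pattern_entropy(fr),
               contrast = g$contrast, correlation = g$correlation,
               energy = g$energy, homogeneity = g$homogeneity,
               excitation = excitation_measure(frames[, , i], m))
  })
  per <- do.call(rbind, per)
  as.data.frame(lapply(per, mean, na.rm = TRUE))
}

#' Preprocess experimental frames for texture comparison
#'
#' Crops a centered physical window of `crop_um x crop_um` microns from
#' each frame (given the camera pixel size), resamples it to
#' `out_px x out_px` pixels, and z-scores the resulting window so simulated
#' and experimental frames share a common scale.
#'
#' @param frames Matrix or 3-d array of raw frames.
#' @param pixel_size Microns per pixel of the input.
#' @param crop_um Side of the physical crop window (microns).
#' @param out_px Output resolution (pixels).
#' @return 3-d array `out_px x out_px x frames` (single matrix in, single
#'   matrix out).
#' @export
preprocess_experimental <- function(frames, pixel_size, crop_um = 100,
                                    out_px = 100) {
  single <- is.matrix(frames)
  if (single) frames <- array(frames, dim = c(dim(frames), 1))
  d <- dim(frames)
  crop_px <- round(crop_um / pixel_size)
  if (crop_px > d[1] || crop_px > d[2])
    stop("crop window (", crop_px, " px) exceeds the frame size")
  r0 <- floor((d[1] - crop_px) / 2) + 1
  c0 <- floor((d[2] - crop_px) / 2) + 1
  out <- array(0, dim = c(out_px, out_px, d[3]))
  for (i in seq_len(d[3])) {
    crop <- frames[r0:(r0 + crop_px - 1), c0:(c0 + crop_px - 1), i]
    out[, , i] <- if (crop_px == out_px) crop else
      as.matrix(EBImage::resize(EBImage::Image(crop), w = out_px,
                                h = out_px))
  }
  out <- zscore_frames(out)
  if (single) out[, , 1] else out
}
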