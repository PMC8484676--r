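#' Model parameters for the activator-substrate system
#'
#' Constructs the validated parameter set of the three-component
#' reaction-diffusion model: active GTPase `A` (slow membrane diffusion),
#' inactive GTPase `I` (fast cytosolic diffusion) and F-actin `F`
#' (non-diffusing local inhibitor). Activation combines a basal rate `k0`
#' with autocatalysis `gamma * A^3 / (A0^3 + A^3)`; deactivation combines a
#' basal rate `s1` with the F-actin feedback `s2 * F / (F0 + F)`. Defaults
#' are the reference calibration values; `k0`, `s2` and the noise magnitudes
#' are the quantities scanned across dynamic regimes.
#'
#' @param D_A,D_I Diffusion coefficients of the active and inactive forms
#'   (au^2 per au of time).
#' @param k0 Basal activation rate (1/time), studied range \[0, 0.3\].
#' @param gamma Autocatalytic rate constant (1/time).
#' @param A0 Half-saturation of the autocatalytic Hill term (concentration).
#' @param s1 Basal deactivation rate (1/time).
#' @param s2 F-actin negative-feedback rate constant (1/time), studied
#'   range \[0, 1.3\].
#' @param F0 Half-saturation of the negative-feedback Hill term.
#' @param kn,ks F-actin polymerization and depolymerization rate constants.
#' @param alpha1 Noise magnitude on the conserved A/I pair.
#' @param alpha2 Noise magnitude on F.
#' @return An object of class `cw_params`.
#' @examples
#' p <- model_params(k0 = 0.2, s2 = 0.8)
#' @export
model_params <- function(D_A = 0.001 / 3, D_I = 0.1 / 3, k0 = 0.2,
                         gamma = 1, A0 = 0.4, s1 = 0.5, s2 = 0.8,
                         F0 = 0.5, kn = 0.1, ks = 0.025,
                         alpha1 = 1e-15, alpha2 = 1e-15) {
  p <- list(D_A = D_A, D_I = D_I, k0 = k0, gamma = gamma, A0 = A0,
            s1 = s1, s2 = s2, F0 = F0, kn = kn, ks = ks,
            alpha1 = alpha1, alpha2 = alpha2)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("parameter '", nm, "' must be a single finite number")
    if (v < 0)
      stop("parameter '", nm, "' must be nonnegative")
  }
  if (p$A0 <= 0) stop("parameter 'A0' must be positive")
  if (p$F0 <= 0) stop("parameter 'F0' must be positive")
  structure(p, class = "cw_params")
}

#' Grid and discretization specification
#'
#' @param mask Binary matrix (1 = cell interior, 0 = background). Pixels on
#'   the outer border of the matrix are always treated as background by the
#'   solver, so masks produced by [make_mask()] (which carry a one-pixel
#'   zero-padding ring) pass through unchanged.
#' @param h Spatial step (au of distance).
#' @param dt Time step (au of time).
#' @param save_every Number of Euler iterations between saved snapshots
#'   (the default 1000 together with `dt = 0.001` saves once per au).
#' @return An object of class `cw_grid`.
#' @export
grid_spec <- function(mask, h = 0.02, dt = 0.001, save_every = 1000) {
  if (!is.matrix(mask)) stop("'mask' must be a matrix")
  m <- mask != 0
  storage.mode(m) <- "integer"
  if (h <= 0) stop("'h' must be positive")
  if (dt < 0) stop("'dt' must be nonnegative")
  if (save_every < 1) stop("'save_every' must be >= 1")
  structure(list(mask = m, h = h, dt = dt,
                 save_every = as.integer(save_every)),
            class = "cw_grid")
}

#' Physical scaling factors
#'
#' Conversion constants between model units and physical units, obtained by
#' matching simulated and experimental dynamics: one au of model time equals
#' `tau_sc` seconds (0.83 s for the starfish data, 1.56 s for the frog data)
#' and one au of model distance equals `r_sc` microns.
#'
#' @param tau_sc Seconds per au of time.
#' @param r_sc Microns per au of distance.
#' @return An object of class `cw_scaling`.
#' @export
scaling_factors <- function(tau_sc = 0.83, r_sc = 15.93) {
  if (tau_sc <= 0 || r_sc <= 0) stop("scaling factors must be positive")
  structure(list(tau_sc = tau_sc, r_sc = r_sc), class = "cw_scaling")
}

#' Build a binary simulation mask
#'
#' @param kind `"square"` (interior of `(size-2)^2` ones inside a one-pixel
#'   zero-padding ring), `"circle"` (inscribed disk with the same padding) or
#'   `"irregular"` (thresholded image resized to the padded bounding box).
#' @param size Total side length in pixels (including the padding ring).
#' @param image For `kind = "irregular"`: a numeric matrix or path to a
#'   PNG/TIFF image; values above `threshold` become cell pixels.
#' @param threshold Binarization threshold for `image`.
#' @return Integer matrix of 0/1 of dimension `size x size`.
#' @examples
#' m <- make_mask("square", 202) # 200 x 200 active interior
#' sum(m) == 200^2
#' @export
make_mask <- function(kind = c("square", "circle", "irregular"), size,
                      image = NULL, threshold = 0.5) {
  kind <- match.arg(kind)
  if (size < 4) stop("'size' must be at least 4")
  m <- matrix(0L, size, size)
  inner <- 2:(size - 1)
  if (kind == "square") {
    m[inner, inner] <- 1L
  } else if (kind == "circle") {
    ctr <- (size + 1) / 2
    rad <- (size - 2) / 2
    ix <- matrix(seq_len(size), size, size)
    iy <- t(ix)
    m[(ix - ctr)^2 + (iy - ctr)^2 <= rad^2] <- 1L
    m[1, ] <- 0L; m[size, ] <- 0L; m[, 1] <- 0L; m[, size] <- 0L
  } else {
    if (is.null(image)) stop("'image' is required for an irregular mask")
    img <- if (is.matrix(image)) image else read_image_gray(image)
    bin <- img > threshold
    rows <- range(which(rowSums(bin) > 0))
    cols <- range(which(colSums(bin) > 0))
    if (!all(is.finite(c(rows, cols))))
      stop("'image' contains no pixels above the threshold")
    crop <- bin[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    res <- EBImage::resize(EBImage::Image(crop * 1), w = size - 2,
                           h = size - 2)
    m[inner, inner] <- as.integer(as.matrix(res) > 0.5)
  }
  m
}

# grayscale image loader for irregular masks (PNG or TIFF)
read_image_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  img
}

#' Construct an initial field state
#'
#' Three standard initialization schemes, all holding mean `A + I = 1` over
#' the mask: `"homogeneous"` (`A = 0, I = 1, F = 0`; patterns then nucleate
#' from the intrinsic noise), `"center_spike"` (`A = 5` on a central
#' 10 x 10 block, `I` lowered uniformly so total mass is unchanged) and
#' `"random_perturbation"` (`A = eps * |xi|`, `I = 1 - A` per pixel with
#' standard-normal `xi`).
#'
#' @param kind Initialization scheme.
#' @param mask Binary mask matrix (or a [grid_spec()] object).
#' @param eps Perturbation amplitude for `"random_perturbation"`.
#' @param spike_size Side of the central activation block.
#' @param spike_value Activator level inside the block.
#' @return An object of class `cw_state`: list with matrices `A`, `I`, `F`
#'   and time `t = 0`.
#' @export
make_initial_state <- function(kind = c("homogeneous", "center_spike",
                                        "random_perturbation"),
                               mask, eps = 1e-4, spike_size = 10,
                               spike_value = 5) {
  kind <- match.arg(kind)
  if (inherits(mask, "cw_grid")) mask <- mask$mask
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  A <- matrix(0, nr, nc)
  I <- matrix(0, nr, nc)
  F_ <- matrix(0, nr, nc)
  I[m] <- 1
  if (kind == "center_spike") {
    r0 <- floor((nr - spike_size) / 2) + 1
    c0 <- floor((nc - spike_size) / 2) + 1
    rows <- r0:(r0 + spike_size - 1)
    cols <- c0:(c0 + spike_size - 1)
    if (any(rows < 1 | rows > nr | cols < 1 | cols > nc) ||
        !all(m[rows, cols]))
      stop("central spike block does not fit inside the mask")
    A[rows, cols] <- spike_value
    I[m] <- 1 - sum(A[m]) / sum(m)
  } else if (kind == "random_perturbation") {
    xi <- abs(rnorm(sum(m)))
    A[m] <- eps * xi
    I[m] <- 1 - eps * xi
  }
  structure(list(A = A, I = I, F = F_, t = 0), class = "cw_state")
}
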