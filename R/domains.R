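#' Wave-domain segmentation parameters
#'
#' @param C_cr Critical circular standard deviation below which directions
#'   within a disk count as coherent.
#' @param theta_m Merge threshold on the wrapped difference of domain mean
#'   directions (radians).
#' @param l_cr Minimum interface length for merging, as a fraction of the
#'   square root of the smaller domain's area.
#' @param r_max Largest disk radius searched for the coherence distance
#'   (pixels).
#' @param std_cap Finite cap on the circular standard deviation as the mean
#'   resultant length approaches zero.
#' @param min_area Minimum domain area (pixels); smaller regions are merged
#'   into the neighbor with the longest shared interface. `NULL` disables
#'   the filter; `"auto"` uses the squared estimated wavelength.
#' @return An object of class `cw_domainparams`.
#' @export
domain_params <- function(C_cr = 0.4, theta_m = 0.5, l_cr = 0.10,
                          r_max = 40, std_cap = 10, min_area = NULL) {
  if (C_cr <= 0) stop("'C_cr' must be positive")
  if (theta_m <= 0 || theta_m > pi) stop("'theta_m' must be in (0, pi]")
  if (l_cr <= 0 || l_cr > 1) stop("'l_cr' must be in (0, 1]")
  if (r_max < 1) stop("'r_max' must be >= 1")
  structure(list(C_cr = C_cr, theta_m = theta_m, l_cr = l_cr,
                 r_max = as.integer(r_max), std_cap = std_cap,
                 min_area = min_area),
            class = "cw_domainparams")
}

#' Circular mean of a set of angles
#'
#' @param angles Vector of angles (radians).
#' @return Mean direction in `[0, 2*pi)`.
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0) stop("empty set of angles")
  atan2(mean(sin(angles)), mean(cos(angles))) %% (2 * pi)
}

#' Circular standard deviation
#'
#' `sqrt(-2 * log(Rbar))` with `Rbar` the mean resultant length of the unit
#' vectors; zero for identical angles, capped at `cap` as `Rbar` approaches
#' zero. Invariant under rotation of all angles.
#'
#' @param angles Vector of angles (radians).
#' @param cap Finite cap for degenerate (uniform) angle sets.
#' @return Nonnegative scalar.
#' @export
circular_std <- function(angles, cap = 10) {
  if (length(angles) == 0) stop("empty set of angles")
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  if (rbar >= 1) return(0)
  if (rbar <= 0) return(cap)
  min(sqrt(-2 * log(rbar)), cap)
}

#' Coherence-distance map
#'
#' For every valid pixel, the largest integer disk radius (up to `r_max`)
#' such that the circular standard deviation of the valid directions within
#' the disk stays below `C_cr`; 0 where even radius 1 fails or the pixel
#' is invalid. Radii are verified incrementally from 1 upward with early
#' exit at the first failure. Deep inside a coherent wave domain the
#' distance is large; it collapses at domain boundaries and near spiral
#' cores, which makes the map a suitable watershed landscape.
#'
#' @param am An `angle_map` object (normally time-averaged, see
#'   [running_circular_mean()]).
#' @param params A [domain_params()] object.
#' @return Matrix of class `coherence_map` with values in `[0, r_max]`.
#' @export
coherence_distance_map <- function(am, params = domain_params()) {
  stopifnot(inherits(am, "angle_map"))
  out <- cw_coherence_core(am$theta, am$valid, params$C_cr, params$r_max,
                           params$std_cap)
  class(out) <- c("coherence_map", class(out))
  out
}

#' Watershed with flat-region absorption
#'
#' Segments a coherence map into catchment basins of its local maxima
#' (watershed of the negated map). Unlike the textbook transform, plateau
#' (flat) pixels never seed basins of their own: levels are flooded in
#' decreasing order and the pixels of each level that touch an
#' already-labeled region are absorbed into it (breadth-first from the
#' region borders) before any remaining connected plateau component is
#' allowed to start a new basin. Every valid pixel receives a label, so the
#' labels tile the mask with no watershed lines; an all-flat input yields a
#' single region.
#'
#' @param coherence Numeric matrix (e.g. a [coherence_distance_map()]).
#' @param mask Optional binary matrix of pixels to segment (default: all).
#' @return Integer `label_map` matrix; 0 marks background.
#' @export
watershed_flat_merge <- function(coherence, mask = NULL) {
  nr <- nrow(coherence); nc <- ncol(coherence)
  m <- if (is.null(mask)) matrix(TRUE, nr, nc) else mask != 0
  labels <- matrix(0L, nr, nc)
  vals <- coherence
  vals[!m] <- -Inf
  nbr_offsets <- c(-1L, 1L, -nr, nr)
  inb <- function(p, o) {         # 4-neighbor validity on the linear grid
    r <- (p - 1L) %% nr + 1L
    !((o == -1L & r == 1L) | (o == 1L & r == nr) |
      (p + o < 1L) | (p + o > nr * nc))
  }
  next_label <- 0L
  for (v in sort(unique(vals[m]), decreasing = TRUE)) {
    level <- which(vals == v)
    if (length(level) == 0) next
    # phase 1: absorb level pixels reachable from existing basins (FIFO)
    queue <- level[vapply(level, function(p) {
      any(vapply(nbr_offsets, function(o)
        inb(p, o) && labels[p + o] > 0L, logical(1)))
    }, logical(1))]
    qh <- 1L
    queue <- as.integer(queue)
    while (qh <= length(queue)) {
      p <- queue[qh]; qh <- qh + 1L
      if (labels[p] > 0L) next
      nl <- integer(0)
      for (o in nbr_offsets)
        if (inb(p, o) && labels[p + o] > 0L) nl <- c(nl, labels[p + o])
      if (length(nl) == 0) next
      labels[p] <- min(nl)  # deterministic conflict resolution
      for (o in nbr_offsets) {
        q <- p + o
        if (inb(p, o) && labels[q] == 0L && vals[q] == v)
          queue <- c(queue, q)
      }
    }
    # phase 2: remaining level pixels form new basins per connected component
    rest <- level[labels[level] == 0L]
    while (length(rest) > 0) {
      next_label <- next_label + 1L
      comp <- rest[1L]
      labels[comp] <- next_label
      qh <- 1L
      while (qh <= length(comp)) {
        p <- comp[qh]; qh <- qh + 1L
        for (o in nbr_offsets) {
          q <- p + o
          if (inb(p, o) && labels[q] == 0L && vals[q] == v) {
            labels[q] <- next_label
            comp <- c(comp, q)
          }
        }
      }
      rest <- rest[labels[rest] == 0L]
    }
  }
  class(labels) <- c("label_map", class(labels))
  labels
}

# interface lengths between 4-adjacent label pairs, as a data frame
label_interfaces <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-nr, ]), as.vector(labels[-1, ])),
    cbind(as.vector(labels[, -nc]), as.vector(labels[, -1])))
  pairs <- pairs[pairs[, 1] != pairs[, 2] & pairs[, 1] > 0 & pairs[, 2] > 0,
                 , drop = FALSE]
  if (nrow(pairs) == 0)
    return(data.frame(a = integer(0), b = integer(0), len = integer(0)))
  a <- pmin(pairs[, 1], pairs[, 2])
  b <- pmax(pairs[, 1], pairs[, 2])
  key <- paste(a, b)
  tab <- table(key)
  ab <- do.call(rbind, strsplit(names(tab), " "))
  data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
             len = as.integer(tab))
}

wrapped_angle_diff <- function(x, y) {
  d <- abs(x - y) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Merge adjacent domains with similar propagation direction
#'
#' Iteratively merges adjacent label pairs whose circular-mean directions
#' differ (wrapped) by less than `theta_m` and whose shared 4-adjacency
#' interface is longer than `l_cr * sqrt(area of the smaller domain)`.
#' Among qualifying pairs the smallest angular difference is merged first
#' (ties broken by label order) and all statistics are recomputed, until no
#' pair qualifies; the fixed point is order-independent in practice.
#'
#' @param labels An integer `label_map`.
#' @param am The `angle_map` the segmentation was derived from.
#' @param params A [domain_params()] object.
#' @return The merged `label_map` with consecutive labels `1..K`.
#' @export
merge_similar_domains <- function(labels, am, params = domain_params()) {
  stopifnot(inherits(am, "angle_map"))
  lab <- unclass(labels)
  repeat {
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids) < 2) break
    areas <- tabulate(lab, nbins = max(ids))
    means <- vapply(ids, function(i) {
      th <- am$theta[lab == i & am$valid]
      if (length(th) == 0) NA_real_ else circular_mean(th)
    }, numeric(1))
    names(means) <- ids
    inter <- label_interfaces(lab)
    if (nrow(inter) == 0) break
    dth <- wrapped_angle_diff(means[as.character(inter$a)],
                              means[as.character(inter$b)])
    need <- params$l_cr *
      sqrt(pmin(areas[inter$a], areas[inter$b]))
    ok <- !is.na(dth) & dth < params$theta_m & inter$len > need
    if (!any(ok)) break
    cand <- inter[ok, , drop = FALSE]
    cand$dth <- dth[ok]
    cand <- cand[order(cand$dth, cand$a, cand$b), , drop = FALSE]
    lab[lab == cand$b[1]] <- cand$a[1]
  }
  relabel_consecutive(lab)
}

relabel_consecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  class(out) <- c("label_map", class(out))
  out
}

# merge regions below the area threshold into the neighbor with the
# longest shared interface (keeps the labels a partition of the mask)
filter_small_domains <- function(labels, min_area) {
  lab <- unclass(labels)
  repeat {
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids) < 2) break
    areas <- tabulate(lab, nbins = max(ids))
    small <- ids[areas[ids] < min_area]
    if (length(small) == 0) break
    s <- small[which.min(areas[small])]
    inter <- label_interfaces(lab)
    touch <- inter[inter$a == s | inter$b == s, , drop = FALSE]
    if (nrow(touch) == 0) break
    touch <- touch[order(-touch$len), , drop = FALSE]
    target <- if (touch$a[1] == s) touch$b[1] else touch$a[1]
    lab[lab == s] <- target
  }
  relabel_consecutive(lab)
}

#' Estimate the pattern wavelength
#'
#' Spatial autocorrelation of the centered activator along the mean
#' propagation direction, evaluated at integer pixel shifts; the lag of the
#' first local minimum is returned as the wavelength estimate.
#'
#' @param frame Activator snapshot matrix.
#' @param mask Binary mask.
#' @param direction Mean propagation angle (radians).
#' @param max_lag Largest shift tested (pixels).
#' @return Wavelength in pixels (`NA` when no minimum is found).
#' @export
estimate_wavelength <- function(frame, mask, direction,
                                max_lag = floor(min(dim(frame)) / 2)) {
  m <- mask != 0
  ac <- vapply(seq_len(max_lag), function(d) {
    dr <- round(d * sin(direction))
    dc <- round(d * cos(direction))
    fs <- shift_mat(frame, dr, dc)
    ms <- shift_mat(m * 1, dr, dc) != 0
    ov <- m & ms
    if (sum(ov) < 16) return(NA_real_)
    a <- frame[ov]; b <- fs[ov]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  drop_idx <- which(diff(ac) > 0)
  if (length(drop_idx) == 0) return(NA_real_)
  drop_idx[1]  # first local minimum of the autocorrelation
}

#' Segment a movie into wave domains
#'
#' Full pipeline: per-frame wave-vector fields ([wave_vector_field()] at
#' frame lag `tau_c`), running circular averaging over `T_av` frames,
#' coherence-distance maps, flat-merging watershed, direction-similarity
#' merging, optional minimum-area filtering, and per-frame domain
#' statistics.
#'
#' @param movie 3-d array `[rows, cols, frames]` of activator snapshots, or
#'   an `rd_sim` object (its stored `A` stack is used).
#' @param mask Binary matrix, or a list of per-frame masks for movies with
#'   a moving edge.
#' @param wf_params A [wave_params()] object. For simulation output saved
#'   once per au the defaults reproduce the reference analysis settings.
#' @param dom_params A [domain_params()] object.
#' @param label_every Segment only every `label_every`-th averaged frame
#'   (the averaging window changes slowly, so consecutive segmentations are
#'   nearly redundant).
#' @param scaling A [scaling_factors()] object for physical-unit areas.
#' @param h Spatial step used for unit conversion.
#' @return List of class `wave_domains`: `labels` (list of label maps),
#'   `angle_maps` (the averaged maps segmented), `frame_index` (index of
#'   the first raw frame of each averaging window), and `stats`
#'   (see [domain_statistics()]).
#' @export
detect_wave_domains <- function(movie, mask = NULL,
                                wf_params = wave_params(),
                                dom_params = domain_params(),
                                label_every = 1L,
                                scaling = scaling_factors(), h = 0.02) {
  if (inherits(movie, "rd_sim")) {
    if (is.null(mask)) mask <- movie$grid$mask
    h <- movie$grid$h
    scaling <- movie$scaling
    movie <- movie$A
  }
  nt <- dim(movie)[3]
  if (nt < wf_params$tau_c + wf_params$T_av)
    stop("movie too short for one averaging window at this frame lag")
  static_mask <- !is.list(mask)
  get_mask <- function(i) {
    if (is.null(mask)) return(NULL)
    if (static_mask) mask else mask[[i]]
  }
  n_fields <- nt - wf_params$tau_c
  fields <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    mi <- get_mask(i)
    mj <- get_mask(i + wf_params$tau_c)
    pair_mask <- if (is.null(mi)) NULL else if (static_mask) mi else
      (mi != 0) & (mj != 0)
    fields[[i]] <- wave_vector_field(movie[, , i],
                                     movie[, , i + wf_params$tau_c],
                                     pair_mask, wf_params)
  }
  window_masks <- if (is.null(mask)) NULL else if (static_mask) mask else
    mask[seq_len(n_fields)]
  avg <- running_circular_mean(fields, min(wf_params$T_av, n_fields),
                               window_masks)
  pick <- seq(1, length(avg), by = label_every)
  labels <- vector("list", length(pick))
  for (k in seq_along(pick)) {
    am <- avg[[pick[k]]]
    coh <- coherence_distance_map(am, dom_params)
    lab <- watershed_flat_merge(coh, am$valid)
    lab <- merge_similar_domains(lab, am, dom_params)
    min_area <- dom_params$min_area
    if (identical(min_area, "auto")) {
      th_bar <- circular_mean(am$theta[am$valid])
      wl <- estimate_wavelength(movie[, , pick[k]],
                                if (is.null(mask)) am$valid else
                                  get_mask(pick[k]), th_bar)
      min_area <- if (is.na(wl)) NULL else wl^2
    }
    if (!is.null(min_area)) lab <- filter_small_domains(lab, min_area)
    labels[[k]] <- lab
  }
  stats <- domain_statistics(labels, lapply(pick, function(i) avg[[i]]),
                             scaling, h)
  structure(list(labels = labels, angle_maps = avg[pick],
                 frame_index = pick, stats = stats),
            class = "wave_domains")
}

#' @export
print.wave_domains <- function(x, ...) {
  counts <- vapply(x$labels, function(l) length(unique(l[l > 0])),
                   integer(1))
  cat(sprintf("Wave-domain segmentation over %d frames: %s domains (first -> last)\n",
              length(x$labels),
              paste(counts[c(1, length(counts))], collapse = " -> ")))
  invisible(x)
}

#' Per-frame wave-domain statistics
#'
#' @param labels List of `label_map` matrices (or a single matrix).
#' @param angle_maps Optional matching list of `angle_map` objects for the
#'   per-domain mean direction.
#' @param scaling A [scaling_factors()] object; one pixel covers
#'   `(r_sc * h)^2` square microns.
#' @param h Spatial step (au).
#' @return Data frame of class `domain_stats` with columns `frame`,
#'   `label`, `area_px`, `area_um2`, `mean_theta`, plus attribute `counts`
#'   (domains per frame).
#' @export
domain_statistics <- function(labels, angle_maps = NULL,
                              scaling = scaling_factors(), h = 0.02) {
  if (is.matrix(labels)) labels <- list(labels)
  if (length(labels) == 0) stop("empty label series")
  px_area <- (scaling$r_sc * h)^2
  rows <- list()
  for (f in seq_along(labels)) {
    lab <- labels[[f]]
    ids <- sort(unique(lab[lab > 0]))
    for (i in ids) {
      sel <- lab == i
      mt <- if (!is.null(angle_maps)) {
        am <- angle_maps[[f]]
        th <- am$theta[sel & am$valid]
        if (length(th) == 0) NA_real_ else circular_mean(th)
      } else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(frame = f, label = i, area_px = sum(sel),
                   area_um2 = sum(sel) * px_area, mean_theta = mt)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "counts") <- vapply(labels, function(l)
    length(unique(l[l > 0])), integer(1))
  class(out) <- c("domain_stats", "data.frame")
  out
}
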