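#' Scan a two-parameter grid of dynamic regimes
#'
#' Runs one simulation per grid point over `k0 x s2` (or `gamma x s2`),
#' classifies the low-activity regime when the growth stage completes
#' within the simulated duration, and reports the pattern amplitude,
#' excitation measure and texture features of the final window.
#'
#' @param k0_values,s2_values,gamma_values Parameter grids; supply exactly
#'   two of the three axes (one of `k0_values`/`gamma_values` plus
#'   `s2_values`).
#' @param base_params Template [model_params()] object.
#' @param grid A [grid_spec()] object shared by all runs.
#' @param duration Simulated time per point (au).
#' @param seed Base seed; point `i` uses `seed + i - 1`.
#' @param texture_window Number of trailing frames entering the texture
#'   features.
#' @return Data frame with one row per grid point: the varied parameters,
#'   `T_g`, `regime`, `swing`, `amplitude`, `excitation` and the texture
#'   features.
#' @export
scan_parameter_space <- function(k0_values = NULL, s2_values,
                                 gamma_values = NULL,
                                 base_params = model_params(),
                                 grid, duration = 500, seed = 1,
                                 texture_window = 20) {
  if (is.null(k0_values) == is.null(gamma_values))
    stop("supply exactly one of 'k0_values' or 'gamma_values'")
  first <- if (is.null(gamma_values)) k0_values else gamma_values
  first_name <- if (is.null(gamma_values)) "k0" else "gamma"
  pts <- expand.grid(first = first, s2 = s2_values)
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- unclass(base_params)
    p[[first_name]] <- pts$first[i]
    p$s2 <- pts$s2[i]
    params <- do.call(model_params, p)
    sim <- run_simulation(params, grid, duration = duration,
                          seed = seed + i - 1)
    tr <- pattern_amplitude(sim)
    st <- detect_stages(tr)
    regime <- NA_character_
    swing <- NA_real_
    if (is.finite(st$T_g) && st$T_g < duration) {
      rc <- tryCatch(classify_regime(sim, st$T_g), error = function(e) NULL)
      if (!is.null(rc)) {
        regime <- rc$label
        swing <- rc$autocorr_swing
      }
    }
    nt <- dim(sim$A)[3]
    win <- max(1, nt - texture_window + 1):nt
    tex <- tryCatch(
      texture_profile(sim$A[, , win, drop = FALSE], sim$grid$mask),
      error = function(e)
        data.frame(entropy = NA, contrast = NA, correlation = NA,
                   energy = NA, homogeneity = NA, excitation = NA))
    row <- data.frame(x = pts$first[i], s2 = pts$s2[i], T_g = st$T_g,
                      regime = regime, swing = swing,
                      amplitude = tr$amp[nrow(tr)])
    names(row)[1] <- first_name
    rows[[i]] <- cbind(row, tex)
  }
  do.call(rbind, rows)
}
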