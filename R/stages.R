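#' Pattern amplitude trace
#'
#' Amplitude of the activator pattern per saved state, `max A - min A` over
#' the masked pixels, together with its natural log (defined where the
#' amplitude is positive). During the low-activity stage the log amplitude
#' grows linearly in time; it plateaus in the high-activity stage.
#'
#' @param sim An `rd_sim` object (the stored audit is used, so all saved
#'   states are covered regardless of which snapshot stacks were kept).
#' @return Data frame of class `amplitude_trace` with columns `t`, `amp`,
#'   `log_amp`.
#' @export
pattern_amplitude <- function(sim) {
  stopifnot(inherits(sim, "rd_sim"))
  if (nrow(sim$audit) == 0) stop("empty snapshot series")
  amp <- sim$audit$max_A - sim$audit$min_A
  out <- data.frame(t = sim$audit$t, amp = amp,
                    log_amp = ifelse(amp > 0, log(amp), NA_real_))
  class(out) <- c("amplitude_trace", "data.frame")
  out
}

#' Detect the low- and high-activity stages
#'
#' The low-activity stage is the period of (near-)linear increase of the log
#' amplitude: frames where the smoothed slope `d log(amp)/dt` exceeds
#' `slope_threshold`. Because both the pre-growth noise floor and the
#' saturated plateau produce short spurious threshold crossings, the growth
#' stage is identified as the longest sustained run of above-threshold
#' frames; its end time is `T_g`, the duration of the low-activity stage,
#' and later frames form the high-activity stage. The slope is estimated by
#' central differences and smoothed with a short moving average before
#' thresholding.
#'
#' @param trace An [pattern_amplitude()] data frame (any data frame with
#'   columns `t` and `log_amp` works).
#' @param slope_threshold Threshold on the log-amplitude slope
#'   (1 per au of time; the reference calibration is 1e-3).
#' @param smooth_window Moving-average window (frames) for the slope series.
#' @param tau_sc Seconds per au for the reported `T_g_s`.
#' @return List of class `stage_report`: `T_g` (au; `NA` if no growth stage
#'   is found), `T_g_s` (seconds), `slope` (data frame `t`, `slope`), and
#'   `stage` (per-frame factor `"low"`/`"high"`).
#' @export
detect_stages <- function(trace, slope_threshold = 1e-3, smooth_window = 5,
                          tau_sc = 0.83) {
  stopifnot(all(c("t", "log_amp") %in% names(trace)))
  t <- trace$t
  la <- trace$log_amp
  n <- length(t)
  if (n < 3) stop("trace too short for slope estimation")
  slope <- rep(NA_real_, n)
  ok <- is.finite(la)
  # central differences on the log amplitude (one-sided at the ends)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    if (ok[lo] && ok[hi] && t[hi] > t[lo])
      slope[i] <- (la[hi] - la[lo]) / (t[hi] - t[lo])
  }
  slope_s <- moving_average(slope, smooth_window)
  above <- !is.na(slope_s) & slope_s > slope_threshold
  if (!any(above)) {
    stage <- factor(rep("high", n), levels = c("low", "high"))
    out <- list(T_g = NA_real_, T_g_s = NA_real_,
                slope = data.frame(t = t, slope = slope_s), stage = stage)
    class(out) <- "stage_report"
    return(out)
  }
  runs <- rle(above)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  growth <- which(runs$values)
  main <- growth[which.max(runs$lengths[growth])]
  end <- run_end[main]  # last frame still above the threshold
  T_g <- t[end]
  stage <- factor(ifelse(seq_len(n) <= run_end[main], "low", "high"),
                  levels = c("low", "high"))
  out <- list(T_g = T_g, T_g_s = T_g * tau_sc,
              slope = data.frame(t = t, slope = slope_s), stage = stage)
  class(out) <- "stage_report"
  out
}

#' @export
print.stage_report <- function(x, ...) {
  if (is.na(x$T_g)) {
    cat("No growth (low-activity) stage detected.\n")
  } else {
    cat(sprintf("Low-activity stage: T_g = %.4g au (%.4g s); %d low / %d high frames\n",
                x$T_g, x$T_g_s, sum(x$stage == "low"),
                sum(x$stage == "high")))
  }
  invisible(x)
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  out <- rep(NA_real_, n)
  half <- floor(w / 2)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    v <- x[lo:hi]
    out[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

#' Temporal autocorrelation of the activator pattern
#'
#' For each lag `tau`, the Pearson correlation over masked pixels between
#' the activator snapshot at `t_ref` and the snapshot at `t_ref + tau`.
#' Quasi-static patterns keep the coefficient near one; oscillatory
#' patterns drive it periodically between roughly +1 and -1.
#'
#' @param sim An `rd_sim` object with stored `A` snapshots.
#' @param t_ref Reference time (au).
#' @param lags Vector of lags (au); each `t_ref + lag` is matched to the
#'   nearest saved state.
#' @return Data frame `lag`, `corr`; `NA` with a warning at lags where a
#'   frame has zero variance.
#' @export
temporal_autocorrelation <- function(sim, t_ref, lags) {
  stopifnot(inherits(sim, "rd_sim"))
  m <- sim$grid$mask != 0
  ref <- get_frame(sim, t_ref)[m]
  v_ref <- stats::var(ref)
  corrs <- vapply(lags, function(tau) {
    x <- get_frame(sim, t_ref + tau)[m]
    if (!is.finite(v_ref) || v_ref == 0 || stats::var(x) == 0) {
      warning("zero-variance frame at lag ", tau,
              "; correlation undefined", call. = FALSE)
      return(NA_real_)
    }
    cor(ref, x)
  }, numeric(1))
  data.frame(lag = lags, corr = corrs)
}

#' Classify the low-activity regime
#'
#' Computes the swing (max minus min) of the temporal autocorrelation over
#' the lag window `tau in [0, 0.4 * T_g]` evaluated at `t = 0.5 * T_g` (the
#' window therefore ends before the high-activity stage: `t + tau < 0.9 *
#' T_g`). The regime is oscillatory when the swing exceeds one, otherwise
#' quasi-static.
#'
#' @param sim An `rd_sim` object with stored `A` snapshots.
#' @param T_g Duration of the low-activity stage (au), e.g. from
#'   [detect_stages()].
#' @param min_prominence Peak prominence passed to [oscillation_period()].
#' @return List of class `regime_class`: `label`, `autocorr_swing`,
#'   `period` (au; `NA` unless oscillatory), and the autocorrelation curve.
#' @export
classify_regime <- function(sim, T_g, min_prominence = 0.05) {
  if (!is.finite(T_g) || T_g <= 0) stop("'T_g' must be a positive time")
  dt_f <- frame_spacing(sim)
  t_ref <- 0.5 * T_g
  max_lag <- 0.4 * T_g
  lags <- seq(0, max_lag, by = dt_f)
  lags <- lags[t_ref + lags < 0.9 * T_g + 0.5 * dt_f]
  if (t_ref + max(lags) > max(sim$times) + 0.5 * dt_f)
    stop("autocorrelation window extends beyond the simulated series")
  curve <- temporal_autocorrelation(sim, t_ref, lags)
  swing <- max(curve$corr, na.rm = TRUE) - min(curve$corr, na.rm = TRUE)
  oscillatory <- is.finite(swing) && swing > 1
  period <- if (oscillatory)
    oscillation_period(curve, min_prominence = min_prominence)
  else NA_real_
  out <- list(label = if (oscillatory) "oscillatory" else "quasi-static",
              autocorr_swing = swing, period = period, curve = curve)
  class(out) <- "regime_class"
  out
}

#' @export
print.regime_class <- function(x, ...) {
  cat(sprintf("Low-activity regime: %s (autocorrelation swing %.3f)\n",
              x$label, x$autocorr_swing))
  if (is.finite(x$period))
    cat(sprintf("  oscillation period: %.3g au\n", x$period))
  invisible(x)
}

#' Oscillation period from an autocorrelation curve
#'
#' Mean spacing between successive local maxima of the autocorrelation
#' curve. Peaks are strict local maxima with at least `min_prominence` drop
#' to the surrounding minima, which suppresses numerical ripple.
#'
#' @param curve Data frame with columns `lag` and `corr`.
#' @param min_prominence Minimum peak prominence.
#' @return Mean peak spacing (au), or `NA` when fewer than two peaks exist.
#' @export
oscillation_period <- function(curve, min_prominence = 0.05) {
  peaks <- find_peaks(curve$corr, min_prominence)
  if (length(peaks) < 2) return(NA_real_)
  mean(diff(curve$lag[peaks]))
}

find_peaks <- function(x, min_prominence = 0.05) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[is.finite(x[cand])]
  keep <- vapply(cand, function(i) {
    # prominence: drop to the highest minimum separating it from higher ground
    left <- x[1:(i - 1)]
    right <- x[(i + 1):n]
    higher_l <- which(left >= x[i])
    higher_r <- which(right >= x[i]) + i
    lo_l <- if (length(higher_l)) min(x[(max(higher_l)):(i - 1)]) else min(left, na.rm = TRUE)
    lo_r <- if (length(higher_r)) min(x[(i + 1):(min(higher_r))]) else min(right, na.rm = TRUE)
    x[i] - max(lo_l, lo_r) >= min_prominence
  }, logical(1))
  cand[keep]
}

#' Excitation measure of a snapshot
#'
#' Fraction of the masked area where the activator exceeds its spatial
#' mean. High inhibition shrinks the activation fronts relative to the
#' refractory area and lowers this measure.
#'
#' @param frame Activator snapshot matrix.
#' @param mask Binary mask.
#' @return Fraction in `[0, 1]`.
#' @export
excitation_measure <- function(frame, mask) {
  m <- mask != 0
  if (!any(m)) stop("empty mask")
  v <- frame[m]
  mean(v > mean(v))
}
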