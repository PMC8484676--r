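#' Reaction rate of the activator
#'
#' Evaluates, elementwise, the net activation rate
#' `f = (k0 + gamma * A^3/(A0^3 + A^3)) * I - (s1 + s2 * F/(F0 + F)) * A`.
#' The same `f` enters the activator equation with a plus sign and the
#' substrate equation with a minus sign, so the reaction conserves `A + I`.
#' The rate is quasi-positive: at `A = 0` it reduces to `k0 * I >= 0`, which
#' (with the analogous bounds for `I` and `F`) guarantees positivity of the
#' noise-free solution.
#'
#' @param A,I,F Nonnegative concentrations (scalars or arrays of equal shape).
#' @param params A [model_params()] object.
#' @return The rate array, same shape as the inputs.
#' @export
reaction_rate <- function(A, I, F, params = model_params()) {
  if (any(A < 0, na.rm = TRUE) || any(I < 0, na.rm = TRUE) ||
      any(F < 0, na.rm = TRUE))
    stop("concentrations must be nonnegative")
  act <- params$k0 + params$gamma * A^3 / (params$A0^3 + A^3)
  deact <- params$s1 + params$s2 * F / (params$F0 + F)
  act * I - deact * A
}

#' Mask-weighted discrete Laplacian
#'
#' Five-point stencil in which each of the four neighbor fluxes is multiplied
#' by the neighbor's mask value, so no concentration crosses the mask
#' boundary (zero-flux conditions on an arbitrary cell shape). Fluxes are
#' pairwise antisymmetric, hence the output sums to zero over the mask.
#' Pixels outside the matrix are treated as background.
#'
#' @param field Numeric matrix.
#' @param mask Binary matrix of the same shape.
#' @param h Spatial step.
#' @return Matrix of `(1/h^2) * sum of neighbor fluxes`; zero outside the
#'   mask.
#' @export
masked_laplacian <- function(field, mask, h = 0.02) {
  if (!all(dim(field) == dim(mask)))
    stop("'field' and 'mask' must have the same shape")
  m <- (mask != 0) * 1
  nr <- nrow(field); nc <- ncol(field)
  pad <- function(x) rbind(0, cbind(0, x, 0), 0)
  fp <- pad(field * m)  # background values never contribute
  mp <- pad(m)
  ctr <- 2:(nr + 1)
  cc <- 2:(nc + 1)
  f0 <- fp[ctr, cc]
  L <- mp[ctr - 1, cc] * (fp[ctr - 1, cc] - f0) +
       mp[ctr + 1, cc] * (fp[ctr + 1, cc] - f0) +
       mp[ctr, cc - 1] * (fp[ctr, cc - 1] - f0) +
       mp[ctr, cc + 1] * (fp[ctr, cc + 1] - f0)
  L * m / h^2
}

#' Stability ratio of the explicit scheme
#'
#' Returns the ratio `max(D_A, D_I) * dt / h^2`; the forward-Euler
#' discretization of the diffusion terms is stable when the ratio is below
#' 1/2.
#'
#' @param params A [model_params()] object.
#' @param grid A [grid_spec()] object.
#' @return The scalar ratio.
#' @examples
#' stability_ratio(model_params(), grid_spec(make_mask("square", 10)))
#' @export
stability_ratio <- function(params, grid) {
  max(params$D_A, params$D_I) * grid$dt / grid$h^2
}

#' Add intrinsic noise with positivity repair
#'
#' Adds `alpha1 * xi1 * dt` to `A` and subtracts the identical realization
#' from `I` (molecule-number fluctuations move mass between the two forms,
#' never create it), and adds `alpha2 * xi2 * dt` to `F`. Where the noise
#' drives `A` or `I` negative, the value is clamped to zero and the overshoot
#' moved to the partner so that `A + I` is unchanged per pixel; negative `F`
#' is clamped to zero (it has no conservation partner).
#'
#' Uses R's random number stream; the compiled simulation core draws the
#' same scheme from its own seeded generator.
#'
#' @param state A `cw_state` object.
#' @param alpha1,alpha2 Noise magnitudes.
#' @param dt Time step.
#' @param mask Binary mask; background pixels receive no noise.
#' @return The updated `cw_state`.
#' @export
apply_noise_with_repair <- function(state, alpha1, alpha2, dt, mask) {
  m <- mask != 0
  n <- sum(m)
  if (alpha1 != 0) {
    e <- alpha1 * rnorm(n) * dt
    A <- state$A[m] + e
    I <- state$I[m] - e
    neg <- A < 0
    I[neg] <- I[neg] + A[neg]
    A[neg] <- 0
    neg <- I < 0
    A[neg] <- A[neg] + I[neg]
    I[neg] <- 0
    state$A[m] <- A
    state$I[m] <- I
  }
  if (alpha2 != 0) {
    F_ <- state$F[m] + alpha2 * rnorm(n) * dt
    state$F[m] <- pmax(F_, 0)
  }
  state
}

#' Single forward-Euler step (reference implementation)
#'
#' One explicit update `C <- C + dt * (f_C + D_C * L)` for the three fields,
#' followed by [apply_noise_with_repair()]. This pure-R version defines the
#' scheme; [run_simulation()] executes the identical update in compiled code.
#'
#' @param state A `cw_state`.
#' @param params A [model_params()] object.
#' @param grid A [grid_spec()] object.
#' @return The advanced `cw_state`.
#' @export
euler_step <- function(state, params, grid) {
  m <- grid$mask != 0
  f <- matrix(0, nrow(state$A), ncol(state$A))
  f[m] <- reaction_rate(state$A[m], state$I[m], state$F[m], params)
  LA <- masked_laplacian(state$A, grid$mask, grid$h)
  LI <- masked_laplacian(state$I, grid$mask, grid$h)
  A <- state$A + grid$dt * (f + params$D_A * LA) * m
  I <- state$I + grid$dt * (-f + params$D_I * LI) * m
  F_ <- state$F + grid$dt * (params$kn * state$A - params$ks * state$F) * m
  for (nm in c("A", "I", "F")) {
    v <- switch(nm, A = A, I = I, F = F_)
    if (any(!is.finite(v[m])))
      stop("numerical failure (non-finite values) in field ", nm,
           " at t = ", state$t + grid$dt)
  }
  out <- structure(list(A = A, I = I, F = F_, t = state$t + grid$dt),
                   class = "cw_state")
  apply_noise_with_repair(out, params$alpha1, params$alpha2, grid$dt,
                          grid$mask)
}

#' Run the reaction-diffusion simulation
#'
#' Integrates the three-field system with the explicit scheme in compiled
#' code, saving a snapshot every `grid$save_every` iterations (by default
#' once per au of time). Every saved state is audited: total `A + I` mass
#' and per-field min/max over the mask, so mass conservation (relative
#' deviation within 1e-11) and positivity can be checked on any run.
#' Trajectories are bit-reproducible for a fixed `seed`.
#'
#' @param params A [model_params()] object.
#' @param grid A [grid_spec()] object.
#' @param init Initialization kind passed to [make_initial_state()], or a
#'   ready-made `cw_state` object.
#' @param duration Simulated time (au); rounded down to whole steps.
#' @param seed Integer seed for the simulation's own random generator.
#' @param fields Which concentration fields to store as snapshot stacks
#'   (the audit always covers all three).
#' @param eps Perturbation amplitude when `init = "random_perturbation"`.
#' @param scaling A [scaling_factors()] object attached for unit conversion
#'   in downstream reports.
#' @return An object of class `rd_sim`: list with `times`, 3-d snapshot
#'   arrays (`A`, and optionally `I`, `F`), the `audit` data frame, the
#'   final full state, and the inputs.
#' @examples
#' g <- grid_spec(make_mask("square", 42))
#' sim <- run_simulation(model_params(), g, duration = 5, seed = 1)
#' summary(sim)
#' @export
run_simulation <- function(params, grid, init = "homogeneous", duration,
                           seed = 1L, fields = "A", eps = 1e-4,
                           scaling = scaling_factors()) {
  stopifnot(inherits(params, "cw_params"), inherits(grid, "cw_grid"))
  r <- stability_ratio(params, grid)
  if (r >= 0.5)
    stop("explicit scheme unstable: stability ratio ", signif(r, 3),
         " >= 1/2; reduce dt or increase h")
  state <- if (inherits(init, "cw_state")) init else
    make_initial_state(init, grid$mask, eps = eps)
  n_steps <- floor(duration / grid$dt + 1e-9)
  res <- cw_simulate_core(state$A, state$I, state$F, grid$mask,
                          unclass(params), grid$h, grid$dt,
                          grid$save_every, as.integer(n_steps),
                          state$t, as.double(seed), numeric(0), list(),
                          "A" %in% fields, "I" %in% fields,
                          "F" %in% fields)
  build_rd_sim(res, params, grid, scaling, seed, fields)
}

build_rd_sim <- function(res, params, grid, scaling, seed, fields) {
  audit <- data.frame(t = res$times, mass = res$mass,
                      min_A = res$minA, max_A = res$maxA,
                      min_I = res$minI, max_I = res$maxI,
                      min_F = res$minF, max_F = res$maxF)
  structure(list(times = res$times,
                 A = res$frames_A, I = res$frames_I, F = res$frames_F,
                 audit = audit,
                 final = structure(list(A = res$A_final, I = res$I_final,
                                        F = res$F_final,
                                        t = res$times[length(res$times)]),
                                   class = "cw_state"),
                 rng_state = res$rng_state, comp = res$comp,
                 params = params, grid = grid, scaling = scaling,
                 seed = seed, fields = fields),
            class = "rd_sim")
}

#' Continue a simulation from its saved end state
#'
#' Resumes integration bit-exactly (the generator state is carried over) and
#' appends the new snapshots and audit rows to the existing series.
#'
#' @param sim An `rd_sim` object.
#' @param duration Additional simulated time (au).
#' @return The extended `rd_sim`.
#' @export
extend_simulation <- function(sim, duration) {
  stopifnot(inherits(sim, "rd_sim"))
  grid <- sim$grid
  n_steps <- floor(duration / grid$dt + 1e-9)
  res <- cw_simulate_core(sim$final$A, sim$final$I, sim$final$F, grid$mask,
                          unclass(sim$params), grid$h, grid$dt,
                          grid$save_every, as.integer(n_steps),
                          sim$final$t, 0, sim$rng_state,
                          if (is.null(sim$comp)) list() else sim$comp,
                          "A" %in% sim$fields, "I" %in% sim$fields,
                          "F" %in% sim$fields)
  new <- build_rd_sim(res, sim$params, grid, sim$scaling, sim$seed,
                      sim$fields)
  # drop the duplicated joint state at the splice point
  keep <- -1L
  sim$times <- c(sim$times, new$times[keep])
  for (f in c("A", "I", "F")) {
    if (is.null(sim[[f]])) next
    sim[[f]] <- bind_frames(sim[[f]], new[[f]], drop_first = TRUE)
  }
  sim$audit <- rbind(sim$audit, new$audit[keep, , drop = FALSE])
  rownames(sim$audit) <- NULL
  sim$final <- new$final
  sim$rng_state <- new$rng_state
  sim$comp <- new$comp
  sim
}

bind_frames <- function(a, b, drop_first = FALSE) {
  if (drop_first) b <- b[, , -1L, drop = FALSE]
  out <- array(0, dim = c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

#' Extract a saved snapshot
#'
#' @param sim An `rd_sim` object.
#' @param t Time (au) of the snapshot; matched to the nearest saved state.
#' @param field Field name (`"A"`, `"I"` or `"F"`); must have been stored.
#' @return The snapshot matrix.
#' @export
get_frame <- function(sim, t, field = "A") {
  stopifnot(inherits(sim, "rd_sim"))
  x <- sim[[field]]
  if (is.null(x))
    stop("field '", field, "' was not stored; rerun with fields = c(...)")
  i <- which.min(abs(sim$times - t))
  if (abs(sim$times[i] - t) > 0.51 * frame_spacing(sim))
    warning("requested t = ", t, " matched to saved state at t = ",
            sim$times[i])
  x[, , i]
}

frame_spacing <- function(sim) {
  if (length(sim$times) < 2) return(sim$grid$save_every * sim$grid$dt)
  median(diff(sim$times))
}

#' @export
print.rd_sim <- function(x, ...) {
  cat("Reaction-diffusion simulation (mass-conserved activator-substrate)\n")
  cat(sprintf("  grid: %d x %d px (%d active), h = %g, dt = %g\n",
              nrow(x$grid$mask), ncol(x$grid$mask), sum(x$grid$mask),
              x$grid$h, x$grid$dt))
  cat(sprintf("  k0 = %g, s2 = %g, gamma = %g, alpha1 = %g, alpha2 = %g\n",
              x$params$k0, x$params$s2, x$params$gamma, x$params$alpha1,
              x$params$alpha2))
  cat(sprintf("  %d saved states over t in [%g, %g] au\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
summary.rd_sim <- function(object, ...) {
  a <- object$audit
  dev <- max(abs(a$mass / a$mass[1] - 1))
  cat("Simulation audit over", nrow(a), "saved states:\n")
  cat(sprintf("  total A+I mass: initial %.6g, max relative deviation %.3g\n",
              a$mass[1], dev))
  cat(sprintf("  min over all states: A %.3g, I %.3g, F %.3g\n",
              min(a$min_A), min(a$min_I), min(a$min_F)))
  cat(sprintf("  final activator amplitude (max - min): %.4g\n",
              a$max_A[nrow(a)] - a$min_A[nrow(a)]))
  invisible(data.frame(mass_rel_dev = dev, min_A = min(a$min_A),
                       min_I = min(a$min_I), min_F = min(a$min_F)))
}

#' @export
plot.rd_sim <- function(x, t = max(x$times), field = "A", ...) {
  fr <- get_frame(x, t, field)
  fr[x$grid$mask == 0] <- NA
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  image(t(fr[nrow(fr):1, ]), axes = FALSE, useRaster = TRUE,
        main = sprintf("%s at t = %g au", field, x$times[which.min(abs(x$times - t))]),
        ...)
  amp <- x$audit$max_A - x$audit$min_A
  plot(x$audit$t, pmax(amp, .Machine$double.xmin), type = "l", log = "y",
       xlab = "t (au)", ylab = "max A - min A", main = "pattern amplitude")
  invisible(x)
}
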