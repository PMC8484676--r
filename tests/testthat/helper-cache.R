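# long simulations reused by several test files, run once per session
.cw_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cw_cache, inherits = FALSE))
    assign(key, force(expr), envir = .cw_cache)
  get(key, envir = .cw_cache, inherits = FALSE)
}

# reference simulation on a 100x100 active mask, grown adaptively until the
# low-activity stage has completed (plus `post` au of high-activity data)
grown_sim <- function(s2, seed, post = 50, max_t = 3000) {
  cached(sprintf("grown_%g_%d_%g", s2, seed, post), {
    g <- grid_spec(make_mask("square", 102))
    p <- model_params(k0 = 0.2, s2 = s2)
    sim <- run_simulation(p, g, duration = 500, seed = seed)
    repeat {
      st <- detect_stages(pattern_amplitude(sim))
      done <- is.finite(st$T_g) && st$T_g < max(sim$times) - 50 &&
        max(sim$times) > st$T_g / 0.9 + post
      if (done || max(sim$times) >= max_t) break
      sim <- extend_simulation(sim, 200)
    }
    sim
  })
}

noisy_sim <- function() {
  cached("noisy", {
    g <- grid_spec(make_mask("square", 102))
    p <- model_params(k0 = 0.2, s2 = 0.8, alpha1 = 3, alpha2 = 0.1)
    run_simulation(p, g, duration = 500, seed = 207)
  })
}
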