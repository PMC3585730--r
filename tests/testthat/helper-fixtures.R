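# Shared fixtures: noiseless generators and small designs built in code.

# Figure-style map parameter sets (alpha = 0.99 throughout; panels differ
# in beta and initial size).
fig_growth <- function(phi_0) growth_params(K = 0.01, phi_inf = 1,
                                            phi_0 = phi_0)
fig_exponential <- function() list(sp = survival_params("exponential",
                                                        0.99, 0.5),
                                   g = fig_growth(0.01))
fig_logistic <- function() list(sp = survival_params("logistic", 0.99, 0.2),
                                g = fig_growth(0.01))
fig_hyperbolic <- function() list(sp = survival_params("hyperbolic",
                                                       0.99, 0.1),
                                  g = fig_growth(0.1))

# Noiseless study-shaped observations generated from a chosen form and
# descriptor (single constant alpha, no dead-cover pathway, continuous
# densities, exact traits).
noiseless_obs <- function(form, descriptor, alpha = 0.95, beta = 0.002,
                          n_quadrats = 15, seed = 42) {
  tr <- truth_params(form = form, descriptor = descriptor,
                     alpha = alpha, beta_live = beta, beta_dead = 0,
                     trait_sdlog = 0, mode = "deterministic")
  simulate_dataset(study_design(n_shores = 1, n_quadrats = n_quadrats),
                   tr, seed = seed)
}

# Brute-force interior-maxima scan (independent oracle for
# count_local_maxima on curves without plateaus).
brute_maxima <- function(curve) {
  n <- length(curve)
  cnt <- 0L
  for (i in 2:(n - 1L)) {
    if (curve[i] > curve[i - 1L] && curve[i] > curve[i + 1L])
      cnt <- cnt + 1L
  }
  cnt
}

# Brute-force toroidal neighbourhood sums (independent O(n^2) oracle for
# local_resource_use).
brute_local_use <- function(arena, radius, side) {
  live <- arena[arena$alive, , drop = FALSE]
  n <- nrow(live)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      dx <- abs(live$x[i] - live$x[j]); dx <- min(dx, side - dx)
      dy <- abs(live$y[i] - live$y[j]); dy <- min(dy, side - dy)
      if (dx * dx + dy * dy <= radius^2) s <- s + live$size[j]
    }
    out[i] <- s
  }
  out
}
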