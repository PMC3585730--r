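#' Parameters of the spatial individual-based simulator
#'
#' Individuals settle as a spatial Poisson process in a square arena,
#' grow by Ford-Walford steps, and die depending on crowding in a
#' circular neighbourhood. Crowding is measured as local resource use:
#' the summed body size of living individuals within
#' `neighborhood_radius` (self included). Two mortality responses are
#' available: `"threshold"` (survive with probability `p_high` while
#' local use is at or below `theta`, `p_low` above it) and `"geometric"`
#' (survival probability `p_high * exp(-gamma * u)`, declining smoothly
#' with local use). The arena wraps toroidally so local densities carry
#' no edge bias.
#'
#' @param arena_side Side length of the square arena (arbitrary length
#'   units).
#' @param settlement_intensity Expected settlers per unit area.
#' @param growth A [growth_params()] object for body size per step.
#' @param neighborhood_radius Radius of the circular neighbourhood.
#' @param response `"threshold"` or `"geometric"`.
#' @param theta Local-resource-use threshold (threshold response).
#' @param p_high,p_low Per-step survival probabilities below/above the
#'   threshold (`0 <= p_low <= p_high <= 1`); `p_high` is also the
#'   crowding-free survival of the geometric response.
#' @param gamma Decay rate of the geometric response per unit local use.
#' @param n_steps Number of time steps to simulate.
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   output.
#' @return An object of class `"ibm_params"`.
#' @export
ibm_params <- function(arena_side = 5,
                       settlement_intensity = 10,
                       growth = growth_params(K = 0.15, phi_inf = 1,
                                              phi_0 = 0.05),
                       neighborhood_radius = 0.5,
                       response = c("threshold", "geometric"),
                       theta = 2, p_high = 0.99, p_low = 0.4,
                       gamma = 1, n_steps = 15, seed = 1) {
  response <- match.arg(response)
  stopifnot(arena_side > 0, settlement_intensity >= 0,
            inherits(growth, "growth_params"),
            neighborhood_radius > 0, theta > 0,
            p_low >= 0, p_high >= p_low, p_high <= 1,
            gamma >= 0, n_steps >= 0)
  structure(list(arena_side = arena_side,
                 settlement_intensity = settlement_intensity,
                 growth = growth,
                 neighborhood_radius = neighborhood_radius,
                 response = response, theta = theta,
                 p_high = p_high, p_low = p_low, gamma = gamma,
                 n_steps = as.integer(n_steps), seed = seed),
            class = "ibm_params")
}

#' @export
print.ibm_params <- function(x, ...) {
  cat("IBM parameters: ", x$response, " response, arena ",
      format(x$arena_side), " x ", format(x$arena_side),
      ", intensity ", format(x$settlement_intensity), "\n", sep = "")
  invisible(x)
}

#' Seed an arena with Poisson-distributed settlers
#'
#' Draws the settler count as Poisson(intensity * arena area) and places
#' each individual independently and uniformly in the arena, at the
#' initial body size `growth$phi_0`.
#'
#' @param params An [ibm_params()] object. Uses the current RNG state
#'   (call `set.seed()` first for reproducibility; [run_ibm()] does this
#'   for you).
#' @return A data.frame with columns `x`, `y`, `size`, `alive`.
#' @export
seed_arena <- function(params) {
  stopifnot(inherits(params, "ibm_params"))
  n <- stats::rpois(1, params$settlement_intensity * params$arena_side^2)
  data.frame(x = stats::runif(n, 0, params$arena_side),
             y = stats::runif(n, 0, params$arena_side),
             size = rep(params$growth$phi_0, n),
             alive = rep(TRUE, n))
}

#' Local resource use of every living individual
#'
#' For each living individual, the summed body size of living
#' individuals within the neighbourhood radius, self included — so the
#' value is always at least the individual's own size. Distances are
#' toroidal (the arena wraps) to avoid edge-density bias.
#'
#' @param arena A data.frame as produced by [seed_arena()].
#' @param radius Neighbourhood radius, > 0.
#' @param arena_side Arena side length (needed for the toroidal wrap).
#' @return Numeric vector of local resource use, one entry per *living*
#'   individual, in arena row order.
#' @export
local_resource_use <- function(arena, radius, arena_side) {
  stopifnot(is.data.frame(arena), radius > 0, arena_side > 0)
  live <- arena[arena$alive, , drop = FALSE]
  n <- nrow(live)
  if (n == 0L) return(numeric(0))
  dx <- abs(outer(live$x, live$x, "-"))
  dx <- pmin(dx, arena_side - dx)
  dy <- abs(outer(live$y, live$y, "-"))
  dy <- pmin(dy, arena_side - dy)
  within <- (dx * dx + dy * dy) <= radius^2
  as.vector(within %*% live$size)
}

#' Draw one survival step from local resource use
#'
#' Threshold response: survive with probability `p_high` when local use
#' `u <= theta` (boundary inclusive), `p_low` above. Geometric response:
#' survive with probability `p_high * exp(-gamma * u)`.
#'
#' @param u Local resource use, >= 0. Vectorised.
#' @param params An [ibm_params()] object. Uses the current RNG state.
#' @return Logical vector: TRUE for survivors.
#' @export
survive_step <- function(u, params) {
  stopifnot(inherits(params, "ibm_params"))
  if (any(u < 0)) stop("'u' must be >= 0")
  p <- if (params$response == "threshold") {
    ifelse(u <= params$theta, params$p_high, params$p_low)
  } else {
    params$p_high * exp(-params$gamma * u)
  }
  stats::runif(length(u)) < p
}

#' Run the individual-based simulation
#'
#' Seeds the arena, then alternates mortality (from local resource use)
#' and growth for `n_steps` steps. Per-step summaries record the settler
#' density, the live density, and the mean body size of survivors. The
#' run is fully reproducible from `params$seed`.
#'
#' @param params An [ibm_params()] object.
#' @return A list of class `"ibm_run"`: `history` (data.frame with
#'   columns `step`, `n_alive`, `density`, `mean_size`),
#'   `settler_density`, `params`, and `arena` (final state).
#' @export
run_ibm <- function(params) {
  stopifnot(inherits(params, "ibm_params"))
  if (!is.null(.GlobalEnv$.Random.seed)) {
    old <- .GlobalEnv$.Random.seed
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  set.seed(as.integer(params$seed %% 2147483629))
  arena <- seed_arena(params)
  area <- params$arena_side^2
  settler_density <- nrow(arena) / area
  hist <- vector("list", params$n_steps + 1L)
  summarize <- function(step) {
    live <- arena$size[arena$alive]
    data.frame(step = step, n_alive = length(live),
               density = length(live) / area,
               mean_size = if (length(live)) mean(live) else NA_real_)
  }
  hist[[1]] <- summarize(0L)
  if (params$n_steps > 0) {
    for (s in seq_len(params$n_steps)) {
      if (any(arena$alive)) {
        u <- local_resource_use(arena, params$neighborhood_radius,
                                params$arena_side)
        surv <- survive_step(u, params)
        arena$alive[arena$alive] <- surv
        arena$size[arena$alive] <- grow_step(arena$size[arena$alive],
                                             params$growth)
      }
      hist[[s + 1L]] <- summarize(s)
    }
  }
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  structure(list(history = history,
                 settler_density = settler_density,
                 params = params, arena = arena),
            class = "ibm_run")
}

#' @export
print.ibm_run <- function(x, ...) {
  h <- x$history
  cat("IBM run (", x$params$response, "): settlers ",
      h$n_alive[1], ", survivors at step ", max(h$step), ": ",
      h$n_alive[nrow(h)], "\n", sep = "")
  invisible(x)
}

#' Settler-recruit experiment over a settlement-intensity gradient
#'
#' Runs the IBM across a grid of settlement intensities with several
#' replicate seeds per intensity, and summarises live density at every
#' step. The per-step mean density as a function of settler density is
#' the simulated settler-recruit curve, ready for
#' [classify_map_shape()].
#'
#' @param intensity_grid Increasing vector of settlement intensities.
#' @param params An [ibm_params()] object (its
#'   `settlement_intensity` is overridden along the grid).
#' @param replicates Replicate runs per intensity.
#' @param seed Base seed; replicate `r` at grid point `i` uses a
#'   deterministic seed derived from `(seed, i, r)`.
#' @return A list of class `"sr_experiment"`: `runs` (tidy data.frame:
#'   `intensity`, `replicate`, `step`, `settler_density`, `density`,
#'   `mean_size`), `mean_density` and `sd_density` (step x intensity
#'   matrices), `intensity_grid`, `steps`.
#' @export
settler_recruit_experiment <- function(intensity_grid, params,
                                       replicates = 3, seed = 1) {
  stopifnot(length(intensity_grid) >= 1L, all(intensity_grid >= 0),
            !is.unsorted(intensity_grid), replicates >= 1,
            inherits(params, "ibm_params"))
  runs <- list()
  for (i in seq_along(intensity_grid)) {
    for (r in seq_len(replicates)) {
      p <- params
      p$settlement_intensity <- intensity_grid[i]
      p$seed <- (abs(seed) * 48271 + i * 524287 + r * 69621) %% 2147483629
      out <- run_ibm(p)
      h <- out$history
      runs[[length(runs) + 1L]] <- data.frame(
        intensity = intensity_grid[i], replicate = r, step = h$step,
        settler_density = out$settler_density,
        density = h$density, mean_size = h$mean_size,
        row.names = NULL)
    }
  }
  runs <- do.call(rbind, runs)
  steps <- sort(unique(runs$step))
  mean_d <- tapply(runs$density, list(runs$step, runs$intensity), mean)
  sd_d <- tapply(runs$density, list(runs$step, runs$intensity),
                 stats::sd)
  structure(list(runs = runs, mean_density = mean_d, sd_density = sd_d,
                 intensity_grid = intensity_grid, steps = steps),
            class = "sr_experiment")
}

#' @export
print.sr_experiment <- function(x, ...) {
  cat("Settler-recruit experiment: ", length(x$intensity_grid),
      " intensities x ", max(x$runs$replicate), " replicates, steps 0..",
      max(x$steps), "\n", sep = "")
  invisible(x)
}

#' Shape class of the simulated settler-recruit curve at each step
#'
#' @param exp A `"sr_experiment"` object.
#' @param tol Relative tolerance for [classify_map_shape()].
#' @return Named character vector: one shape class per step (mean curve
#'   over replicates).
#' @export
experiment_shape_by_step <- function(exp, tol = 1e-9) {
  stopifnot(inherits(exp, "sr_experiment"))
  out <- apply(exp$mean_density, 1, classify_map_shape, tol = tol)
  names(out) <- paste0("t", rownames(exp$mean_density))
  out
}
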