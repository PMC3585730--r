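#' Per-step survival fraction as a function of resource use
#'
#' Evaluates the survival fraction `lambda(u)` for resource use
#' `u = N_t * phi_t` (density times mean body size) under the chosen
#' functional form:
#' \describe{
#'   \item{exponential}{`lambda = alpha * exp(-beta * u)`}
#'   \item{logistic}{`lambda = 1 / (1 + alpha' * exp(beta * u))` with
#'     `alpha' = 1/alpha - 1` (default, decreasing convention; the
#'     `"literal"` convention flips the sign of the exponent)}
#'   \item{hyperbolic}{`lambda = alpha / (1 + beta * u)`}
#' }
#' For every form `lambda(0) = alpha`, and `lambda` is strictly decreasing
#' in `u` when `beta > 0` (under the default logistic convention).
#'
#' @param params A [survival_params()] object.
#' @param u Resource-use scalar(s), >= 0. Vectorised.
#' @return Survival fraction(s) in (0, 1].
#' @examples
#' survival_fraction(survival_params("hyperbolic", 0.99, 0.1), u = 10)
#' @export
survival_fraction <- function(params, u) {
  if (!inherits(params, "survival_params"))
    stop("'params' must be a survival_params object")
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("'u' must be finite numeric")
  if (any(u < 0))
    stop("resource use 'u' must be >= 0 (got ", min(u), ")")
  a <- params$alpha
  b <- params$beta
  switch(params$form,
    exponential = a * exp(-b * u),
    logistic = {
      ap <- 1 / a - 1
      s <- if (params$logistic_sign == "decreasing") 1 else -1
      1 / (1 + ap * exp(s * b * u))
    },
    hyperbolic = a / (1 + b * u))
}

#' One Ford-Walford growth step
#'
#' Advances mean body size by one base time step of the recursion
#' `phi_{t+1} = phi_t * exp(-K) + phi_inf * (1 - exp(-K))`. The asymptote
#' `phi_inf` is a fixed point and sizes approach it monotonically.
#'
#' @param phi Current body size(s), > 0. Vectorised.
#' @param g A [growth_params()] object.
#' @param delta Number of base time steps to advance (default 1; may be
#'   fractional, using the continuous von Bertalanffy interpolation).
#' @return Body size(s) after `delta` steps.
#' @examples
#' grow_step(0.01, growth_params(K = 0.01, phi_inf = 1, phi_0 = 0.01))
#' @export
grow_step <- function(phi, g, delta = 1) {
  if (!inherits(g, "growth_params"))
    stop("'g' must be a growth_params object")
  if (!is.numeric(phi) || any(!is.finite(phi)) || any(phi <= 0))
    stop("'phi' must be > 0")
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0)
  e <- exp(-g$K * delta)
  phi * e + g$phi_inf * (1 - e)
}

#' Construct a cohort state
#'
#' A cohort state holds the step index `t`, the density `N` (individuals
#' per quadrat) and the mean body size `phi` of a closed cohort.
#'
#' @param t Integer step index (>= 0).
#' @param N Density, >= 0.
#' @param phi Mean body size, > 0.
#' @return An object of class `"cohort_state"`.
#' @export
cohort_state <- function(t, N, phi) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0, t == round(t),
            is.numeric(N), length(N) == 1L, is.finite(N),
            is.numeric(phi), length(phi) == 1L, is.finite(phi))
  if (N < 0) stop("'N' must be >= 0 (got ", N, ")")
  if (phi <= 0) stop("'phi' must be > 0 (got ", phi, ")")
  structure(list(t = as.integer(t), N = N, phi = phi),
            class = "cohort_state")
}

#' @export
print.cohort_state <- function(x, ...) {
  cat("Cohort state: t = ", x$t, ", N = ", format(x$N),
      ", phi = ", format(x$phi), "\n", sep = "")
  invisible(x)
}

#' Advance a cohort by one time step
#'
#' Applies one step of the cohort recursion: the density is thinned by the
#' survival fraction evaluated at the current resource use `N * phi`, and
#' the body size advances by one Ford-Walford step.
#'
#' @param state A [cohort_state()] object.
#' @param sp A [survival_params()] object.
#' @param g A [growth_params()] object.
#' @return The next [cohort_state()].
#' @examples
#' st <- cohort_state(0, N = 10, phi = 0.01)
#' step_cohort(st, survival_params("exponential", 0.99, 0.5),
#'             growth_params(0.01, 1, 0.01))
#' @export
step_cohort <- function(state, sp, g) {
  if (!inherits(state, "cohort_state"))
    stop("'state' must be a cohort_state object")
  N1 <- state$N * survival_fraction(sp, state$N * state$phi)
  cohort_state(state$t + 1L, N1, grow_step(state$phi, g))
}

#' Simulate a closed-cohort trajectory
#'
#' Iterates the cohort recursion from initial density `N0` and initial
#' body size `phi0` for `n_steps` steps. Density is non-increasing along
#' the trajectory (survival fractions never exceed 1) and body size grows
#' monotonically towards its asymptote.
#'
#' @param N0 Initial density (number of settlers), >= 0.
#' @param phi0 Initial mean body size, > 0.
#' @param sp A [survival_params()] object.
#' @param g A [growth_params()] object.
#' @param n_steps Number of steps to iterate, >= 0.
#' @return A data.frame with columns `t`, `N`, `phi` and `n_steps + 1`
#'   rows; row 1 is the initial state at `t = 0`.
#' @examples
#' simulate_cohort(10, 0.01, survival_params("exponential", 0.99, 0.5),
#'                 growth_params(0.01, 1, 0.01), n_steps = 2)
#' @export
simulate_cohort <- function(N0, phi0, sp, g, n_steps) {
  stopifnot(is.numeric(n_steps), length(n_steps) == 1L,
            n_steps == round(n_steps))
  if (n_steps < 0) stop("'n_steps' must be >= 0 (got ", n_steps, ")")
  if (!is.numeric(N0) || N0 < 0) stop("'N0' must be >= 0")
  if (!is.numeric(phi0) || phi0 <= 0) stop("'phi0' must be > 0")
  n_steps <- as.integer(n_steps)
  N <- phi <- numeric(n_steps + 1L)
  N[1] <- N0
  phi[1] <- phi0
  if (n_steps > 0) {
    for (i in seq_len(n_steps)) {
      N[i + 1L] <- N[i] * survival_fraction(sp, N[i] * phi[i])
      phi[i + 1L] <- grow_step(phi[i], g)
    }
  }
  data.frame(t = 0:n_steps, N = N, phi = phi)
}

#' Resource-constraint diagnostic
#'
#' Checks the resource constraint `A >= N * phi`: total resource use by a
#' cohort cannot exceed the available resource (for space-limited sessile
#' organisms, the quadrat area). The check is a diagnostic only — it never
#' alters a trajectory, since the published recruitment maps iterate the
#' unconstrained recursion.
#'
#' @param state A [cohort_state()] object (or any list with `N` and `phi`).
#' @param A Total available resource, > 0 (same units as `N * phi`).
#' @return A list with `violated` (logical) and `excess`
#'   (`max(0, N*phi - A)`).
#' @export
resource_violation <- function(state, A) {
  stopifnot(is.numeric(A), length(A) == 1L)
  if (A <= 0) stop("available resource 'A' must be > 0 (got ", A, ")")
  use <- state$N * state$phi
  list(violated = use > A, excess = max(0, use - A))
}
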