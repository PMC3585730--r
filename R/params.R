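#' Survival-form parameters
#'
#' Bundle of parameters for one functional form of per-step survival.
#' All three forms share the resource-independent parameter `alpha` (the
#' survival fraction per base time step at zero resource use) and the
#' resource-use-dependent mortality parameter `beta`, whose units are the
#' inverse of the resource-use unit (e.g. mm^-2 when cover is measured in
#' mm^2 per quadrat); `1/beta` is proportional to the carrying capacity of
#' the system.
#'
#' For the logistic form the survival at zero resource use is written in
#' terms of a derived parameter `alpha' = 1/alpha - 1`, so that
#' `lambda(0) = 1/(1 + alpha') = alpha`. Under the default
#' `logistic_sign = "decreasing"` convention survival is
#' `1/(1 + alpha' * exp(beta * u))`, which declines with resource use `u`
#' as a mortality parameter requires. The `"literal"` convention instead
#' uses `exp(-beta * u)` inside the denominator, which makes survival
#' *increase* with resource use; it is provided for comparison only.
#'
#' @param form One of `"exponential"`, `"logistic"`, `"hyperbolic"`.
#' @param alpha Resource-independent survival fraction per base time step,
#'   in (0, 1].
#' @param beta Resource-use-dependent mortality parameter, >= 0.
#' @param logistic_sign Sign convention for the logistic exponent; one of
#'   `"decreasing"` (default) or `"literal"`. Ignored by the other forms.
#' @return An object of class `"survival_params"`.
#' @seealso [survival_fraction()], [growth_params()]
#' @examples
#' sp <- survival_params("exponential", alpha = 0.99, beta = 0.5)
#' survival_fraction(sp, u = 0)
#' @export
survival_params <- function(form = c("exponential", "logistic", "hyperbolic"),
                            alpha, beta,
                            logistic_sign = c("decreasing", "literal")) {
  form <- match.arg(form)
  logistic_sign <- match.arg(logistic_sign)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha <= 0 || alpha > 1)
    stop("'alpha' must satisfy 0 < alpha <= 1 (got ", alpha, ")")
  if (beta < 0)
    stop("'beta' must be >= 0 (got ", beta, ")")
  structure(
    list(form = form, alpha = alpha, beta = beta,
         logistic_sign = logistic_sign),
    class = "survival_params")
}

#' @export
print.survival_params <- function(x, ...) {
  cat("Survival form: ", x$form, "\n", sep = "")
  cat("  alpha (resource-independent survival/step): ", format(x$alpha),
      "\n", sep = "")
  cat("  beta  (resource-use mortality parameter):   ", format(x$beta),
      "\n", sep = "")
  if (x$form == "logistic") {
    cat("  alpha' = 1/alpha - 1 = ", format(1 / x$alpha - 1),
        "  [", x$logistic_sign, " sign convention]\n", sep = "")
  }
  invisible(x)
}

#' Ford-Walford growth parameters
#'
#' Parameters of the Ford-Walford recursion
#' `phi_{t+1} = phi_t * exp(-K) + phi_inf * (1 - exp(-K))`, the discrete
#' form of von Bertalanffy growth towards the asymptotic body size
#' `phi_inf`.
#'
#' @param K Growth rate per base time step (dimensionless, >= 0).
#' @param phi_inf Asymptotic body size (area units, > 0).
#' @param phi_0 Initial body size (area units, 0 < `phi_0` <= `phi_inf`).
#' @return An object of class `"growth_params"`.
#' @seealso [grow_step()]
#' @examples
#' g <- growth_params(K = 0.01, phi_inf = 1, phi_0 = 0.01)
#' grow_step(0.01, g)
#' @export
growth_params <- function(K, phi_inf, phi_0) {
  stopifnot(is.numeric(K), length(K) == 1L, is.finite(K),
            is.numeric(phi_inf), length(phi_inf) == 1L, is.finite(phi_inf),
            is.numeric(phi_0), length(phi_0) == 1L, is.finite(phi_0))
  if (K < 0) stop("'K' must be >= 0 (got ", K, ")")
  if (phi_inf <= 0) stop("'phi_inf' must be > 0 (got ", phi_inf, ")")
  if (phi_0 <= 0 || phi_0 > phi_inf)
    stop("'phi_0' must satisfy 0 < phi_0 <= phi_inf (got ", phi_0, ")")
  structure(list(K = K, phi_inf = phi_inf, phi_0 = phi_0),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Ford-Walford growth: K = ", format(x$K),
      ", phi_inf = ", format(x$phi_inf),
      ", phi_0 = ", format(x$phi_0), "\n", sep = "")
  invisible(x)
}
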