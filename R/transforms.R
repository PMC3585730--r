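#' Interval survival from start and end densities
#'
#' Computes the observed survival fraction `S = N_end / N_start` over one
#' census interval of a closed cohort. For transform safety the value is
#' also clipped into `[eps, 1 - eps]`; the raw ratio is retained
#' alongside. Observations with `N_start = 0` carry no survival
#' information and are flagged for exclusion from fitting; `N_end >
#' N_start` (a recount error in an intended closed cohort) triggers a
#' warning and is clipped rather than excluded, keeping the quadrat design
#' balanced.
#'
#' @param N_start,N_end Live densities at the start and end of the
#'   interval. Vectorised.
#' @param eps Clipping constant (default `1e-6`).
#' @return A data.frame with columns `S_raw`, `S` (clipped), `excluded`
#'   (logical), `clipped` (logical), `flag` (character, `""` if none).
#' @examples
#' interval_survival(100, 80)
#' @export
interval_survival <- function(N_start, N_end, eps = 1e-6) {
  stopifnot(is.numeric(N_start), is.numeric(N_end),
            length(N_start) == length(N_end), eps > 0, eps < 0.5)
  if (any(N_start < 0, na.rm = TRUE) || any(N_end < 0, na.rm = TRUE))
    stop("densities must be >= 0")
  S_raw <- ifelse(N_start > 0, N_end / N_start, NA_real_)
  excluded <- !(N_start > 0)
  flag <- ifelse(excluded, "zero initial density", "")
  over <- !excluded & S_raw > 1
  if (any(over, na.rm = TRUE))
    warning(sum(over, na.rm = TRUE),
            " observation(s) with N_end > N_start in a closed cohort; ",
            "survival clipped to 1 - eps")
  S <- pmin(pmax(S_raw, eps), 1 - eps)
  clipped <- !excluded & (S != S_raw)
  flag[over] <- "survival > 1 (clipped)"
  flag[!excluded & S_raw <= eps] <- "survival at lower clip"
  data.frame(S_raw = S_raw, S = S, excluded = excluded,
             clipped = clipped, flag = flag,
             stringsAsFactors = FALSE)
}

#' Standardise interval survival to a common base interval
#'
#' Converts a survival fraction observed over `T_days` days to the
#' equivalent survival over a base interval (30 days by default), assuming
#' survival compounds multiplicatively over sub-intervals (constant
#' per-day hazard within the interval): `S_30 = S^(30 / T_days)`.
#'
#' @param S Survival fraction(s) in (0, 1].
#' @param T_days Interval length(s) in days, > 0.
#' @param base Base interval length in days (default 30).
#' @return Per-base-interval survival fraction(s).
#' @examples
#' standardize_survival(0.64, 60)  # 0.8
#' @export
standardize_survival <- function(S, T_days, base = 30) {
  stopifnot(is.numeric(S), is.numeric(T_days), base > 0)
  if (any(S <= 0, na.rm = TRUE) || any(S > 1, na.rm = TRUE))
    stop("'S' must be in (0, 1]")
  if (any(T_days <= 0, na.rm = TRUE))
    stop("'T_days' must be > 0")
  S^(base / T_days)
}

#' Rescale a per-base-interval survival prediction to an interval
#'
#' The exact inverse of [standardize_survival()]:
#' `lambda_T = lambda_30^(T_days / 30)`.
#'
#' @param lambda_30 Per-base-interval survival fraction(s) in (0, 1].
#' @param T_days Target interval length(s) in days, > 0.
#' @param base Base interval length in days (default 30).
#' @return Survival fraction(s) over `T_days`.
#' @examples
#' rescale_prediction(0.5, 60)  # 0.25
#' @export
rescale_prediction <- function(lambda_30, T_days, base = 30) {
  stopifnot(is.numeric(lambda_30), is.numeric(T_days), base > 0)
  if (any(lambda_30 <= 0, na.rm = TRUE) || any(lambda_30 > 1, na.rm = TRUE))
    stop("'lambda_30' must be in (0, 1]")
  if (any(T_days <= 0, na.rm = TRUE))
    stop("'T_days' must be > 0")
  lambda_30^(T_days / base)
}

#' Linearising transform of the survival scale
#'
#' Maps a survival fraction to the response scale on which each
#' functional form is linear in the resource-use predictor:
#' \describe{
#'   \item{exponential}{`ln S = ln(alpha) - beta * X`}
#'   \item{logistic}{`ln(1/S - 1) = ln(alpha') + beta * X`}
#'   \item{hyperbolic}{`1/S = 1/alpha + (beta/alpha) * X`}
#' }
#'
#' @param form One of `"exponential"`, `"logistic"`, `"hyperbolic"`.
#' @param S Survival fraction(s) strictly inside (0, 1) (after clipping).
#' @return Transformed response value(s).
#' @examples
#' linearize("hyperbolic", 0.5)  # 2
#' linearize("logistic", 0.5)    # 0
#' @export
linearize <- function(form = c("exponential", "logistic", "hyperbolic"), S) {
  form <- match.arg(form)
  stopifnot(is.numeric(S))
  if (any(S <= 0, na.rm = TRUE) || any(S >= 1, na.rm = TRUE))
    stop("'S' must lie strictly inside (0, 1); clip first")
  switch(form,
    exponential = log(S),
    logistic = log(1 / S - 1),
    hyperbolic = 1 / S)
}

#' Back-transform regression coefficients to survival-form parameters
#'
#' Inverts the linearisation of [linearize()]: given the intercept and
#' slope of the transformed-scale regression, recovers `(alpha, beta)`.
#' Inadmissible results (`alpha` outside (0, 1] or `beta < 0`) are
#' returned with `admissible = FALSE` and never silently clamped.
#'
#' @param form One of `"exponential"`, `"logistic"`, `"hyperbolic"`.
#' @param intercept,slope Transformed-scale regression coefficients.
#' @return A list with `alpha`, `beta`, `admissible` (logical) and
#'   `note` (character, reason when inadmissible).
#' @examples
#' back_transform_params("hyperbolic", intercept = 2, slope = 1)
#' @export
back_transform_params <- function(form = c("exponential", "logistic",
                                           "hyperbolic"),
                                  intercept, slope) {
  form <- match.arg(form)
  stopifnot(is.numeric(intercept), is.numeric(slope),
            length(intercept) == 1L, length(slope) == 1L)
  out <- switch(form,
    exponential = list(alpha = exp(intercept), beta = -slope),
    logistic = {
      ap <- exp(intercept)
      list(alpha = 1 / (1 + ap), beta = slope)
    },
    hyperbolic = {
      a <- 1 / intercept
      list(alpha = a, beta = slope * a)
    })
  note <- character(0)
  if (!is.finite(out$alpha) || out$alpha <= 0 || out$alpha > 1)
    note <- c(note, sprintf("alpha = %.6g outside (0, 1]", out$alpha))
  if (!is.finite(out$beta) || out$beta < 0)
    note <- c(note, sprintf("beta = %.6g < 0", out$beta))
  out$admissible <- length(note) == 0L
  out$note <- paste(note, collapse = "; ")
  out
}

#' Adjusted R-squared
#'
#' `1 - (1 - R^2) * (n - 1) / (n - p - 1)` with `R^2 = 1 - rss/tss`, for
#' a regression with `p` predictors (excluding the intercept) fitted to
#' `n` observations.
#'
#' @param rss Residual sum of squares, >= 0.
#' @param tss Total sum of squares, > 0.
#' @param n Number of observations.
#' @param p Number of predictors excluding the intercept.
#' @return Adjusted R-squared (<= 1; can be negative).
#' @examples
#' adjusted_r2(rss = 0.5, tss = 1, n = 52, p = 1)
#' @export
adjusted_r2 <- function(rss, tss, n, p) {
  stopifnot(is.numeric(rss), rss >= 0, is.numeric(tss),
            is.numeric(n), is.numeric(p))
  if (tss <= 0) stop("'tss' must be > 0")
  if (n <= p + 1) stop("need n > p + 1 (got n = ", n, ", p = ", p, ")")
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}
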