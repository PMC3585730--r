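#' Build the regression design for one descriptor and form
#'
#' Assembles the paired (predictor, transformed response) samples used by
#' the linearised fits: the resource-use predictor `X` for the chosen
#' body-size descriptor (`density`: `X = N_start`; `basal_cover`:
#' `X = basal_area * N_start`; `operc_cover`:
#' `X = operc_area * N_start`), and the transformed per-30-day survival
#' response for the chosen functional form. Observations flagged by
#' [interval_survival()] (zero initial density) are dropped; the number
#' dropped and the number of clipped survivals are attached as
#' attributes.
#'
#' @param observations A quadrat-census data.frame with columns `shore`,
#'   `quadrat`, `period`, `T_days`, `N_start`, `N_end`, `operc_area`,
#'   `basal_area`, `dead_cover` (see [read_observations()]).
#' @param descriptor One of `"density"`, `"basal_cover"`, `"operc_cover"`.
#' @param form Functional form for the response transform (default
#'   `"logistic"`).
#' @param base Base interval in days for time standardisation (default 30).
#' @return A data.frame with columns `shore`, `quadrat`, `period`,
#'   `T_days`, `X`, `S_raw`, `S_30`, `y`, `dead_cover`, `clipped`;
#'   attributes `n_excluded` and `n_clipped`.
#' @export
build_design <- function(observations,
                         descriptor = c("density", "basal_cover",
                                        "operc_cover"),
                         form = c("logistic", "exponential", "hyperbolic"),
                         base = 30) {
  descriptor <- match.arg(descriptor)
  form <- match.arg(form)
  obs <- check_observations(observations)
  if (nrow(obs) == 0L) stop("no observations supplied")
  trait_col <- switch(descriptor, density = NULL,
                      basal_cover = "basal_area",
                      operc_cover = "operc_area")
  if (!is.null(trait_col)) {
    bad <- !is.finite(obs[[trait_col]])
    if (any(bad))
      stop("descriptor '", descriptor, "' requires finite '", trait_col,
           "': ", sum(bad), " offending row(s)")
  }
  iv <- interval_survival(obs$N_start, obs$N_end)
  keep <- !iv$excluded
  n_excluded <- sum(!keep)
  obs <- obs[keep, , drop = FALSE]
  iv <- iv[keep, , drop = FALSE]
  X <- switch(descriptor,
    density = obs$N_start,
    basal_cover = obs$basal_area * obs$N_start,
    operc_cover = obs$operc_area * obs$N_start)
  S_30 <- standardize_survival(iv$S, obs$T_days, base = base)
  out <- data.frame(shore = obs$shore, quadrat = obs$quadrat,
                    period = obs$period, T_days = obs$T_days,
                    X = X, S_raw = iv$S_raw, S_30 = S_30,
                    y = linearize(form, S_30),
                    dead_cover = obs$dead_cover,
                    clipped = iv$clipped,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_clipped") <- sum(iv$clipped)
  out
}

# minimal schema check shared by fitting and IO; returns the data.frame
check_observations <- function(obs) {
  need <- c("shore", "quadrat", "period", "T_days", "N_start", "N_end",
            "operc_area", "basal_area", "dead_cover")
  if (!is.data.frame(obs))
    stop("'observations' must be a data.frame")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observations are missing column(s): ", paste(miss, collapse = ", "))
  if (any(obs$T_days <= 0)) stop("'T_days' must be > 0")
  if (any(obs$N_start < 0) || any(obs$N_end < 0))
    stop("densities must be >= 0")
  obs
}

#' Fit one survival functional form by linearised regression
#'
#' Fits one functional form to quadrat census observations: interval
#' survivals are standardised to a 30-day base, transformed to the form's
#' linear scale, and regressed on the resource-use predictor by ordinary
#' least squares. The intercept and slope are back-transformed to
#' `(alpha, beta)`. Goodness of fit is the adjusted R-squared on the
#' transformed scale (the scale on which the model is fitted); an
#' R-squared on the survival scale is also reported for transparency.
#' Each quadrat-by-interval record carries equal weight.
#'
#' The study design this pipeline targets censuses each shore separately,
#' so fits are intended per shore; [fit_all_forms()] handles the
#' splitting. `fit_form` itself fits exactly the observations it is
#' given.
#'
#' @inheritParams build_design
#' @param form One of `"exponential"`, `"logistic"`, `"hyperbolic"`.
#' @return An object of class `"recruit_fit"`; see Details. Key fields:
#'   `alpha`, `beta` (back-transformed, with `admissible` flag), `n`,
#'   `adj_r2` (transformed scale), `r2_survival`, `aic`, `coefficients`,
#'   `residuals`, `diagnostics` (from [residual_trend()]).
#' @examples
#' obs <- simulate_dataset(study_design(n_shores = 1, n_quadrats = 20),
#'                         truth_params(), seed = 1)
#' fit_form(obs, "logistic", "operc_cover")
#' @export
fit_form <- function(observations,
                     form = c("exponential", "logistic", "hyperbolic"),
                     descriptor = c("density", "basal_cover", "operc_cover"),
                     base = 30) {
  form <- match.arg(form)
  descriptor <- match.arg(descriptor)
  d <- build_design(observations, descriptor, form, base)
  if (nrow(d) < 3L)
    stop("need >= 3 usable observations (got ", nrow(d), ")")
  if (stats::sd(d$X) == 0)
    stop("rank-deficient design: predictor '", descriptor, "' is constant")
  fit <- stats::lm(y ~ X, data = d)
  co <- stats::coef(fit)
  bt <- back_transform_params(form, unname(co[1]), unname(co[2]))
  finish_fit(fit, d, form = form, descriptor = descriptor, base = base,
             alpha = bt$alpha, beta = c(beta = bt$beta),
             admissible = bt$admissible, note = bt$note,
             spec = list(alpha_by_period = FALSE,
                         include_dead_cover = FALSE))
}

# assemble a recruit_fit object from an lm fit on a build_design frame
finish_fit <- function(fit, d, form, descriptor, base, alpha, beta,
                       admissible, note, spec) {
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((d$y - mean(d$y))^2)
  n <- nrow(d)
  p <- length(stats::coef(fit)) - 1L
  # survival-scale fit: back-transform fitted values and compare to S_30
  S_hat <- inv_linearize(form, stats::fitted(fit))
  r2_surv <- 1 - sum((d$S_30 - S_hat)^2) / sum((d$S_30 - mean(d$S_30))^2)
  k <- length(stats::coef(fit)) + 1L  # + error variance
  structure(
    list(form = form, descriptor = descriptor, spec = spec, base = base,
         alpha = alpha, beta = beta,
         admissible = admissible, note = note,
         coefficients = stats::coef(fit),
         n = n, k = k, rss = rss, tss = tss,
         adj_r2 = adjusted_r2(rss, tss, n, p),
         r2_survival = r2_surv,
         aic = gaussian_aic(rss, n, length(stats::coef(fit))),
         residuals = res, fitted = stats::fitted(fit),
         design = d,
         n_excluded = attr(d, "n_excluded"),
         n_clipped = attr(d, "n_clipped"),
         diagnostics = residual_trend_core(res, d$X),
         lm = fit),
    class = "recruit_fit")
}

# inverse of linearize(): transformed scale back to survival
inv_linearize <- function(form, y) {
  switch(form,
    exponential = exp(y),
    logistic = 1 / (1 + exp(y)),
    hyperbolic = 1 / y)
}

#' @export
print.recruit_fit <- function(x, ...) {
  cat("Linearised ", x$form, " survival fit (descriptor: ", x$descriptor,
      ")\n", sep = "")
  if (isTRUE(x$spec$alpha_by_period)) {
    cat("  alpha by period:\n")
    for (p in names(x$alpha))
      cat("    ", p, ": ", format(x$alpha[[p]], digits = 4), "\n", sep = "")
  } else {
    cat("  alpha = ", format(x$alpha, digits = 4), "\n", sep = "")
  }
  for (b in names(x$beta))
    cat("  ", b, " = ", format(x$beta[[b]], digits = 4), "\n", sep = "")
  if (!x$admissible) cat("  [inadmissible: ", x$note, "]\n", sep = "")
  cat("  n = ", x$n, ", adjusted R2 (transformed scale) = ",
      format(x$adj_r2, digits = 3), ", AIC = ", format(x$aic, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Residual-trend diagnostics for a linearised fit
#'
#' A well-specified functional form should leave residuals with no trend
#' against the resource-use predictor. Reports the Spearman rank
#' correlation of the residuals and of their absolute values against the
#' predictor, plus the number of sign runs in predictor order (few runs
#' indicate systematic curvature). Numbers only — no pass/fail verdict.
#'
#' @param fit A `"recruit_fit"` object.
#' @return A list with `cor_resid_x`, `cor_absresid_x`, `sign_runs`,
#'   `n`, `available` (FALSE with NAs when `n < 5`).
#' @export
residual_trend <- function(fit) {
  if (!inherits(fit, "recruit_fit"))
    stop("'fit' must be a recruit_fit object")
  residual_trend_core(fit$residuals, fit$design$X)
}

residual_trend_core <- function(res, X) {
  n <- length(res)
  if (n < 5L)
    return(list(cor_resid_x = NA_real_, cor_absresid_x = NA_real_,
                sign_runs = NA_integer_, n = n, available = FALSE))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b, method = "spearman")
  }
  cr <- safe_cor(res, X)
  ca <- safe_cor(abs(res), X)
  sg <- sign(res[order(X)])
  sg <- sg[sg != 0]
  runs <- if (length(sg)) 1L + sum(diff(sg) != 0) else 0L
  list(cor_resid_x = cr, cor_absresid_x = ca, sign_runs = runs,
       n = n, available = TRUE)
}

#' Gaussian-OLS Akaike information criterion
#'
#' `AIC = n * ln(RSS / n) + 2k`, with `k` counting the regression
#' coefficients plus one for the error variance.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param n_coef Number of regression coefficients (k = `n_coef + 1`).
#' @return The AIC value.
#' @examples
#' gaussian_aic(rss = 10, n = 10, n_coef = 1)  # 10*log(1) + 4
#' @export
gaussian_aic <- function(rss, n, n_coef) {
  stopifnot(rss >= 0, n > 0, n_coef >= 0)
  k <- n_coef + 1
  n * log(rss / n) + 2 * k
}

#' Fit the extended temporal-variation model
#'
#' The extended model generalises the logistic operculum-cover fit in two
#' optional directions: the resource-independent survival `alpha` may
#' vary among census periods (one transformed-scale intercept per
#' period), and the cover of dead shells may enter as an additional
#' mortality term alongside live cover:
#' `ln(1/S_30 - 1) = ln(alpha'_period) + beta_live * (O * N) +
#' beta_dead * D`.
#' With both switches off the model reduces exactly to
#' `fit_form(form = "logistic", descriptor = "operc_cover")`.
#'
#' Fits are per shore; supplying observations from more than one shore is
#' an error (use [select_extended()] or split first).
#'
#' @inheritParams build_design
#' @param alpha_by_period Logical: one `alpha` per census period?
#' @param include_dead_cover Logical: include the dead-shell cover term?
#' @return A `"recruit_fit"` object; `alpha` is a named vector (one entry
#'   per period) when `alpha_by_period`, and `beta` holds `beta_live`
#'   (and `beta_dead` when included).
#' @examples
#' obs <- simulate_dataset(study_design(n_shores = 1), truth_params(),
#'                         seed = 1)
#' fit_extended(obs, alpha_by_period = TRUE, include_dead_cover = TRUE)
#' @export
fit_extended <- function(observations, alpha_by_period = TRUE,
                         include_dead_cover = TRUE, base = 30) {
  stopifnot(is.logical(alpha_by_period), is.logical(include_dead_cover))
  obs <- check_observations(observations)
  if (length(unique(obs$shore)) > 1L)
    stop("fit_extended() fits one shore at a time; got shores: ",
         paste(unique(obs$shore), collapse = ", "))
  d <- build_design(obs, "operc_cover", "logistic", base)
  d$period <- factor(d$period, levels = unique(d$period))
  if (alpha_by_period) {
    cnt <- table(d$period)
    low <- names(cnt)[cnt < 3]
    if (length(cnt) < 2L)
      stop("alpha_by_period requires >= 2 census periods")
    if (length(low))
      stop("period(s) with < 3 observations: ", paste(low, collapse = ", "))
  }
  fml <- if (alpha_by_period) {
    if (include_dead_cover) y ~ 0 + period + X + dead_cover
    else y ~ 0 + period + X
  } else {
    if (include_dead_cover) y ~ X + dead_cover else y ~ X
  }
  fit <- stats::lm(fml, data = d)
  co <- stats::coef(fit)
  if (alpha_by_period) {
    ic <- co[grepl("^period", names(co))]
    alpha <- 1 / (1 + exp(unname(ic)))
    names(alpha) <- sub("^period", "", names(ic))
  } else {
    alpha <- 1 / (1 + exp(unname(co["(Intercept)"])))
  }
  beta <- c(beta_live = unname(co["X"]))
  if (include_dead_cover) beta <- c(beta, beta_dead = unname(co["dead_cover"]))
  admissible <- all(is.finite(alpha)) && all(alpha > 0) && all(alpha <= 1) &&
    all(is.finite(beta)) && all(beta >= 0)
  note <- if (admissible) "" else "alpha outside (0,1] or negative beta"
  finish_fit(fit, d, form = "logistic", descriptor = "operc_cover",
             base = base, alpha = alpha, beta = beta,
             admissible = admissible, note = note,
             spec = list(alpha_by_period = alpha_by_period,
                         include_dead_cover = include_dead_cover))
}

#' Select among extended-model candidates by AIC
#'
#' Fits the four-candidate set crossing period-varying `alpha` with the
#' dead-cover term on one shore's observations, and selects the candidate
#' with the lowest Gaussian-OLS AIC; ties are broken towards fewer
#' parameters. All candidates are fitted to the identical observation
#' set.
#'
#' @inheritParams build_design
#' @return A list of class `"aic_selection"`: `table` (data.frame of
#'   candidate specs, k, AIC, delta-AIC), `fits` (the four
#'   `"recruit_fit"` objects), `best` (the winning fit), `best_spec`.
#' @export
select_extended <- function(observations, base = 30) {
  cand <- expand.grid(alpha_by_period = c(FALSE, TRUE),
                      include_dead_cover = c(FALSE, TRUE))
  fits <- lapply(seq_len(nrow(cand)), function(i)
    fit_extended(observations, cand$alpha_by_period[i],
                 cand$include_dead_cover[i], base = base))
  select_by_aic(fits)
}

#' Pick the best fit from a candidate list by AIC
#'
#' @param fits A list of `"recruit_fit"` objects fitted to the identical
#'   observation set (checked: same n and same response values).
#' @return A list of class `"aic_selection"`; see [select_extended()].
#' @export
select_by_aic <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (!all(vapply(fits, inherits, TRUE, "recruit_fit")))
    stop("'fits' must be recruit_fit objects")
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) != 1L)
    stop("candidates fitted on different data (n differs)")
  y0 <- fits[[1]]$design$y
  same <- vapply(fits, function(f) isTRUE(all.equal(f$design$y, y0)), TRUE)
  if (!all(same))
    stop("candidates fitted on different data (responses differ)")
  k <- vapply(fits, function(f) f$k, 0)
  aic <- vapply(fits, function(f) f$aic, 0)
  ord <- order(aic, k)  # ties -> fewer parameters
  best <- fits[[ord[1]]]
  tab <- data.frame(
    alpha_by_period = vapply(fits, function(f) isTRUE(f$spec$alpha_by_period),
                             TRUE),
    include_dead_cover = vapply(fits,
                                function(f) isTRUE(f$spec$include_dead_cover),
                                TRUE),
    k = k, aic = aic, delta_aic = aic - min(aic))
  tab <- tab[order(tab$aic, tab$k), ]
  structure(list(table = tab, fits = fits, best = best,
                 best_spec = best$spec),
            class = "aic_selection")
}

#' @export
print.aic_selection <- function(x, ...) {
  cat("AIC model selection (", nrow(x$table), " candidates)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  cat("Best: alpha_by_period = ", x$best_spec$alpha_by_period,
      ", include_dead_cover = ", x$best_spec$include_dead_cover, "\n",
      sep = "")
  invisible(x)
}

#' Adjusted R-squared table across forms and descriptors
#'
#' Fits every functional form crossed with every body-size descriptor,
#' separately per shore, and tabulates the transformed-scale adjusted
#' R-squared — the layout used to compare whether body-size traits
#' improve on density alone and which form fits best.
#'
#' @inheritParams build_design
#' @param forms,descriptors Character vectors of forms / descriptors to
#'   cross (defaults: all three of each).
#' @return A data.frame with columns `shore`, `descriptor`, one column
#'   per form (adjusted R-squared), plus an attribute `"fits"` holding
#'   the underlying `"recruit_fit"` objects keyed
#'   `shore|form|descriptor`.
#' @export
fit_all_forms <- function(observations,
                          forms = c("exponential", "logistic", "hyperbolic"),
                          descriptors = c("density", "basal_cover",
                                          "operc_cover"),
                          base = 30) {
  obs <- check_observations(observations)
  shores <- unique(obs$shore)
  rows <- list()
  fits <- list()
  for (sh in shores) {
    sub <- obs[obs$shore == sh, , drop = FALSE]
    for (de in descriptors) {
      r2 <- vapply(forms, function(fo) {
        f <- fit_form(sub, fo, de, base = base)
        fits[[paste(sh, fo, de, sep = "|")]] <<- f
        f$adj_r2
      }, 0)
      rows[[length(rows) + 1L]] <-
        data.frame(shore = sh, descriptor = de, t(r2))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:2)] <- forms
  attr(out, "fits") <- fits
  out
}
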