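#' Quadrat-census study design
#'
#' Describes the sampling design a synthetic dataset should emulate: how
#' many shores, how many quadrats per shore, the quadrat area, and the
#' census schedule (ordered period labels with interval lengths in days).
#' Defaults mirror a spring-settling intertidal barnacle cohort followed
#' photographically over its first year: 2 shores, 52 quadrats of
#' 5 x 5 cm (2500 mm^2) per shore, censused June, July, October and
#' February (intervals of 30, 90 and 120 days).
#'
#' @param n_shores Number of shores (default 2).
#' @param n_quadrats Quadrats per shore (default 52).
#' @param quadrat_area Quadrat area in mm^2 (default 2500).
#' @param schedule data.frame with columns `period` (label) and `T_days`
#'   (interval length, > 0); at least one interval (two censuses).
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(n_shores = 2, n_quadrats = 52,
                         quadrat_area = 2500,
                         schedule = data.frame(
                           period = c("June-July", "July-October",
                                      "October-February"),
                           T_days = c(30, 90, 120))) {
  stopifnot(n_shores >= 1, n_quadrats >= 1, quadrat_area > 0,
            is.data.frame(schedule),
            all(c("period", "T_days") %in% names(schedule)))
  if (nrow(schedule) < 1L || any(schedule$T_days <= 0))
    stop("'schedule' needs >= 1 interval with positive T_days")
  structure(list(n_shores = as.integer(n_shores),
                 n_quadrats = as.integer(n_quadrats),
                 quadrat_area = quadrat_area,
                 schedule = schedule),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design: ", x$n_shores, " shore(s) x ", x$n_quadrats,
      " quadrats of ", format(x$quadrat_area), " mm^2\n", sep = "")
  cat("  census intervals: ",
      paste(x$schedule$period, " (", x$schedule$T_days, " d)",
            sep = "", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ground-truth parameters for the synthetic generator
#'
#' The latent model behind a synthetic quadrat census. Per-30-day
#' survival follows the chosen functional form driven by total mortality
#' pressure `u = beta_live * X + beta_dead * D`, where `X` is the
#' resource-use predictor of the chosen descriptor at the interval start
#' and `D` is accumulated dead-shell cover; `alpha` may differ by census
#' period. The operculum trait grows by Ford-Walford (density-
#' independent); mean basal area responds plastically to density as
#' `B_max / (1 + c * N)`. Settlement densities are log-uniform. Dead
#' cover accumulates as `persistence * deaths * basal_area` per interval.
#' Reported traits carry lognormal measurement jitter around the latent
#' values.
#'
#' Default magnitudes: `alpha` of 0.97 for the first interval and 0.92
#' thereafter, `beta_live = 0.04` and `beta_dead = 0.036` per mm^2 of
#' cover — survival-and-cover magnitudes typical of a dense spring
#' barnacle cohort on a 25 cm^2 quadrat.
#'
#' @param form Survival functional form (default `"logistic"`).
#' @param descriptor Resource-use descriptor driving survival (default
#'   `"operc_cover"`).
#' @param alpha Per-period resource-independent survival (recycled to the
#'   number of intervals in the design).
#' @param beta_live Mortality per unit live cover (mm^-2).
#' @param beta_dead Mortality per unit dead-shell cover (mm^-2); 0
#'   disables the dead-cover pathway.
#' @param growth [growth_params()] for the operculum trait per 30-day
#'   step (mm^2).
#' @param B_max Mean basal area at zero density (mm^2).
#' @param basal_c Plasticity coefficient of basal area (per individual).
#' @param settle_min,settle_max Log-uniform settlement range
#'   (individuals per quadrat).
#' @param persistence Fraction of each interval's dead-shell area that
#'   persists as cover, in `[0, 1]`.
#' @param trait_sdlog Lognormal sdlog of trait measurement jitter (0
#'   disables).
#' @param mode `"binomial"` (integer individuals, binomial survival
#'   noise) or `"deterministic"` (continuous densities, no survival
#'   noise).
#' @return An object of class `"truth_params"`.
#' @export
truth_params <- function(form = c("logistic", "exponential", "hyperbolic"),
                         descriptor = c("operc_cover", "density",
                                        "basal_cover"),
                         alpha = c(0.97, 0.92, 0.92),
                         beta_live = 0.04,
                         beta_dead = 0.036,
                         growth = growth_params(K = 0.06, phi_inf = 1.2,
                                                phi_0 = 0.2),
                         B_max = 4, basal_c = 0.02,
                         settle_min = 180, settle_max = 400,
                         persistence = 0.1,
                         trait_sdlog = 0.05,
                         mode = c("binomial", "deterministic")) {
  form <- match.arg(form)
  descriptor <- match.arg(descriptor)
  mode <- match.arg(mode)
  stopifnot(all(alpha > 0), all(alpha <= 1), beta_live >= 0, beta_dead >= 0,
            inherits(growth, "growth_params"), B_max > 0, basal_c >= 0,
            settle_min > 0, settle_max >= settle_min,
            persistence >= 0, persistence <= 1, trait_sdlog >= 0)
  structure(list(form = form, descriptor = descriptor, alpha = alpha,
                 beta_live = beta_live, beta_dead = beta_dead,
                 growth = growth, B_max = B_max, basal_c = basal_c,
                 settle_min = settle_min, settle_max = settle_max,
                 persistence = persistence, trait_sdlog = trait_sdlog,
                 mode = mode),
            class = "truth_params")
}

#' @export
print.truth_params <- function(x, ...) {
  cat("Synthetic-generator truth (", x$form, " form, descriptor ",
      x$descriptor, ", ", x$mode, " mode)\n", sep = "")
  cat("  alpha by period: ", paste(format(x$alpha), collapse = ", "),
      "\n  beta_live = ", format(x$beta_live),
      ", beta_dead = ", format(x$beta_dead), "\n", sep = "")
  invisible(x)
}

#' Log-uniform settlement densities
#'
#' Draws independent log-uniform settlement densities on
#' `[settle_min, settle_max]` (median `sqrt(min * max)`), emulating an
#' experimental manipulation of settler density spanning orders of
#' magnitude.
#'
#' @param n Number of quadrats.
#' @param settle_min,settle_max Range endpoints, `0 < min <= max`.
#' @return Numeric vector of length `n` within the range.
#' @export
sample_settlement <- function(n, settle_min, settle_max) {
  stopifnot(n >= 0)
  if (!(settle_min > 0) || settle_max < settle_min)
    stop("need 0 < settle_min <= settle_max")
  exp(stats::runif(n, log(settle_min), log(settle_max)))
}

#' Density-plastic mean basal area
#'
#' `B(N) = B_max / (1 + c * N)`: mean basal area per individual shrinks
#' with crowding, equalling `B_max` in an empty quadrat. This is the
#' generator's stand-in for the plastic reduction of basal area at high
#' density; the operculum trait, by contrast, grows independently of
#' density.
#'
#' @param N Density (individuals per quadrat), >= 0. Vectorised.
#' @param B_max Basal area at zero density (mm^2).
#' @param c Plasticity coefficient (per individual), >= 0.
#' @return Mean basal area(s) in mm^2.
#' @examples
#' plastic_basal_area(10, B_max = 10, c = 0.1)  # 5
#' @export
plastic_basal_area <- function(N, B_max, c) {
  stopifnot(B_max > 0, c >= 0)
  if (any(N < 0)) stop("'N' must be >= 0")
  B_max / (1 + c * N)
}

# survival at given alpha for the truth's form, with unit beta and
# resource-use u already including all mortality terms
form_survival <- function(form, alpha, u) {
  switch(form,
    exponential = alpha * exp(-u),
    logistic = 1 / (1 + (1 / alpha - 1) * exp(u)),
    hyperbolic = alpha / (1 + u))
}

#' Simulate a study-shaped synthetic quadrat census
#'
#' Generates a complete synthetic dataset under a known ground truth:
#' settlement densities are drawn log-uniform per quadrat, each cohort is
#' thinned interval by interval with per-30-day survival from the truth's
#' functional form (rescaled to the interval length, survivors binomial
#' in `"binomial"` mode), the operculum trait grows by Ford-Walford,
#' basal area responds plastically to density, and dead-shell cover
#' accumulates from each interval's deaths. One deterministic RNG
#' substream per quadrat (derived from `seed`) guarantees that adding
#' quadrats or shores never perturbs existing ones.
#'
#' @param design A [study_design()] object.
#' @param truth A [truth_params()] object.
#' @param seed Integer seed governing all stochastic layers.
#' @return A data.frame in the census schema (`shore`, `quadrat`,
#'   `period`, `T_days`, `N_start`, `N_end`, `operc_area`, `basal_area`,
#'   `dead_cover`), one row per quadrat and interval, with attribute
#'   `"truth_log"`: a data.frame of the latent per-row state
#'   (`lambda_30`, `lambda_T`, true traits, deaths).
#' @examples
#' obs <- simulate_dataset(study_design(n_shores = 1, n_quadrats = 5),
#'                         truth_params(), seed = 1)
#' head(obs)
#' @export
simulate_dataset <- function(design, truth, seed) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_params"),
            is.numeric(seed), length(seed) == 1L)
  sched <- design$schedule
  n_int <- nrow(sched)
  alpha <- rep_len(truth$alpha, n_int)
  g <- truth$growth
  if (!is.null(.GlobalEnv$.Random.seed)) {
    old <- .GlobalEnv$.Random.seed
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  rows <- vector("list", design$n_shores * design$n_quadrats)
  logs <- vector("list", length(rows))
  idx <- 0L
  for (sh in seq_len(design$n_shores)) {
    for (q in seq_len(design$n_quadrats)) {
      idx <- idx + 1L
      # deterministic per-quadrat substream, independent of total counts
      sub <- (abs(seed) * 1009 + sh * 524287 + q * 48271) %% 2147483629
      set.seed(as.integer(sub))
      N <- sample_settlement(1, truth$settle_min, truth$settle_max)
      if (truth$mode == "binomial") N <- max(1, round(N))
      O <- g$phi_0  # latent operculum area at first census
      D <- 0        # accumulated dead-shell cover
      rec <- log_rec <- vector("list", n_int)
      for (i in seq_len(n_int)) {
        Td <- sched$T_days[i]
        B <- plastic_basal_area(N, truth$B_max, truth$basal_c)
        X <- switch(truth$descriptor,
          density = N, operc_cover = O * N, basal_cover = B * N)
        u <- truth$beta_live * X + truth$beta_dead * D
        l30 <- form_survival(truth$form, alpha[i], u)
        lT <- l30^(Td / 30)
        N_end <- if (truth$mode == "binomial" && N > 0) {
          stats::rbinom(1, N, lT)
        } else N * lT
        deaths <- N - N_end
        jit <- function(v) if (truth$trait_sdlog > 0)
          v * stats::rlnorm(1, -truth$trait_sdlog^2 / 2, truth$trait_sdlog)
          else v
        rec[[i]] <- data.frame(
          shore = paste0("shore", sh), quadrat = paste0("q", q),
          period = sched$period[i], T_days = Td,
          N_start = N, N_end = N_end,
          operc_area = jit(O), basal_area = jit(B), dead_cover = D,
          stringsAsFactors = FALSE)
        log_rec[[i]] <- data.frame(
          shore = paste0("shore", sh), quadrat = paste0("q", q),
          period = sched$period[i],
          lambda_30 = l30, lambda_T = lT, u = u,
          operc_true = O, basal_true = B, deaths = deaths,
          stringsAsFactors = FALSE)
        D <- D + truth$persistence * deaths * B
        O <- grow_step(O, g, delta = Td / 30)
        N <- N_end
      }
      rows[[idx]] <- do.call(rbind, rec)
      logs[[idx]] <- do.call(rbind, log_rec)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  truth_log <- do.call(rbind, logs)
  rownames(truth_log) <- NULL
  attr(out, "truth_log") <- truth_log
  out
}
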