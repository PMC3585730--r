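#' Settler-recruit map of the cohort model
#'
#' Builds the map `N_t = f(N_0)` of the recruitment function: for each
#' initial density in `N0_grid` the cohort recursion is iterated with the
#' given survival form and growth parameters, and the density is recorded
#' at the requested time steps. Plotting a column of the result against
#' `N0_grid` gives the settler-recruit curve at that step; its shape
#' (monotonic, unimodal, multimodal) diagnoses the strength and timing of
#' density-dependent mortality.
#'
#' @param sp A [survival_params()] object.
#' @param g A [growth_params()] object; the initial body size is
#'   `g$phi_0`.
#' @param N0_grid Strictly increasing vector of positive initial
#'   densities. The default is 400 log-spaced points on `[1, 1e4]`.
#' @param steps Integer vector of time steps at which to record density
#'   (default `0:500`; growth with small `K` saturates on a `~1/K` step
#'   scale, so 500 steps cover the full growth trajectory at `K = 0.01`).
#' @return An object of class `"recruitment_map"`: a list with `N0_grid`,
#'   `steps`, and a `values` matrix (`length(N0_grid)` rows, one column
#'   per step). Column `t = 0` equals `N0_grid` exactly.
#' @examples
#' sp <- survival_params("hyperbolic", 0.99, 0.1)
#' g <- growth_params(0.01, 1, 0.1)
#' m <- recruitment_map(sp, g, N0_grid = c(1, 10, 100), steps = c(0, 5))
#' m$values
#' @export
recruitment_map <- function(sp, g,
                            N0_grid = default_n0_grid(),
                            steps = 0:500) {
  if (!inherits(sp, "survival_params") || !inherits(g, "growth_params"))
    stop("'sp' and 'g' must be survival_params / growth_params objects")
  if (!is.numeric(N0_grid) || length(N0_grid) < 1L || any(N0_grid <= 0))
    stop("'N0_grid' must be positive")
  if (is.unsorted(N0_grid, strictly = TRUE))
    stop("'N0_grid' must be strictly increasing")
  steps <- as.integer(steps)
  if (length(steps) < 1L || any(steps < 0))
    stop("'steps' must be nonnegative integers")
  t_max <- max(steps)
  vals <- matrix(NA_real_, nrow = length(N0_grid), ncol = length(steps),
                 dimnames = list(NULL, paste0("t", steps)))
  N <- N0_grid
  phi <- g$phi_0
  if (0L %in% steps) vals[, match(0L, steps)] <- N
  if (t_max > 0) {
    for (t in seq_len(t_max)) {
      N <- N * survival_fraction(sp, N * phi)
      phi <- grow_step(phi, g)
      if (t %in% steps) vals[, match(t, steps)] <- N
    }
  }
  structure(list(N0_grid = N0_grid, steps = steps, values = vals,
                 sp = sp, g = g),
            class = "recruitment_map")
}

#' Default initial-density grid for recruitment maps
#'
#' 400 log-spaced points on `[1, 1e4]`. With a small initial body size
#' (e.g. `phi_0 = 0.01`) density dependence only engages at large `N0`,
#' so the grid spans four orders of magnitude.
#'
#' @param n Number of grid points.
#' @param from,to Range endpoints (positive).
#' @return Numeric vector of length `n`.
#' @export
default_n0_grid <- function(n = 400, from = 1, to = 1e4) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

#' @export
print.recruitment_map <- function(x, ...) {
  cat("Settler-recruit map (", x$sp$form, " form)\n", sep = "")
  cat("  N0 grid: ", length(x$N0_grid), " points on [",
      format(min(x$N0_grid)), ", ", format(max(x$N0_grid)), "]\n", sep = "")
  cat("  steps recorded: ", length(x$steps), " (t = ", min(x$steps), "..",
      max(x$steps), ")\n", sep = "")
  invisible(x)
}

#' Convert a recruitment map to a long data.frame
#'
#' @param x A `"recruitment_map"` object.
#' @param row.names,optional Unused, for S3 compatibility.
#' @param ... Unused.
#' @return A data.frame with columns `N0`, `t`, `N`.
#' @export
as.data.frame.recruitment_map <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(N0 = rep(x$N0_grid, times = length(x$steps)),
             t = rep(x$steps, each = length(x$N0_grid)),
             N = as.vector(x$values))
}

#' Count interior local maxima of a curve
#'
#' Counts strict interior local maxima (points of compensation of a
#' settler-recruit curve) after merging plateaus: consecutive values whose
#' difference is within `tol` times the curve's maximum absolute value are
#' collapsed into one point, so a flat-topped peak counts once.
#'
#' @param curve Numeric vector, length >= 3.
#' @param tol Relative tolerance for plateau merging (default `1e-9`).
#' @return Integer count of interior local maxima.
#' @examples
#' count_local_maxima(c(1, 2, 1, 2, 1))  # 2
#' count_local_maxima(c(1, 2, 3, 4))     # 0
#' @export
count_local_maxima <- function(curve, tol = 1e-9) {
  if (!is.numeric(curve) || any(!is.finite(curve)))
    stop("'curve' must be finite numeric")
  if (length(curve) < 3L)
    stop("'curve' must have length >= 3 (got ", length(curve), ")")
  stopifnot(is.numeric(tol), tol >= 0)
  th <- tol * max(abs(curve))
  # collapse runs of values equal within th into single representatives
  grp <- cumsum(c(TRUE, abs(diff(curve)) > th))
  v <- as.numeric(tapply(curve, grp, mean))
  m <- length(v)
  if (m < 3L) return(0L)
  mid <- v[2:(m - 1L)]
  sum(mid > v[1:(m - 2L)] & mid > v[3:m])
}

#' Classify the shape of a settler-recruit curve
#'
#' Classifies a curve as `monotonic_increasing` (no interior maxima and
#' nondecreasing within tolerance), `unimodal` (exactly one interior
#' maximum), or `multimodal` (two or more interior maxima —
#' overcompensation with multiple points of compensation). A curve with no
#' interior maxima that is not nondecreasing (e.g. strictly decreasing)
#' returns `"other"`.
#'
#' @inheritParams count_local_maxima
#' @return A character scalar: one of `"monotonic_increasing"`,
#'   `"unimodal"`, `"multimodal"`, `"other"`.
#' @examples
#' classify_map_shape(c(1, 2, 3))      # monotonic_increasing
#' classify_map_shape(c(1, 3, 2))      # unimodal
#' classify_map_shape(c(1, 3, 2, 4, 1))  # multimodal
#' @export
classify_map_shape <- function(curve, tol = 1e-9) {
  k <- count_local_maxima(curve, tol)
  if (k >= 2L) return("multimodal")
  if (k == 1L) return("unimodal")
  th <- tol * max(abs(curve))
  if (all(diff(curve) >= -th)) "monotonic_increasing" else "other"
}

#' Shape class of each recorded step of a recruitment map
#'
#' Applies [classify_map_shape()] to every column of a recruitment map.
#'
#' @param map A `"recruitment_map"` object.
#' @param tol Relative tolerance, see [count_local_maxima()].
#' @return Named character vector, one class per recorded step.
#' @export
map_shape_by_step <- function(map, tol = 1e-9) {
  if (!inherits(map, "recruitment_map"))
    stop("'map' must be a recruitment_map object")
  out <- apply(map$values, 2, classify_map_shape, tol = tol)
  names(out) <- paste0("t", map$steps)
  out
}
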