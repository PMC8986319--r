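#' LOESS smoothing (tricube local polynomial regression)
#'
#' Local polynomial regression with tricube weights over the
#' span-fraction nearest neighbours of each grid point, computed by
#' explicit per-point weighted least squares. Degree 1 (local linear) is
#' the default; degree 2 (local quadratic, the classic R default for
#' figure smoothers) follows curvature better and is what the landmark
#' pipeline uses. Optional observation weights multiply the tricube
#' kernel weights — useful when each point is a mean over a shrinking
#' number of queens.
#'
#' @param x numeric grid (e.g. ages); need not be sorted.
#' @param y response values, same length.
#' @param span fraction of points in each local neighbourhood, in (0, 1].
#' @param degree local polynomial degree, 1 or 2.
#' @param weights optional non-negative observation weights.
#' @return A tibble of class `cp_smooth` with columns `age` and `fitted`,
#'   in increasing `age` order; `span` and `degree` kept as attributes.
#' @export
#' @examples
#' sm <- loess_smooth(0:20, (0:20)^2 / 40 + rnorm(21, 0, 0.2))
#' find_peak_age(sm)
loess_smooth <- function(x, y, span = 0.75, degree = 1, weights = NULL) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "cp_validation_error")
  }
  n <- length(x)
  if (n < 3) abort("Need at least 3 points", class = "cp_validation_error")
  if (span <= 0 || span > 1) {
    abort("span must lie in (0, 1]", class = "cp_validation_error")
  }
  q <- max(degree + 1, floor(span * n))
  if (q < 2) abort("span * n too small for a local fit",
                   class = "cp_validation_error")
  if (is.null(weights)) weights <- rep(1, n)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; weights <- weights[ord]
  fitted <- vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d, partial = q)[q]
    w <- if (h > 0) {
      tri <- pmax(0, 1 - (d / h)^3)^3
      tri * weights
    } else {
      as.numeric(d == 0) * weights
    }
    use <- w > 0
    if (sum(use) <= degree || length(unique(x[use])) <= degree) {
      # degenerate neighbourhood: weighted mean
      return(sum(w * y) / sum(w))
    }
    xc <- x[use] - x[i]
    X <- if (degree == 1) cbind(1, xc) else cbind(1, xc, xc^2)
    wf <- w[use]
    XtWX <- crossprod(X, X * wf)
    XtWy <- crossprod(X, y[use] * wf)
    beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(beta)) return(sum(w * y) / sum(w))
    beta[1]
  }, numeric(1))
  out <- tibble(age = x, fitted = fitted)
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  class(out) <- unique(c("cp_smooth", class(out)))
  out
}

as_curve <- function(curve) {
  if (inherits(curve, "cp_smooth")) {
    tibble(age = curve$age, value = curve$fitted)
  } else if (inherits(curve, "cp_trajectory")) {
    tibble(age = curve$age_week, value = curve$relative_value)
  } else if (is.data.frame(curve) && all(c("age", "fitted") %in% names(curve))) {
    tibble(age = curve$age, value = curve$fitted)
  } else {
    abort("Expected a cp_smooth, cp_trajectory, or age/fitted data frame",
          class = "cp_validation_error")
  }
}

#' Age of the global maximum of a smoothed curve
#'
#' Ties are resolved to the earliest age.
#'
#' @param curve a [loess_smooth()] result, a trajectory, or a data frame
#'   with `age` and `fitted` columns.
#' @return The age of the maximum.
#' @export
find_peak_age <- function(curve) {
  cv <- as_curve(curve)
  if (nrow(cv) == 0) abort("Empty curve", class = "cp_validation_error")
  cv$age[which.max(cv$value)]
}

#' Age at which relative mortality rises above a level and stays there
#'
#' First age at which the (smoothed) relative mortality exceeds `level`
#' and remains above it for at least `persistence` consecutive ages — the
#' point where mortality passes its post-maturation average for good.
#' Returns `NA` if the curve never sustains the level (e.g. always below
#' average, or only the final age exceeds it).
#'
#' @param curve smoothed relative-mortality curve (see [find_peak_age]
#'   for accepted types).
#' @param level threshold, 1 by default (the post-maturation mean).
#' @param persistence required consecutive ages above the level.
#' @return Age of the sustained crossing, or `NA`.
#' @export
mortality_crossing_age <- function(curve, level = 1, persistence = 2L) {
  cv <- as_curve(curve)
  above <- cv$value > level
  n <- nrow(cv)
  if (n == 0) abort("Empty curve", class = "cp_validation_error")
  for (i in seq_len(n - persistence + 1L)) {
    if (all(above[i:(i + persistence - 1L)])) return(cv$age[i])
  }
  NA_real_
}

#' Cohort demographic landmarks
#'
#' Runs the full landmark pipeline on a census table: life table,
#' egg and sexual-pupae schedules, mean-standardization, smoothing
#' (span-`span` local-quadratic LOESS weighted by the number of queens
#' contributing at each age), and landmark extraction.
#'
#' @param table a census tibble.
#' @param span LOESS span.
#' @param trim survivorship trim fraction passed to [mean_standardize()].
#' @param maturation_override optional explicit maturation age.
#' @return One-row tibble: `mean_lifespan`, `lifespan_cv` (as a
#'   fraction), `egg_peak`, `sexual_peak`, `mortality_crossing`.
#' @export
#' @examples
#' cohort_landmarks(simulate_cohort(seed = 1)$census)
cohort_landmarks <- function(table, span = 0.75, trim = 0,
                             maturation_override = NULL) {
  ls <- lifespans(table)
  lt <- build_life_table(ls)
  eggs <- fecundity_schedule(table, "eggs")
  sexual <- fecundity_schedule(table, "sexual_pupae")
  mat <- maturation_age(eggs, override = maturation_override)

  smooth_traj <- function(traj) {
    loess_smooth(traj$age_week, traj$relative_value,
                 span = span, degree = 2, weights = traj$weight)
  }
  egg_traj <- mean_standardize(eggs, maturation_age = mat, trim = trim,
                               life_table = lt)
  sex_traj <- mean_standardize(sexual, maturation_age = mat, trim = trim,
                               life_table = lt)
  mort_traj <- mean_standardize(lt, maturation_age = mat, trim = trim)
  obs <- ls$death_week[ls$observed]
  tibble(
    mean_lifespan = mean(obs),
    lifespan_cv = sd(obs) / mean(obs),
    egg_peak = find_peak_age(smooth_traj(egg_traj)),
    sexual_peak = find_peak_age(smooth_traj(sex_traj)),
    mortality_crossing = mortality_crossing_age(smooth_traj(mort_traj))
  )
}
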