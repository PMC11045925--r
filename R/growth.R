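# Growth-phenotype analysis: maximum specific growth rate and maximum OD from
# plate-style growth curves, LC50 from a dose series, and mutant-vs-reference
# strain comparisons.

# Rolling least-squares of ln(od) on time over windows of `window` consecutive
# points, restricted to windows whose ODs all exceed `od_floor`. Vectorized
# with cumulative sums; returns one row per valid window.
.rolling_log_slopes <- function(times_h, od, window, od_floor) {
  n <- length(times_h)
  if (n < window) return(NULL)
  ok <- od > od_floor
  roll <- function(x) {
    cs <- cumsum(x)
    cs[window:n] - c(0, cs[seq_len(n - window)])
  }
  valid <- roll(as.numeric(ok)) == window
  if (!any(valid)) return(NULL)
  y <- ifelse(ok, log(pmax(od, .Machine$double.xmin)), 0)
  t_ok <- ifelse(ok, times_h, 0)
  S1 <- roll(t_ok)
  S2 <- roll(t_ok^2)
  Sy <- roll(y)
  Syy <- roll(y^2)
  Sty <- roll(t_ok * y)
  Sod <- roll(ifelse(ok, od, 0))
  w <- window
  sxx <- w * S2 - S1^2
  sxy <- w * Sty - S1 * Sy
  syy <- w * Syy - Sy^2
  slope <- sxy / sxx
  r2 <- ifelse(syy > 0, pmin(sxy^2 / (sxx * syy), 1), 1)
  tibble::tibble(
    start_idx = which(valid),
    start_h = times_h[which(valid)],
    slope = slope[valid],
    r2 = r2[valid],
    mean_od = (Sod / w)[valid]
  )
}

#' Growth metrics from a single growth curve
#'
#' `max_od` is the maximum of a 3-point median-smoothed curve (robust to
#' single-point spikes). `mu_max` is built from sliding-window log-linear
#' fits of `ln(OD)` versus time (default window of 5 points, about 100 min at
#' 20-min sampling) over windows whose ODs all exceed `od_floor`: because a
#' logistic curve satisfies `d ln OD/dt = mu (1 - OD/K)`, the window slopes
#' are regressed on the window-mean OD (weighted by OD^2, the inverse
#' variance of log-scale noise) and `mu_max` is the intercept at OD = 0.
#' This extrapolation is exact on noiseless exponential and logistic input
#' and, unlike taking the raw maximum window slope, is not inflated by noisy
#' low-OD windows. When the valid windows span too narrow an OD range for the
#' regression, the maximum window slope is used directly.
#'
#' @param times_h Strictly increasing time points (hours), >= 10.
#' @param od Non-negative ODs, same length as `times_h`.
#' @param window Points per sliding window (>= 3); default 5.
#' @param od_floor Windows containing any OD at or below this floor are
#'   excluded from the slope fits; default 0.01. For noisy data raise it to a
#'   few times the OD noise level.
#' @return One-row tibble: `mu_max` (per hour, clamped at 0), `max_od`,
#'   `window_start_h` and `r2_window` (of the max-slope window), `n_windows`,
#'   `evaluable`.
#' @export
#' @examples
#' t <- seq(0, 20, by = 1 / 3)
#' fit_growth_metrics(t, 0.05 * exp(0.3 * t))
fit_growth_metrics <- function(times_h, od, window = 5, od_floor = 0.01) {
  if (length(times_h) != length(od)) {
    stop("times_h and od must have the same length", call. = FALSE)
  }
  if (length(times_h) < 10 || any(diff(times_h) <= 0)) {
    stop("need >= 10 strictly increasing time points", call. = FALSE)
  }
  if (any(!is.finite(od)) || any(od < 0)) {
    stop("od must be finite and >= 0", call. = FALSE)
  }
  .assert_scalar_number(window, "window", lower = 3)
  .assert_scalar_number(od_floor, "od_floor", lower = 0)
  max_od <- max(stats::runmed(od, 3))
  wins <- .rolling_log_slopes(times_h, od, as.integer(window), od_floor)
  if (is.null(wins) || nrow(wins) == 0) {
    return(tibble::tibble(mu_max = NA_real_, max_od = max_od,
                          window_start_h = NA_real_, r2_window = NA_real_,
                          n_windows = 0L, evaluable = FALSE))
  }
  best <- which.max(wins$slope)
  x <- wins$mean_od
  y <- wins$slope
  wt <- x^2
  xbar <- sum(wt * x) / sum(wt)
  sxx <- sum(wt * (x - xbar)^2)
  # need a real OD spread to extrapolate; otherwise report the max slope
  if (nrow(wins) >= 3 && sxx > 1e-6 * max(x)^2 * sum(wt)) {
    ybar <- sum(wt * y) / sum(wt)
    b <- sum(wt * (x - xbar) * (y - ybar)) / sxx
    mu_hat <- ybar - b * xbar
  } else {
    mu_hat <- max(y)
  }
  tibble::tibble(
    mu_max = max(mu_hat, 0),
    max_od = max_od,
    window_start_h = wins$start_h[best],
    r2_window = wins$r2[best],
    n_windows = nrow(wins),
    evaluable = TRUE
  )
}

#' Growth metrics for every curve in a tidy table
#'
#' @param curves Tidy tibble with `strain`, `condition`, `conc_mM`,
#'   `replicate`, `time_h`, `od` (the [simulate_growth_curves()] schema).
#' @inheritParams fit_growth_metrics
#' @return Tibble with one metrics row per (strain, condition, conc_mM,
#'   replicate) curve.
#' @export
fit_growth_metrics_table <- function(curves, window = 5, od_floor = 0.01) {
  curves <- tibble::as_tibble(curves)
  needed <- c("strain", "condition", "conc_mM", "replicate", "time_h", "od")
  if (!all(needed %in% names(curves))) {
    stop("curves need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  curves |>
    dplyr::group_by(.data$strain, .data$condition, .data$conc_mM,
                    .data$replicate) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::reframe(fit_growth_metrics(.data$time_h, .data$od,
                                      window = window, od_floor = od_floor))
}

#' Estimate the LC50 from a dose series
#'
#' Fits a four-parameter logistic
#' `metric(c) = bottom + (top - bottom) / (1 + (c/ec50)^h)` by
#' Levenberg-Marquardt least squares and reports the concentration at which
#' the fitted metric falls to 50% of its zero-concentration value. When the
#' fit fails (or `method = "interpolation"`), the 50% crossing is obtained by
#' monotone linear interpolation of the replicate-mean metric relative to the
#' zero-concentration value.
#'
#' @param conc_mM Concentrations (mM), including 0; >= 4 distinct values.
#' @param metric Growth metric per concentration (Max OD by convention, or
#'   mu_max); duplicated concentrations are averaged.
#' @param method `"fourPL"` (default) or `"interpolation"`.
#' @return A list with `lc50_mM`, `method` (the one actually used), `fit`
#'   (named 4PL coefficients, or `NULL`), and the averaged `dose` tibble.
#' @export
#' @examples
#' estimate_lc50(c(0, 1, 2, 3), c(100, 75, 50, 25), method = "interpolation")
estimate_lc50 <- function(conc_mM, metric,
                          method = c("fourPL", "interpolation")) {
  method <- match.arg(method)
  if (length(conc_mM) != length(metric)) {
    stop("conc_mM and metric must have the same length", call. = FALSE)
  }
  dose <- tibble::tibble(conc_mM = conc_mM, metric = metric) |>
    dplyr::group_by(.data$conc_mM) |>
    dplyr::summarise(metric = mean(.data$metric), .groups = "drop") |>
    dplyr::arrange(.data$conc_mM)
  if (nrow(dose) < 4) stop(">= 4 distinct concentrations required", call. = FALSE)
  if (dose$conc_mM[1] != 0) {
    stop("a zero-concentration reference is required", call. = FALSE)
  }
  m0 <- dose$metric[dose$conc_mM == 0]
  if (m0 <= 0) stop("zero-concentration metric must be positive", call. = FALSE)
  if (diff(range(dose$metric)) <= 1e-12 * max(abs(dose$metric), 1)) {
    stop("no dose effect: all metric values are equal", call. = FALSE)
  }

  interpolate <- function() {
    rel <- 100 * dose$metric / m0
    below <- which(rel <= 50)
    if (length(below) == 0) {
      stop("metric never falls to 50% of the untreated value; ",
           "extend the dose range", call. = FALSE)
    }
    j <- below[1]
    if (j == 1) return(0)
    # walk back to the nearest point still above 50%
    i <- max(which(rel[seq_len(j - 1)] > 50))
    dose$conc_mM[i] + (rel[i] - 50) / (rel[i] - rel[j]) *
      (dose$conc_mM[j] - dose$conc_mM[i])
  }

  if (method == "interpolation") {
    return(list(lc50_mM = interpolate(), method = "interpolation",
                fit = NULL, dose = dose))
  }

  fit <- tryCatch({
    pos <- dose$conc_mM[dose$conc_mM > 0]
    rel <- dose$metric / m0
    ec50_start <- dose$conc_mM[which.min(abs(rel - 0.5))]
    if (ec50_start <= 0) ec50_start <- stats::median(pos)
    four_pl <- function(p, conc) {
      p$bottom + (p$top - p$bottom) / (1 + (conc / p$ec50)^p$h)
    }
    res <- minpack.lm::nls.lm(
      par = list(bottom = min(dose$metric), top = m0,
                 ec50 = ec50_start, h = 1),
      lower = c(0, 0, min(pos) / 100, 0.05),
      fn = function(p) dose$metric - four_pl(p, dose$conc_mM),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (res$info %in% 1:4) res else NULL
  }, error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- unlist(fit$par)
    top <- cf[["top"]]
    bottom <- cf[["bottom"]]
    if (top / 2 > bottom) {
      ratio <- (top - bottom) / (top / 2 - bottom) - 1
      lc50 <- cf[["ec50"]] * ratio^(1 / cf[["h"]])
      if (is.finite(lc50) && lc50 > 0) {
        return(list(lc50_mM = lc50, method = "fourPL", fit = cf, dose = dose))
      }
    }
  }
  list(lc50_mM = interpolate(), method = "interpolation", fit = NULL,
       dose = dose)
}

#' Compare a mutant strain to the reference
#'
#' Two-sided Student's t-test (pooled variance) per growth metric on
#' replicate values; the reported difference is mutant minus reference.
#'
#' @param mutant_metrics,reference_metrics Tibbles of per-replicate metrics
#'   containing the columns named in `metrics` (e.g. from
#'   [fit_growth_metrics_table()]).
#' @param metrics Metric columns to compare.
#' @param alpha Significance level used only for the star annotation.
#' @param var_equal Student (default) vs Welch.
#' @return Tibble with one row per metric: `difference`, `p_value`, `stars`,
#'   `n_mutant`, `n_reference`, `evaluable`.
#' @export
#' @examples
#' m <- tibble::tibble(mu_max = c(0.30, 0.31, 0.29))
#' r <- tibble::tibble(mu_max = c(0.40, 0.41, 0.39))
#' compare_strains(m, r, metrics = "mu_max")
compare_strains <- function(mutant_metrics, reference_metrics,
                            metrics = c("mu_max", "max_od"), alpha = 0.05,
                            var_equal = TRUE) {
  .assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                        strict_lower = TRUE)
  rows <- lapply(metrics, function(mname) {
    if (!mname %in% names(mutant_metrics) ||
        !mname %in% names(reference_metrics)) {
      stop("metric column '", mname, "' missing", call. = FALSE)
    }
    x <- mutant_metrics[[mname]]
    y <- reference_metrics[[mname]]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble::tibble(metric = mname, difference = NA_real_,
                            p_value = NA_real_, stars = "ns",
                            n_mutant = length(x), n_reference = length(y),
                            evaluable = FALSE))
    }
    ht <- .t_two_sample(x, y, var_equal = var_equal)
    tibble::tibble(metric = mname, difference = mean(x) - mean(y),
                   p_value = ht$p_value,
                   stars = significance_stars(ht$p_value),
                   n_mutant = length(x), n_reference = length(y),
                   evaluable = TRUE)
  })
  dplyr::bind_rows(rows)
}
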