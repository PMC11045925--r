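# Internal helpers shared across modules.

# Multiplicative lognormal noise factor with mean exactly 1 and the requested
# coefficient of variation. cv = 0 degenerates to a deterministic factor of 1.
.lognormal_factor <- function(n, cv) {
  stopifnot(is.numeric(cv), length(cv) == 1)
  if (cv < 0) stop("noise CV must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Pseudo-count convention: half the smallest positive value in scope.
# NA when there is no positive value at all.
.half_min_positive <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  if (length(pos) == 0) return(NA_real_)
  min(pos) / 2
}

# log2 ratio of two group means; the pseudo-count is added to BOTH means, and
# only when at least one of them is zero. Both-zero means give log2fc = 0.
.log2_ratio <- function(mean_num, mean_den, pseudo) {
  if (mean_num == 0 && mean_den == 0) return(0)
  if (mean_num == 0 || mean_den == 0) {
    if (!is.finite(pseudo) || pseudo <= 0) {
      return(if (mean_num == 0) -Inf else Inf)
    }
    return(log2((mean_num + pseudo) / (mean_den + pseudo)))
  }
  log2(mean_num / mean_den)
}

# Two-sample t-test wrapper tolerating constant data (where stats::t.test
# errors). Returns NA p-value when either side has fewer than 2 values.
.t_two_sample <- function(x, y, var_equal = TRUE) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(
      statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
      df = nx + ny - 2,
      p_value = if (same) 1 else 0
    ))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

# One-sample, one-sided (greater) t-test with the same constant-data guard.
.t_one_greater <- function(x, mu) {
  n <- length(x)
  if (n < 2) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  if (stats::sd(x) == 0) {
    return(list(
      statistic = if (mean(x) > mu) Inf else if (mean(x) < mu) -Inf else 0,
      df = n - 1,
      p_value = if (mean(x) > mu) 0 else 1
    ))
  }
  ht <- stats::t.test(x, mu = mu, alternative = "greater")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Map p-values to significance stars
#'
#' Standard star encoding used throughout the reports: `***` for p <= 0.001,
#' `**` for p <= 0.01, `*` for p <= 0.05 and `ns` otherwise (including `NA`).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length with values in
#'   `c("***", "**", "*", "ns")`.
#' @export
#' @examples
#' significance_stars(c(0.0005, 0.004, 0.04, 0.4, NA))
significance_stars <- function(p) {
  out <- rep("ns", length(p))
  out[!is.na(p) & p <= 0.05] <- "*"
  out[!is.na(p) & p <= 0.01] <- "**"
  out[!is.na(p) & p <= 0.001] <- "***"
  out
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}
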