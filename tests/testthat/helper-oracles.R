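# Independent closed-form oracles used to check the implementation paths.
# These deliberately avoid stats::t.test and stats::quantile.

# textbook pooled-variance two-sample t-test, two-sided
oracle_t_two_sided <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(statistic = tstat, p_value = 2 * pt(-abs(tstat), nx + ny - 2))
}

# one-sample, one-sided (greater) t-test
oracle_t_one_greater <- function(x, mu) {
  n <- length(x)
  tstat <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(statistic = tstat, p_value = pt(tstat, n - 1, lower.tail = FALSE))
}

# quartile by explicit linear interpolation between order statistics
# (the type-7 convention), written from the definition
oracle_quartile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# brute-force IQR fence enumeration, recomputing the fences on the kept
# values until no further value falls outside them (the declared convention)
oracle_iqr_flags <- function(x, k = 1.5) {
  flagged <- rep(FALSE, length(x))
  repeat {
    idx <- which(!flagged)
    if (length(idx) < 4) return(flagged)
    q1 <- oracle_quartile(x[idx], 0.25)
    q3 <- oracle_quartile(x[idx], 0.75)
    bad <- x[idx] < q1 - k * (q3 - q1) | x[idx] > q3 + k * (q3 - q1)
    if (!any(bad)) return(flagged)
    flagged[idx[bad]] <- TRUE
  }
}

# closed-form logistic growth curve
oracle_logistic <- function(t, mu, K, od0) {
  K / (1 + ((K - od0) / od0) * exp(-mu * t))
}

# build an oocyte assay design with exact fold changes over background:
# importers reach fold_import x background (A = 1, rate solved from the
# saturable form), exporters sit at beta x background
recovery_design <- function(n_imp, n_exp, n_null, fold_import = 4,
                            beta = 0.25, background_ratio = 0.25,
                            c_medium = 2, incubation_h = 3) {
  bg <- background_ratio * c_medium
  contribution <- (fold_import - 1) * bg
  k <- -log(1 - contribution / c_medium) / incubation_h
  rows <- list()
  add <- function(tb) rows[[length(rows) + 1]] <<- tb
  for (i in seq_len(n_imp)) {
    add(transporter_truth(paste0("IMP", i), paste0("cmp", i), "importer",
                          accumulation_ratio_A = 1, rate_k = k))
  }
  for (i in seq_len(n_exp)) {
    add(transporter_truth(paste0("EXP", i), paste0("cmp", i), "exporter",
                          exporter_factor_beta = beta))
  }
  # inactive conditions get their own compounds (hence their own GFP
  # controls) so error rates are measured over independent comparisons
  for (i in seq_len(n_null)) {
    add(transporter_truth(paste0("NUL", i), paste0("ncmp", i), "none"))
  }
  dplyr::bind_rows(rows)
}
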