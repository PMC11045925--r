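# Synthetic-data generators: serum exometabolome screen, oocyte uptake assay,
# and dose-dependent logistic growth. Every generator returns both the
# observable table and a ground-truth sidecar so downstream callers can be
# benchmarked by parameter/label recovery.

#' Parameters for the synthetic serum exometabolome screen
#'
#' Defines a mixture of consumed, secreted and unchanged compounds measured in
#' a control (serum only) and a treated (serum incubated with yeast) group,
#' with multiplicative lognormal replicate noise on LC-MS-like peak responses.
#'
#' @param n_compounds Number of compounds in the screen.
#' @param frac_consumed,frac_secreted Fractions of compounds with a true
#'   negative / positive log2 fold change. Their sum must be <= 1.
#' @param effect_log2fc_range Length-2 interval of absolute true log2 fold
#'   changes for effect compounds; strictly positive.
#' @param replicate_cv Coefficient of variation of the per-replicate lognormal
#'   measurement noise (fraction, e.g. 0.15 for 15%).
#' @param n_replicates_per_group Replicates per group (>= 2).
#' @param baseline_response_range Length-2 interval of baseline peak responses;
#'   baselines are drawn log-uniformly over it.
#' @param frac_drug Fraction of compounds annotated as drugs/xenobiotics (the
#'   rest are metabolites); annotation only, orthogonal to the effect mixture.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A validated parameter list of class `serum_sim_params`.
#' @export
serum_sim_params <- function(n_compounds = 1000,
                             frac_consumed = 0.2,
                             frac_secreted = 0.15,
                             effect_log2fc_range = c(0.8, 2),
                             replicate_cv = 0.15,
                             n_replicates_per_group = 3,
                             baseline_response_range = c(1e4, 1e7),
                             frac_drug = 0.3,
                             seed = NULL) {
  .assert_scalar_number(n_compounds, "n_compounds", lower = 1)
  .assert_scalar_number(frac_consumed, "frac_consumed", lower = 0, upper = 1)
  .assert_scalar_number(frac_secreted, "frac_secreted", lower = 0, upper = 1)
  if (frac_consumed + frac_secreted > 1) {
    stop("frac_consumed + frac_secreted must be <= 1", call. = FALSE)
  }
  .assert_scalar_number(replicate_cv, "replicate_cv", lower = 0)
  .assert_scalar_number(n_replicates_per_group, "n_replicates_per_group",
                        lower = 2)
  .assert_scalar_number(frac_drug, "frac_drug", lower = 0, upper = 1)
  if (length(effect_log2fc_range) != 2 || any(effect_log2fc_range <= 0) ||
      diff(effect_log2fc_range) < 0) {
    stop("effect_log2fc_range must be a strictly positive interval",
         call. = FALSE)
  }
  if (length(baseline_response_range) != 2 ||
      any(baseline_response_range <= 0) ||
      diff(baseline_response_range) < 0) {
    stop("baseline_response_range must be a positive interval", call. = FALSE)
  }
  structure(list(
    n_compounds = as.integer(n_compounds),
    frac_consumed = frac_consumed,
    frac_secreted = frac_secreted,
    effect_log2fc_range = effect_log2fc_range,
    replicate_cv = replicate_cv,
    n_replicates_per_group = as.integer(n_replicates_per_group),
    baseline_response_range = baseline_response_range,
    frac_drug = frac_drug,
    seed = seed
  ), class = "serum_sim_params")
}

#' Simulate a serum exometabolome screen
#'
#' Draws a compound x sample table of positive responses. Control replicates
#' scatter around a per-compound baseline; treated replicates are multiplied
#' by `2^e` where `e` is the compound's true log2 fold change (negative for
#' consumed, positive for secreted, zero for unchanged compounds). Class
#' counts are exact: `round(frac * n_compounds)` compounds per effect class.
#'
#' @param params A [serum_sim_params()] object.
#' @return A list with
#'   * `responses`: tidy tibble with columns `compound_id`, `class`
#'     (metabolite/drug), `sample_id`, `group` (control/treated), `replicate`,
#'     `response`;
#'   * `truth`: tibble with `compound_id`, `direction`
#'     (consumed/secreted/unchanged), `true_log2fc`, `baseline`.
#' @export
#' @examples
#' sim <- simulate_serum_screen(serum_sim_params(n_compounds = 20, seed = 1))
#' head(sim$responses)
simulate_serum_screen <- function(params = serum_sim_params()) {
  stopifnot(inherits(params, "serum_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_compounds
  n_cons <- round(params$frac_consumed * n)
  n_sec <- round(params$frac_secreted * n)
  if (n_cons + n_sec > n) n_sec <- n - n_cons

  direction <- rep(c("consumed", "secreted", "unchanged"),
                   c(n_cons, n_sec, n - n_cons - n_sec))
  effect <- numeric(n)
  if (n_cons + n_sec > 0) {
    mag <- stats::runif(n_cons + n_sec,
                        params$effect_log2fc_range[1],
                        params$effect_log2fc_range[2])
    effect[seq_len(n_cons + n_sec)] <- mag * ifelse(direction[seq_len(n_cons + n_sec)] == "consumed", -1, 1)
  }
  lo <- log10(params$baseline_response_range[1])
  hi <- log10(params$baseline_response_range[2])
  baseline <- 10^stats::runif(n, lo, hi)
  compound_id <- sprintf("C%04d", seq_len(n))
  cmpd_class <- ifelse(stats::runif(n) < params$frac_drug, "drug", "metabolite")

  k <- params$n_replicates_per_group
  grid <- tidyr::expand_grid(
    compound_idx = seq_len(n),
    group = c("control", "treated"),
    replicate = seq_len(k)
  )
  expected <- baseline[grid$compound_idx] *
    ifelse(grid$group == "treated", 2^effect[grid$compound_idx], 1)
  responses <- tibble::tibble(
    compound_id = compound_id[grid$compound_idx],
    class = cmpd_class[grid$compound_idx],
    sample_id = paste0(grid$group, "_", grid$replicate),
    group = grid$group,
    replicate = grid$replicate,
    response = expected * .lognormal_factor(nrow(grid), params$replicate_cv)
  )
  truth <- tibble::tibble(
    compound_id = compound_id,
    direction = direction,
    true_log2fc = effect,
    baseline = baseline
  )
  list(responses = responses, truth = truth)
}

#' Ground-truth activity of one transporter x compound condition
#'
#' Importers follow first-order saturable uptake toward an asymptotic
#' accumulation ratio `A` (intracellular over medium concentration; `A = 1`
#' equilibrative ceiling, `A > 1` concentrative). Exporters deplete the
#' endogenous background multiplicatively by `beta`. Inactive conditions sit
#' at the background.
#'
#' @param transporter,compound Condition labels.
#' @param activity One of `"importer"`, `"exporter"`, `"none"`.
#' @param accumulation_ratio_A Asymptotic C_in / C_medium for importers
#'   (>= 1); ignored otherwise.
#' @param rate_k First-order uptake rate (per hour) for importers; ignored
#'   otherwise.
#' @param exporter_factor_beta Multiplier in `[0, 1)` applied to the
#'   endogenous background for exporters; ignored otherwise.
#' @return One-row tibble; bind rows to build an assay design.
#' @export
transporter_truth <- function(transporter, compound,
                              activity = c("importer", "exporter", "none"),
                              accumulation_ratio_A = 1,
                              rate_k = 1,
                              exporter_factor_beta = 0.5) {
  activity <- match.arg(activity)
  if (activity == "importer") {
    .assert_scalar_number(accumulation_ratio_A, "accumulation_ratio_A", lower = 1)
    .assert_scalar_number(rate_k, "rate_k", lower = 0, strict_lower = TRUE)
  }
  if (activity == "exporter") {
    .assert_scalar_number(exporter_factor_beta, "exporter_factor_beta",
                          lower = 0, upper = 1)
    if (exporter_factor_beta >= 1) {
      stop("exporter_factor_beta must be < 1 for exporters", call. = FALSE)
    }
  }
  tibble::tibble(
    transporter = as.character(transporter),
    compound = as.character(compound),
    activity = activity,
    accumulation_ratio_A = accumulation_ratio_A,
    rate_k = rate_k,
    exporter_factor_beta = exporter_factor_beta
  )
}

#' Parameters for the synthetic oocyte uptake assay
#'
#' Assay constants default to the standard design: substrate at 2 mM, 3 h
#' incubation, pools of 10 oocytes, triplicate pools.
#'
#' @param c_medium Substrate concentration in the assay medium (mM).
#' @param incubation_h Incubation time (hours).
#' @param oocyte_volume_uL Volume of one oocyte (microlitres).
#' @param pool_size Oocytes per extracted pool.
#' @param n_pools Replicate pools per condition.
#' @param background_ratio Endogenous leak at assay end, as a fraction of
#'   `c_medium`. A scalar, or a named vector keyed by compound.
#' @param noise_cv Lognormal measurement CV per pool (fraction).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A validated parameter list of class `oocyte_sim_params`.
#' @export
oocyte_sim_params <- function(c_medium = 2.0,
                              incubation_h = 3.0,
                              oocyte_volume_uL = 1.0,
                              pool_size = 10,
                              n_pools = 3,
                              background_ratio = 0.25,
                              noise_cv = 0.2,
                              seed = NULL) {
  .assert_scalar_number(c_medium, "c_medium", lower = 0, strict_lower = TRUE)
  .assert_scalar_number(incubation_h, "incubation_h", lower = 0,
                        strict_lower = TRUE)
  .assert_scalar_number(oocyte_volume_uL, "oocyte_volume_uL", lower = 0,
                        strict_lower = TRUE)
  .assert_scalar_number(pool_size, "pool_size", lower = 1)
  .assert_scalar_number(n_pools, "n_pools", lower = 1)
  if (!is.numeric(background_ratio) || any(background_ratio < 0)) {
    stop("background_ratio must be numeric and >= 0", call. = FALSE)
  }
  .assert_scalar_number(noise_cv, "noise_cv", lower = 0)
  structure(list(
    c_medium = c_medium,
    incubation_h = incubation_h,
    oocyte_volume_uL = oocyte_volume_uL,
    pool_size = as.integer(pool_size),
    n_pools = as.integer(n_pools),
    background_ratio = background_ratio,
    noise_cv = noise_cv,
    seed = seed
  ), class = "oocyte_sim_params")
}

# expected intracellular concentration for one condition, noiseless
.oocyte_c_in <- function(activity, A, k, beta, background, c_medium,
                         incubation_h) {
  switch(activity,
    importer = background + A * c_medium * (1 - exp(-k * incubation_h)),
    exporter = beta * background,
    none = background,
    control = background,
    stop("unknown activity: ", activity, call. = FALSE)
  )
}

#' Simulate an oocyte uptake assay
#'
#' For every transporter x compound condition in `truths` (plus an
#' automatically added GFP-only control per compound) the expected
#' intracellular concentration is computed from the condition's activity
#' (see [transporter_truth()]), then `n_pools` pooled LC-MS responses are
#' drawn as `pool_size * oocyte_volume_uL * C_in` times lognormal noise.
#'
#' @param truths Tibble of conditions as built from [transporter_truth()];
#'   (transporter, compound) pairs must be unique.
#' @param params An [oocyte_sim_params()] object.
#' @return A list with
#'   * `measurements`: tibble with `transporter`, `compound`, `pool_id`,
#'     `n_oocytes`, `response` (the control rows use transporter
#'     `"GFP_control"`);
#'   * `truth`: condition-level tibble with the noiseless `c_in_true` (mM)
#'     and the generating activity.
#' @export
#' @examples
#' design <- transporter_truth("T1", "ACA", "importer",
#'                             accumulation_ratio_A = 4, rate_k = 2)
#' sim <- simulate_oocyte_assay(design, oocyte_sim_params(seed = 1))
#' sim$truth
simulate_oocyte_assay <- function(truths, params = oocyte_sim_params()) {
  stopifnot(inherits(params, "oocyte_sim_params"))
  truths <- tibble::as_tibble(truths)
  needed <- c("transporter", "compound", "activity")
  if (!all(needed %in% names(truths))) {
    stop("`truths` needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(truths[c("transporter", "compound")]) > 0) {
    stop("duplicate (transporter, compound) conditions", call. = FALSE)
  }
  if (any(truths$transporter == "GFP_control")) {
    stop("'GFP_control' is reserved for the auto-generated control",
         call. = FALSE)
  }
  if (!is.null(params$seed)) set.seed(params$seed)

  bg_for <- function(compound) {
    br <- params$background_ratio
    r <- if (!is.null(names(br))) unname(br[compound]) else br[1]
    if (is.na(r)) r <- 0
    r * params$c_medium
  }

  controls <- tibble::tibble(
    transporter = "GFP_control",
    compound = unique(truths$compound),
    activity = "control",
    accumulation_ratio_A = NA_real_,
    rate_k = NA_real_,
    exporter_factor_beta = NA_real_
  )
  for (col in c("accumulation_ratio_A", "rate_k", "exporter_factor_beta")) {
    if (!col %in% names(truths)) truths[[col]] <- NA_real_
  }
  conditions <- dplyr::bind_rows(truths[names(controls)], controls)

  c_in <- vapply(seq_len(nrow(conditions)), function(i) {
    row <- conditions[i, ]
    .oocyte_c_in(row$activity, row$accumulation_ratio_A, row$rate_k,
                 row$exporter_factor_beta, bg_for(row$compound),
                 params$c_medium, params$incubation_h)
  }, numeric(1))
  truth <- tibble::tibble(
    transporter = conditions$transporter,
    compound = conditions$compound,
    activity = conditions$activity,
    c_in_true = c_in
  )

  grid <- tidyr::expand_grid(idx = seq_len(nrow(conditions)),
                             pool = seq_len(params$n_pools))
  expected_amount <- params$pool_size * params$oocyte_volume_uL * c_in[grid$idx]
  measurements <- tibble::tibble(
    transporter = conditions$transporter[grid$idx],
    compound = conditions$compound[grid$idx],
    pool_id = paste0("pool_", grid$pool),
    n_oocytes = params$pool_size,
    response = expected_amount * .lognormal_factor(nrow(grid), params$noise_cv)
  )
  list(measurements = measurements, truth = truth)
}

#' Parameters for synthetic dose-dependent logistic growth
#'
#' Growth follows `OD(t) = K(c) / (1 + ((K(c) - od0)/od0) exp(-mu(c) t))`
#' where both the specific growth rate and the carrying capacity are inhibited
#' by a shared Hill term: `mu(c) = mu0 / (1 + (c/lc50)^h)` and
#' `K(c) = K0 / (1 + (c/lc50)^h)`. Defaults emulate a 72-h run sampled every
#' 20 minutes with an inoculum OD of 0.01 and a compound LC50 anchored at
#' 2.45 mM (the acrylic-acid fixture used throughout the growth tests).
#'
#' @param mu0 Uninhibited maximum specific growth rate (per hour).
#' @param K0 Uninhibited carrying capacity (OD units).
#' @param od0 Inoculum OD (must be < `K0`).
#' @param hill_h Hill coefficient of the inhibition term.
#' @param lc50_true Concentration halving both `mu` and `K` (mM).
#' @param concentrations Dose series (mM); must include 0 for a reference.
#' @param t_grid Sampling times (hours), strictly increasing.
#' @param od_noise_sd Additive Gaussian OD noise (truncated at 0).
#' @param n_replicates Replicate curves per concentration.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A validated parameter list of class `growth_sim_params`.
#' @export
growth_sim_params <- function(mu0 = 0.4,
                              K0 = 1.2,
                              od0 = 0.01,
                              hill_h = 2,
                              lc50_true = 2.45,
                              concentrations = 2.45 * c(0, 0.25, 0.5, 1, 2, 4, 8),
                              t_grid = seq(0, 72, by = 1 / 3),
                              od_noise_sd = 0.02,
                              n_replicates = 3,
                              seed = NULL) {
  .assert_scalar_number(mu0, "mu0", lower = 0, strict_lower = TRUE)
  .assert_scalar_number(K0, "K0", lower = 0, strict_lower = TRUE)
  .assert_scalar_number(od0, "od0", lower = 0, strict_lower = TRUE)
  if (od0 >= K0) stop("od0 must be < K0", call. = FALSE)
  .assert_scalar_number(hill_h, "hill_h", lower = 0, strict_lower = TRUE)
  .assert_scalar_number(lc50_true, "lc50_true", lower = 0, strict_lower = TRUE)
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(diff(t_grid) <= 0) || length(t_grid) < 10) {
    stop("t_grid must be strictly increasing with >= 10 points", call. = FALSE)
  }
  .assert_scalar_number(od_noise_sd, "od_noise_sd", lower = 0)
  .assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  structure(list(
    mu0 = mu0, K0 = K0, od0 = od0, hill_h = hill_h, lc50_true = lc50_true,
    concentrations = concentrations, t_grid = t_grid,
    od_noise_sd = od_noise_sd, n_replicates = as.integer(n_replicates),
    seed = seed
  ), class = "growth_sim_params")
}

# closed-form logistic with dose inhibition; exported through truth sidecars
.logistic_od <- function(t, mu, K, od0) {
  K / (1 + ((K - od0) / od0) * exp(-mu * t))
}

#' Simulate dose-dependent growth curves
#'
#' @param params A [growth_sim_params()] object.
#' @param strain,condition Labels carried into the output table.
#' @return A list with
#'   * `curves`: tidy tibble with `strain`, `condition`, `conc_mM`,
#'     `replicate`, `time_h`, `od`;
#'   * `truth`: per-concentration tibble with the inhibited `mu_c`, `K_c` and
#'     `lc50_true`.
#' @export
#' @examples
#' sim <- simulate_growth_curves(growth_sim_params(seed = 1))
#' sim$truth
simulate_growth_curves <- function(params = growth_sim_params(),
                                   strain = "BY4741",
                                   condition = "dose_series") {
  stopifnot(inherits(params, "growth_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  inhib <- 1 + (params$concentrations / params$lc50_true)^params$hill_h
  mu_c <- params$mu0 / inhib
  K_c <- params$K0 / inhib
  # keep the logistic well-defined when inhibition pushes K below the inoculum
  K_c <- pmax(K_c, params$od0 * 1.001)
  truth <- tibble::tibble(
    conc_mM = params$concentrations,
    mu_c = mu_c,
    K_c = K_c,
    lc50_true = params$lc50_true
  )
  grid <- tidyr::expand_grid(
    ci = seq_along(params$concentrations),
    replicate = seq_len(params$n_replicates),
    time_h = params$t_grid
  )
  od_clean <- .logistic_od(grid$time_h, mu_c[grid$ci], K_c[grid$ci], params$od0)
  od <- od_clean
  if (params$od_noise_sd > 0) {
    od <- pmax(od_clean + stats::rnorm(length(od_clean), 0, params$od_noise_sd), 0)
  }
  curves <- tibble::tibble(
    strain = strain,
    condition = condition,
    conc_mM = params$concentrations[grid$ci],
    replicate = paste0("rep_", grid$replicate),
    time_h = grid$time_h,
    od = od
  )
  list(curves = curves, truth = truth)
}
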