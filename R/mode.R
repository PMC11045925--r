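# Concentrative vs equilibrative classification: compare the intracellular
# concentration reached by a significant importer with the (constant) medium
# concentration, with optional endogenous-background correction from the
# GFP-only control.

#' Assay constants for concentration conversion
#'
#' @param c_medium_mM Substrate concentration in the medium (mM); default 2.
#' @param oocyte_volume_uL Volume of a single oocyte (microlitres).
#' @param response_per_mM Calibration factor converting response-per-oocyte to
#'   mM; with unity calibration only ratios to the medium are meaningful,
#'   which is all the mode call uses.
#' @return A validated list of class `assay_constants`.
#' @export
assay_constants <- function(c_medium_mM = 2.0, oocyte_volume_uL = 1.0,
                            response_per_mM = 1.0) {
  .assert_scalar_number(c_medium_mM, "c_medium_mM", lower = 0,
                        strict_lower = TRUE)
  .assert_scalar_number(oocyte_volume_uL, "oocyte_volume_uL", lower = 0,
                        strict_lower = TRUE)
  .assert_scalar_number(response_per_mM, "response_per_mM", lower = 0,
                        strict_lower = TRUE)
  structure(list(c_medium_mM = c_medium_mM,
                 oocyte_volume_uL = oocyte_volume_uL,
                 response_per_mM = response_per_mM),
            class = "assay_constants")
}

#' Convert a per-oocyte amount to an intracellular concentration
#'
#' `c_in = amount / (response_per_mM * oocyte_volume_uL)`. Doubling the
#' oocyte volume halves the concentration for a fixed amount.
#'
#' @param per_oocyte_amount Non-negative per-oocyte amount(s).
#' @param constants An [assay_constants()] object.
#' @return Concentration(s) in mM.
#' @export
#' @examples
#' amount_to_concentration(2, assay_constants())
amount_to_concentration <- function(per_oocyte_amount,
                                    constants = assay_constants()) {
  stopifnot(inherits(constants, "assay_constants"))
  if (any(per_oocyte_amount < 0)) stop("amount must be >= 0", call. = FALSE)
  per_oocyte_amount / (constants$response_per_mM * constants$oocyte_volume_uL)
}

#' Compare intracellular concentrations to the medium
#'
#' The medium concentration is treated as a known constant (substrate in
#' excess, medium volume much larger than the oocytes). Reports
#' `log2fc = log2(mean(c_in) / c_medium)` and a one-sided one-sample
#' Student's t-test of `c_in > c_medium`. All-zero replicates give a
#' `-Inf` log2 fold change (equilibrative by definition).
#'
#' @param c_in_values Replicate intracellular concentrations (mM), >= 2.
#' @param c_medium Medium concentration (mM).
#' @return A list with `log2fc`, `p_one_sided`, `statistic`, `df`, `n`.
#' @export
#' @examples
#' compare_to_medium(c(7.5, 8.2, 8.4), c_medium = 2)
compare_to_medium <- function(c_in_values, c_medium = 2.0) {
  .assert_scalar_number(c_medium, "c_medium", lower = 0, strict_lower = TRUE)
  m <- mean(c_in_values)
  lfc <- if (m == 0) -Inf else log2(m / c_medium)
  ht <- .t_one_greater(c_in_values, c_medium)
  list(log2fc = lfc, p_one_sided = ht$p_value, statistic = ht$statistic,
       df = ht$df, n = length(c_in_values))
}

#' Classify the mode of transport
#'
#' Concentrative iff the intracellular concentration significantly exceeds
#' the medium (`log2fc > 0` and one-sided `p <= alpha`); otherwise
#' equilibrative. Callers should restrict to import-direction conditions.
#'
#' @param log2fc Log2 fold change versus the medium.
#' @param p_one_sided One-sided p-value of `c_in > c_medium`.
#' @param alpha Significance level; default 0.05.
#' @return `"concentrative"` or `"equilibrative"` (`NA` on missing inputs).
#' @export
classify_mode <- function(log2fc, p_one_sided, alpha = 0.05) {
  .assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                        strict_lower = TRUE)
  if (is.na(log2fc) || is.na(p_one_sided)) return(NA_character_)
  if (log2fc > 0 && p_one_sided <= alpha) "concentrative" else "equilibrative"
}

#' Correct a mode call for endogenous background uptake
#'
#' When the GFP-only control itself accumulates the compound above the medium
#' (significant positive control-vs-medium test) the raw mode call is biased
#' by endogenous transport. The correction subtracts the control mean from
#' every transporter replicate and re-runs the mode test on the differences;
#' the corrected concentration `max(mean_T - mean_GFP, 0)` is reported
#' alongside and can never exceed the raw mean.
#'
#' @param c_in_transporter Replicate transporter concentrations (mM).
#' @param c_in_gfp Replicate control concentrations (mM) for the same
#'   compound; `NULL` skips the correction with a warning.
#' @param c_medium Medium concentration (mM).
#' @param alpha Significance level.
#' @return A list with `corrected_c_in`, `corrected_log2fc`,
#'   `p_one_sided_corrected`, `mode_after_correction`, `background_biased`.
#' @export
#' @examples
#' background_correct(c(4.8, 5.0, 5.2), c(0.9, 1.0, 1.1), c_medium = 2)
background_correct <- function(c_in_transporter, c_in_gfp, c_medium = 2.0,
                               alpha = 0.05) {
  if (is.null(c_in_gfp) || length(c_in_gfp) == 0) {
    warning("no GFP control concentrations; background correction skipped")
    return(list(corrected_c_in = NA_real_, corrected_log2fc = NA_real_,
                p_one_sided_corrected = NA_real_,
                mode_after_correction = NA_character_,
                background_biased = NA))
  }
  gfp_mean <- mean(c_in_gfp)
  gfp_test <- compare_to_medium(c_in_gfp, c_medium)
  background_biased <- identical(
    classify_mode(gfp_test$log2fc, gfp_test$p_one_sided, alpha),
    "concentrative"
  )
  corrected_vals <- c_in_transporter - gfp_mean
  corrected_c_in <- max(mean(c_in_transporter) - gfp_mean, 0)
  ht <- .t_one_greater(corrected_vals, c_medium)
  corrected_log2fc <- if (corrected_c_in == 0) -Inf else {
    log2(corrected_c_in / c_medium)
  }
  list(
    corrected_c_in = corrected_c_in,
    corrected_log2fc = corrected_log2fc,
    p_one_sided_corrected = ht$p_value,
    mode_after_correction = classify_mode(corrected_log2fc, ht$p_value, alpha),
    background_biased = background_biased
  )
}

#' Classify transport mode for every imported condition
#'
#' Takes the output of [call_uptake()] plus assay constants, converts
#' per-oocyte amounts (outliers excluded) to concentrations, and classifies
#' every condition called `import` as concentrative or equilibrative, both
#' raw and after endogenous-background correction.
#'
#' @param uptake Output list of [call_uptake()] (`calls` + `per_pool`).
#' @param constants An [assay_constants()] object.
#' @param alpha Significance level; default 0.05.
#' @param control_label Transporter label of the control rows.
#' @return Tibble with one row per import-direction condition: `c_in_mM`,
#'   `log2fc_vs_medium`, `p_one_sided`, `mode`, `background_biased`,
#'   `corrected_c_in_mM`, `mode_after_correction`, plus significance stars
#'   for the raw test. Non-import conditions are kept with `mode = NA` so the
#'   report stays complete.
#' @export
#' @examples
#' design <- transporter_truth("T1", "ACA", "importer",
#'                             accumulation_ratio_A = 4, rate_k = 2)
#' sim <- simulate_oocyte_assay(design, oocyte_sim_params(seed = 1))
#' up <- call_uptake(sim$measurements)
#' call_transport_mode(up)
call_transport_mode <- function(uptake, constants = assay_constants(),
                                alpha = 0.05,
                                control_label = "GFP_control") {
  stopifnot(is.list(uptake), !is.null(uptake$calls), !is.null(uptake$per_pool))
  stopifnot(inherits(constants, "assay_constants"))
  per_pool <- uptake$per_pool
  kept <- dplyr::filter(per_pool, !.data$outlier)
  conc_of <- function(tr, cp) {
    amount_to_concentration(
      kept$per_oocyte[kept$transporter == tr & kept$compound == cp],
      constants
    )
  }
  calls <- uptake$calls
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    tr <- calls$transporter[i]
    cp <- calls$compound[i]
    base <- tibble::tibble(
      transporter = tr, compound = cp, direction = calls$direction[i],
      c_in_mM = NA_real_, log2fc_vs_medium = NA_real_,
      p_one_sided = NA_real_, mode = NA_character_,
      background_biased = NA, corrected_c_in_mM = NA_real_,
      mode_after_correction = NA_character_
    )
    if (!identical(calls$direction[i], "import")) return(base)
    c_in <- conc_of(tr, cp)
    if (length(c_in) < 2) return(base)
    med <- compare_to_medium(c_in, constants$c_medium_mM)
    base$c_in_mM <- mean(c_in)
    base$log2fc_vs_medium <- med$log2fc
    base$p_one_sided <- med$p_one_sided
    base$mode <- classify_mode(med$log2fc, med$p_one_sided, alpha)
    gfp <- conc_of(control_label, cp)
    if (length(gfp) >= 1) {
      corr <- background_correct(c_in, gfp, constants$c_medium_mM, alpha)
      base$background_biased <- corr$background_biased
      base$corrected_c_in_mM <- corr$corrected_c_in
      base$mode_after_correction <- corr$mode_after_correction
    } else {
      warning("no GFP control for compound ", cp,
              "; background correction skipped")
    }
    base
  })
  out <- dplyr::bind_rows(rows)
  out$significance_stars <- significance_stars(out$p_one_sided)
  out
}
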