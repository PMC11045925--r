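# Exometabolome differential screen: per-compound log2 fold change and
# coefficient of variation, dual-threshold filtering, and the
# consumed/secreted/unchanged partition.

# per-group CV in percent; an all-zero group has sd 0 and is reported as 0
.cv_percent <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (m == 0) {
    if (s == 0) 0 else NA_real_
  } else {
    100 * s / m
  }
}

#' Per-compound log2 fold change and coefficient of variation
#'
#' Computes, for every compound in a tidy response table, the log2 ratio of
#' the treated over the control group mean and the percent CV of each group.
#' A pseudo-count is added to both means only when one of them is zero;
#' `pseudo = "auto"` uses half the smallest positive response in the table.
#' Compounds with all-zero responses in both groups are flagged
#' `evaluable = FALSE` and are excluded from direction calling.
#'
#' @param table Tidy tibble with columns `compound_id`, `group`
#'   (`"control"`/`"treated"`), `response` (and any extra columns, ignored).
#' @param pseudo `"auto"` or a positive number.
#' @return Tibble with one row per compound: `compound_id`, `mean_control`,
#'   `mean_treated`, `log2fc`, `cv_control`, `cv_treated`, `evaluable`.
#' @export
#' @examples
#' sim <- simulate_serum_screen(serum_sim_params(n_compounds = 10, seed = 1))
#' compute_log2fc_cv(sim$responses)
compute_log2fc_cv <- function(table, pseudo = "auto") {
  table <- tibble::as_tibble(table)
  needed <- c("compound_id", "group", "response")
  if (!all(needed %in% names(table))) {
    stop("table needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!all(table$group %in% c("control", "treated"))) {
    stop("group must be 'control' or 'treated'", call. = FALSE)
  }
  if (any(!is.finite(table$response)) || any(table$response < 0)) {
    stop("responses must be finite and >= 0", call. = FALSE)
  }
  n_rep <- dplyr::count(table, .data$compound_id, .data$group)
  if (any(n_rep$n < 2)) {
    stop("every compound needs >= 2 replicates per group", call. = FALSE)
  }
  if (identical(pseudo, "auto")) {
    pseudo <- .half_min_positive(table$response)
  } else {
    .assert_scalar_number(pseudo, "pseudo", lower = 0, strict_lower = TRUE)
  }

  stats_tbl <- table |>
    dplyr::group_by(.data$compound_id, .data$group) |>
    dplyr::summarise(
      m = mean(.data$response),
      cv = .cv_percent(.data$response),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "group", values_from = c("m", "cv"))

  stats_tbl |>
    dplyr::mutate(
      evaluable = !(.data$m_control == 0 & .data$m_treated == 0),
      log2fc = mapply(.log2_ratio, .data$m_treated, .data$m_control,
                      MoreArgs = list(pseudo = pseudo)),
      log2fc = ifelse(.data$evaluable, .data$log2fc, NA_real_)
    ) |>
    dplyr::transmute(
      compound_id = .data$compound_id,
      mean_control = .data$m_control,
      mean_treated = .data$m_treated,
      log2fc = .data$log2fc,
      cv_control = .data$cv_control,
      cv_treated = .data$cv_treated,
      evaluable = .data$evaluable
    )
}

#' Classify compounds as consumed, secreted or unchanged
#'
#' Applies the dual-threshold screen filter: a compound passes when
#' `|log2fc| > fc_threshold` and the larger of the two group CVs is below
#' `cv_threshold`. Passing compounds with a negative log2 fold change
#' (supernatant below serum) are called `consumed`, positive ones `secreted`;
#' everything else, including non-evaluable compounds, is `unchanged`.
#'
#' @param stats Output of [compute_log2fc_cv()].
#' @param fc_threshold Absolute log2 fold-change threshold (> 0); default 0.5.
#' @param cv_threshold Percent CV ceiling (> 0); default 30.
#' @return `stats` with added columns `passes_filter` and `direction`.
#' @export
classify_direction <- function(stats, fc_threshold = 0.5, cv_threshold = 30) {
  .assert_scalar_number(fc_threshold, "fc_threshold", lower = 0,
                        strict_lower = TRUE)
  .assert_scalar_number(cv_threshold, "cv_threshold", lower = 0,
                        strict_lower = TRUE)
  stats |>
    dplyr::mutate(
      cv_max = pmax(.data$cv_control, .data$cv_treated),
      passes_filter = .data$evaluable &
        !is.na(.data$log2fc) &
        abs(.data$log2fc) > fc_threshold &
        !is.na(.data$cv_max) &
        .data$cv_max < cv_threshold,
      direction = dplyr::case_when(
        .data$passes_filter & .data$log2fc < 0 ~ "consumed",
        .data$passes_filter & .data$log2fc > 0 ~ "secreted",
        TRUE ~ "unchanged"
      )
    ) |>
    dplyr::select(-"cv_max")
}

#' Summarize a screen partition
#'
#' Counts consumed / secreted / unchanged compounds overall and, when compound
#' classes are supplied, per class. The three direction counts always sum to
#' the number of compounds.
#'
#' @param results Output of [classify_direction()].
#' @param compound_classes Optional tibble with `compound_id` and `class`
#'   (`metabolite` / `drug`; anything else is bucketed as `unknown` with a
#'   warning).
#' @return A list with `overall` (named counts including `total`) and
#'   `by_class` (tibble, or `NULL` when no classes were given).
#' @export
summarize_screen <- function(results, compound_classes = NULL) {
  dirs <- factor(results$direction,
                 levels = c("consumed", "secreted", "unchanged"))
  if (anyNA(dirs)) stop("unknown direction labels in results", call. = FALSE)
  overall <- as.list(table(dirs))
  overall$total <- nrow(results)
  by_class <- NULL
  if (!is.null(compound_classes)) {
    cls <- tibble::as_tibble(compound_classes)[c("compound_id", "class")]
    cls <- dplyr::distinct(cls)
    bad <- !cls$class %in% c("metabolite", "drug", "unknown")
    if (any(bad)) {
      warning(sum(bad), " compound(s) with unrecognized class bucketed as 'unknown'")
      cls$class[bad] <- "unknown"
    }
    by_class <- results |>
      dplyr::left_join(cls, by = "compound_id") |>
      dplyr::mutate(class = dplyr::coalesce(.data$class, "unknown")) |>
      dplyr::count(.data$class, .data$direction) |>
      tidyr::pivot_wider(names_from = "direction", values_from = "n",
                         values_fill = 0)
    for (col in c("consumed", "secreted", "unchanged")) {
      if (!col %in% names(by_class)) by_class[[col]] <- 0L
    }
  }
  list(overall = overall, by_class = by_class)
}

#' Run the full exometabolome screen
#'
#' Convenience wrapper chaining [compute_log2fc_cv()], [classify_direction()]
#' and [summarize_screen()].
#'
#' @inheritParams compute_log2fc_cv
#' @inheritParams classify_direction
#' @return A list with `results` (per-compound tibble) and `summary`.
#' @export
#' @examples
#' sim <- simulate_serum_screen(serum_sim_params(n_compounds = 50, seed = 1))
#' out <- run_exo_screen(sim$responses)
#' out$summary$overall
run_exo_screen <- function(table, fc_threshold = 0.5, cv_threshold = 30,
                           pseudo = "auto") {
  stats_tbl <- compute_log2fc_cv(table, pseudo = pseudo)
  results <- classify_direction(stats_tbl, fc_threshold, cv_threshold)
  classes <- if ("class" %in% names(table)) {
    dplyr::distinct(tibble::as_tibble(table)[c("compound_id", "class")])
  } else {
    NULL
  }
  list(results = results, summary = summarize_screen(results, classes))
}
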