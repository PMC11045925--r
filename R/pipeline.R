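# Pipeline orchestration: schema validation for the on-disk tables, a YAML
# run configuration, stage sequencing, and a combined deorphanization report.
# Stages communicate through tidy CSV + JSON so every intermediate is
# inspectable and a run is resumable.

.schemas <- list(
  serum = list(
    required = c("compound_id", "class", "sample_id", "group", "replicate",
                 "response"),
    key = c("compound_id", "sample_id")
  ),
  oocyte = list(
    required = c("transporter", "compound", "pool_id", "n_oocytes",
                 "response"),
    key = c("transporter", "compound", "pool_id")
  ),
  growth = list(
    required = c("strain", "condition", "conc_mM", "replicate", "time_h",
                 "od"),
    key = c("strain", "condition", "conc_mM", "replicate", "time_h")
  )
)

.row_violations <- function(data, schema_name) {
  v <- list()
  flag <- function(rows, column, problem) {
    if (length(rows) > 0) {
      v[[length(v) + 1]] <<- tibble::tibble(row = rows, column = column,
                                            problem = problem)
    }
  }
  if (schema_name == "serum") {
    flag(which(!data$group %in% c("control", "treated")), "group",
         "group must be 'control' or 'treated'")
    flag(which(!is.finite(data$response) | data$response < 0), "response",
         "response must be finite and >= 0")
  }
  if (schema_name == "oocyte") {
    flag(which(!is.finite(data$n_oocytes) | data$n_oocytes < 1), "n_oocytes",
         "n_oocytes must be >= 1")
    flag(which(!is.finite(data$response) | data$response < 0), "response",
         "response must be finite and >= 0")
  }
  if (schema_name == "growth") {
    flag(which(!is.finite(data$od) | data$od < 0), "od",
         "od must be finite and >= 0")
    flag(which(!is.finite(data$time_h) | data$time_h < 0), "time_h",
         "time_h must be finite and >= 0")
    flag(which(!is.finite(data$conc_mM) | data$conc_mM < 0), "conc_mM",
         "conc_mM must be finite and >= 0")
  }
  key <- .schemas[[schema_name]]$key
  dup <- which(duplicated(data[key]))
  flag(dup, paste(key, collapse = "+"), "duplicated key")
  if (length(v) == 0) {
    tibble::tibble(row = integer(), column = character(),
                   problem = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Validate an input table against a stage schema
#'
#' Reads a CSV (or accepts an in-memory data frame), applies an optional
#' user-column mapping, checks that the required columns are present, and
#' collects row-level violations (negative counts, duplicated keys, ...)
#' with their row numbers instead of failing on the first one.
#'
#' @param path_or_df CSV/TSV path or a data frame.
#' @param schema One of `"serum"`, `"oocyte"`, `"growth"`.
#' @param mapping Optional named character vector `c(required_name = user_name)`
#'   renaming user columns onto the schema.
#' @return A list of class `validated_table` with `data` (tibble),
#'   `violations` (tibble with `row`, `column`, `problem`) and `schema`.
#' @export
#' @examples
#' sim <- simulate_oocyte_assay(
#'   transporter_truth("T1", "ACA", "importer", 4, 2),
#'   oocyte_sim_params(seed = 1)
#' )
#' validate_table(sim$measurements, "oocyte")$violations
validate_table <- function(path_or_df, schema = c("serum", "oocyte", "growth"),
                           mapping = NULL) {
  schema <- match.arg(schema)
  spec <- .schemas[[schema]]
  if (is.character(path_or_df)) {
    if (!file.exists(path_or_df)) {
      stop("file not found: ", path_or_df, call. = FALSE)
    }
    delim <- if (grepl("\\.tsv$", path_or_df)) "\t" else ","
    data <- readr::read_delim(path_or_df, delim = delim,
                              show_col_types = FALSE, progress = FALSE)
  } else {
    data <- tibble::as_tibble(path_or_df)
  }
  if (nrow(data) == 0) stop("input table is empty", call. = FALSE)
  if (!is.null(mapping)) {
    for (target in names(mapping)) {
      if (mapping[[target]] %in% names(data)) {
        names(data)[names(data) == mapping[[target]]] <- target
      }
    }
  }
  missing <- setdiff(spec$required, names(data))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(names(data), collapse = ", "), call. = FALSE)
  }
  data <- data[spec$required]
  structure(list(data = data, violations = .row_violations(data, schema),
                 schema = schema),
            class = "validated_table")
}

#' Read and validate a YAML run configuration
#'
#' A configuration holds one block per stage (`simulate`, `screen`, `uptake`,
#' `mode`, `growth`) plus top-level `seed` and `alpha`. At least one stage
#' block must be present.
#'
#' @param path YAML file path.
#' @return The configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  stages <- intersect(names(cfg), c("simulate", "screen", "uptake", "mode",
                                    "growth"))
  if (length(stages) == 0) {
    stop("config must contain at least one stage block", call. = FALSE)
  }
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  .assert_scalar_number(cfg$alpha, "alpha", lower = 0, upper = 1,
                        strict_lower = TRUE)
  if (cfg$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# stable content hash of the configuration (timestamps excluded by design)
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

.write_csv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  readr::write_csv(x, file.path(dir, name))
}

#' Run the deorphanization pipeline
#'
#' Executes the configured stages in dependency order
#' (simulate -> screen / uptake -> mode / growth), writing every intermediate
#' as tidy CSV (plus JSON truth sidecars) under `out_dir`, and returns a
#' combined report. Identical configuration and seed give an identical report
#' payload. A stage failure marks the stage failed, skips its downstream
#' stages, and is reflected in the report's `status`.
#'
#' Stage blocks:
#' * `simulate`: sub-blocks `serum`, `oocyte`, `growth`, each holding the
#'   matching `*_sim_params()` arguments (oocyte additionally takes a
#'   `truths` list of [transporter_truth()] argument lists).
#' * `screen`: optional `input` CSV (defaults to the simulated serum table),
#'   `fc_threshold`, `cv_threshold`.
#' * `uptake`: optional `input` CSV (defaults to the simulated oocyte table),
#'   `welch`, `bh`, `blank_level`.
#' * `mode`: `c_medium_mM`, `oocyte_volume_uL`, `response_per_mM`.
#' * `growth`: optional `input` CSV, `window`, `od_floor`, `metric`
#'   (`"max_od"` or `"mu_max"`), `reference_strain`.
#'
#' @param config Configuration list or YAML path (see [read_run_config()]).
#' @param out_dir Output directory (created if needed); `NULL` keeps results
#'   in memory only.
#' @param seed Overrides the config seed when given.
#' @return A list of class `deorphan_report`: `provenance`, `status` (per
#'   stage: `ok`, `failed`, `skipped`, `disabled`), and one result element
#'   per executed stage.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else {
    validate_run_config(config)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  alpha <- cfg$alpha
  status <- list()
  report <- list()
  failed_upstream <- character()

  run_stage <- function(name, deps, fun) {
    if (is.null(cfg[[name]])) {
      status[[name]] <<- "disabled"
      return(invisible(NULL))
    }
    if (any(deps %in% failed_upstream)) {
      status[[name]] <<- "skipped"
      message("stage '", name, "' skipped: upstream failure")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(cfg[[name]]), error = function(e) {
      message("stage '", name, "' failed: ", conditionMessage(e))
      e
    })
    if (inherits(res, "error")) {
      status[[name]] <<- "failed"
      failed_upstream <<- c(failed_upstream, name)
    } else {
      status[[name]] <<- "ok"
      report[[name]] <<- res
    }
    invisible(NULL)
  }

  sim <- new.env(parent = emptyenv())
  run_stage("simulate", character(), function(block) {
    out <- list()
    if (!is.null(block$serum)) {
      p <- do.call(serum_sim_params,
                   utils::modifyList(block$serum, list(seed = cfg$seed)))
      sim$serum <- simulate_serum_screen(p)
      .write_csv(sim$serum$responses, out_dir, "serum_screen.csv")
      if (!is.null(out_dir)) {
        jsonlite::write_json(sim$serum$truth,
                             file.path(out_dir, "serum_truth.json"),
                             digits = NA)
      }
      out$serum <- list(n_compounds = nrow(sim$serum$truth))
    }
    if (!is.null(block$oocyte)) {
      truths <- dplyr::bind_rows(lapply(block$oocyte$truths, function(a) {
        do.call(transporter_truth, a)
      }))
      args <- block$oocyte
      args$truths <- NULL
      p <- do.call(oocyte_sim_params,
                   utils::modifyList(args, list(seed = cfg$seed + 1L)))
      sim$oocyte <- simulate_oocyte_assay(truths, p)
      .write_csv(sim$oocyte$measurements, out_dir, "oocyte_assay.csv")
      if (!is.null(out_dir)) {
        jsonlite::write_json(sim$oocyte$truth,
                             file.path(out_dir, "oocyte_truth.json"),
                             digits = NA)
      }
      out$oocyte <- list(n_conditions = nrow(sim$oocyte$truth))
    }
    if (!is.null(block$growth)) {
      p <- do.call(growth_sim_params,
                   utils::modifyList(block$growth, list(seed = cfg$seed + 2L)))
      sim$growth <- simulate_growth_curves(p)
      .write_csv(sim$growth$curves, out_dir, "growth_curves.csv")
      out$growth <- list(n_curves = nrow(dplyr::distinct(
        sim$growth$curves[c("conc_mM", "replicate")])))
    }
    out
  })

  load_input <- function(block, schema, sim_field) {
    if (!is.null(block$input)) {
      vt <- validate_table(block$input, schema, mapping = block$mapping)
    } else if (!is.null(sim[[sim_field]])) {
      tbl <- if (schema == "serum") sim[[sim_field]]$responses else {
        if (schema == "oocyte") sim[[sim_field]]$measurements else {
          sim[[sim_field]]$curves
        }
      }
      vt <- validate_table(tbl, schema)
    } else {
      stop("no input: provide `input` or enable the simulate stage")
    }
    if (nrow(vt$violations) > 0) {
      stop(nrow(vt$violations), " row-level schema violation(s); first: ",
           vt$violations$problem[1], " (row ", vt$violations$row[1], ")")
    }
    vt$data
  }

  run_stage("screen", "simulate", function(block) {
    tbl <- load_input(block, "serum", "serum")
    out <- run_exo_screen(
      tbl,
      fc_threshold = block$fc_threshold %||% 0.5,
      cv_threshold = block$cv_threshold %||% 30
    )
    .write_csv(out$results, out_dir, "screen_results.csv")
    if (!is.null(out_dir)) {
      jsonlite::write_json(out$summary$overall,
                           file.path(out_dir, "screen_summary.json"),
                           auto_unbox = TRUE)
    }
    out
  })

  uptake_res <- NULL
  run_stage("uptake", "simulate", function(block) {
    tbl <- load_input(block, "oocyte", "oocyte")
    out <- call_uptake(
      tbl, alpha = alpha,
      var_equal = !isTRUE(block$welch),
      bh = isTRUE(block$bh),
      blank_level = block$blank_level %||% 0
    )
    uptake_res <<- out
    .write_csv(out$calls, out_dir, "uptake_calls.csv")
    .write_csv(out$per_pool, out_dir, "uptake_per_pool.csv")
    out
  })

  run_stage("mode", c("simulate", "uptake"), function(block) {
    if (is.null(uptake_res)) stop("mode stage requires the uptake stage")
    constants <- assay_constants(
      c_medium_mM = block$c_medium_mM %||% 2.0,
      oocyte_volume_uL = block$oocyte_volume_uL %||% 1.0,
      response_per_mM = block$response_per_mM %||% 1.0
    )
    out <- call_transport_mode(uptake_res, constants, alpha = alpha)
    .write_csv(out, out_dir, "mode_calls.csv")
    out
  })

  run_stage("growth", "simulate", function(block) {
    tbl <- load_input(block, "growth", "growth")
    metrics <- fit_growth_metrics_table(
      tbl, window = block$window %||% 5, od_floor = block$od_floor %||% 0.01
    )
    .write_csv(metrics, out_dir, "growth_metrics.csv")
    metric_col <- block$metric %||% "max_od"
    dose <- metrics |>
      dplyr::group_by(.data$strain, .data$condition) |>
      dplyr::filter(dplyr::n_distinct(.data$conc_mM) >= 4) |>
      dplyr::ungroup()
    lc50 <- NULL
    if (nrow(dose) > 0) {
      first <- dose |>
        dplyr::distinct(.data$strain, .data$condition) |>
        dplyr::slice(1)
      sub <- dose |>
        dplyr::filter(.data$strain == first$strain,
                      .data$condition == first$condition)
      lc50 <- estimate_lc50(sub$conc_mM, sub[[metric_col]])
      .write_csv(lc50$dose, out_dir, "dose_response.csv")
    }
    comparisons <- NULL
    ref <- block$reference_strain %||% "BY4741"
    others <- setdiff(unique(metrics$strain), ref)
    if (length(others) > 0 && ref %in% metrics$strain) {
      comparisons <- dplyr::bind_rows(lapply(others, function(s) {
        dplyr::bind_rows(lapply(unique(metrics$conc_mM), function(cc) {
          mm <- dplyr::filter(metrics, .data$strain == s,
                              .data$conc_mM == cc)
          rr <- dplyr::filter(metrics, .data$strain == ref,
                              .data$conc_mM == cc)
          cmp <- compare_strains(mm, rr, alpha = alpha)
          cmp$strain <- s
          cmp$conc_mM <- cc
          cmp
        }))
      }))
      .write_csv(comparisons, out_dir, "strain_comparisons.csv")
    }
    list(metrics = metrics, lc50 = lc50, comparisons = comparisons)
  })

  provenance <- list(
    config_hash = .config_hash(cfg),
    seed = cfg$seed,
    alpha = alpha,
    package_version = as.character(utils::packageVersion("deorphanr"))
  )
  out <- structure(list(provenance = provenance, status = status,
                        results = report),
                   class = "deorphan_report")
  if (!is.null(out_dir)) {
    payload <- list(provenance = provenance, status = status)
    if (!is.null(report$screen)) payload$screen <- report$screen$summary$overall
    if (!is.null(report$uptake)) payload$uptake_calls <- report$uptake$calls
    if (!is.null(report$mode)) payload$mode_calls <- report$mode
    jsonlite::write_json(payload, file.path(out_dir, "deorphan_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(out, "exit_code") <- if (any(unlist(status) == "failed")) 1L else 0L
  out
}

#' @export
print.deorphan_report <- function(x, ...) {
  cat("Deorphanization report\n")
  cat("  config hash:", x$provenance$config_hash, "\n")
  cat("  seed:", x$provenance$seed, " alpha:", x$provenance$alpha, "\n")
  for (s in names(x$status)) cat(sprintf("  %-9s %s\n", s, x$status[[s]]))
  invisible(x)
}
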