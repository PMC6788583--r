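#' Write a trace to CSV with a sidecar metadata file
#'
#' The trace itself goes to `path` as a two-column CSV with header
#' `time_s,conc_ppm`; the event markers and scenario metadata go to a plain
#' YAML sidecar next to it (same path with extension `.yml`), with keys
#' `scenario_id`, `replicate`, `t_start_s`, `t_end_s`, `target_ach`,
#' `trace_kind`. The same schema is used for user-supplied instrument data.
#'
#' @param trace A [concentration_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "conc_trace"))
  df <- data.frame(time_s = trace$times_s, conc_ppm = trace$conc_ppm)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(scenario_id = trace$scenario_id,
               replicate = trace$replicate,
               t_start_s = trace$event$t_start_s,
               t_end_s = trace$event$t_end_s,
               target_ach = trace$target_ach,
               trace_kind = trace$trace_kind)
  yaml::write_yaml(meta, .sidecar_path(path))
  invisible(path)
}

.sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), ".yml")
}

#' Read a trace CSV and its sidecar metadata
#'
#' Validates as it reads: the header must be `time_s,conc_ppm`, every row
#' numeric, times strictly increasing on a near-constant grid, and the
#' sidecar must supply all required metadata keys. Malformed rows are
#' reported with their line numbers.
#'
#' @param path Path to a trace CSV written by [write_trace()] (or following
#'   the same schema).
#' @return A [concentration_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta_path <- .sidecar_path(path)
  if (!file.exists(meta_path)) {
    stop("missing sidecar metadata file: ", meta_path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(raw), c("time_s", "conc_ppm"))) {
    stop("expected CSV header `time_s,conc_ppm` in ", path, call. = FALSE)
  }
  times <- suppressWarnings(as.numeric(raw$time_s))
  conc <- suppressWarnings(as.numeric(raw$conc_ppm))
  bad <- which(!is.finite(times) | !is.finite(conc))
  if (length(bad)) {
    stop(sprintf("non-numeric trace values at line(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path), call. = FALSE)
  }
  non_mono <- which(diff(times) <= 0)
  if (length(non_mono)) {
    stop(sprintf("non-increasing time at line %d of %s",
                 non_mono[1L] + 2L, path), call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  need <- c("t_start_s", "t_end_s", "target_ach", "trace_kind")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys)) {
    stop("sidecar ", meta_path, " missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  concentration_trace(
    times, conc, transfer_event(meta$t_start_s, meta$t_end_s),
    target_ach = meta$target_ach, trace_kind = meta$trace_kind,
    scenario_id = meta$scenario_id %||% NA_integer_,
    replicate = meta$replicate %||% NA_integer_)
}

#' Configuration for an end-to-end pipeline run
#'
#' @param input_dir Directory of trace CSVs (with sidecars) to analyse; if
#'   `NULL`, traces are simulated from the scenario presets.
#' @param scenario_ids Scenarios to simulate when `input_dir` is `NULL`.
#' @param n_replicates Simulated replicates per scenario.
#' @param baseline_transfer Baseline scenario id for transfer traces.
#' @param baseline_drain Baseline scenario id for drain/flush traces.
#' @param ach_tol Air-exchange admissibility tolerance for the decay fit,
#'   1/h; must be positive.
#' @param seed Base seed for simulation.
#' @param out_dir Directory the report artifacts are written to.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, scenario_ids = 1:9,
                       n_replicates = 3L, baseline_transfer = 1L,
                       baseline_drain = 8L, ach_tol = 1, seed = 1L,
                       out_dir = tempfile("rmmeff_run_")) {
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  if (!is.numeric(ach_tol) || ach_tol <= 0) {
    stop("`ach_tol` must be positive", call. = FALSE)
  }
  structure(list(input_dir = input_dir, scenario_ids = scenario_ids,
                 n_replicates = as.integer(n_replicates),
                 baseline_transfer = as.integer(baseline_transfer),
                 baseline_drain = as.integer(baseline_drain),
                 ach_tol = ach_tol, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline: traces to effectiveness report
#'
#' Ingests (or simulates) concentration traces, evaluates each replicate
#' (decay-fit extrapolation for transfer traces, lid-open mean for
#' drain/flush traces), summarises replicates per scenario, computes the
#' reduction statistics against the configured baselines, and writes the
#' report artifacts to `config$out_dir`: `fits.csv`, `summaries.csv`,
#' `report.csv`, `report.txt` and `run.log`. The log records, per trace,
#' the background estimate, the selected window, the implied air-exchange
#' rate, and any no-observable-emission or unfittable flags. A stage error
#' on one trace is logged and the pipeline continues with the rest. The run
#' is deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `fits`, `summaries`, `reductions`,
#'   `report` and `log_lines`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  log_add <- function(...) {
    log_lines[[length(log_lines) + 1L]] <<- sprintf(...)
  }

  if (is.null(config$input_dir)) {
    log_add("INFO simulating %d replicate(s) of scenarios %s with seed %d",
            config$n_replicates,
            paste(config$scenario_ids, collapse = ","), config$seed)
    traces <- generate_scenario_set(config$scenario_ids,
                                    config$n_replicates,
                                    noise_model(seed = config$seed))
  } else {
    files <- sort(list.files(config$input_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (!length(files)) stop("no trace CSVs in ", config$input_dir,
                             call. = FALSE)
    traces <- lapply(files, read_trace)
    log_add("INFO read %d trace(s) from %s", length(traces),
            config$input_dir)
  }

  fits <- list()
  for (tr in traces) {
    id <- sprintf("scenario %s rep %s", tr$scenario_id, tr$replicate)
    rec <- data.frame(scenario_id = tr$scenario_id, replicate = tr$replicate,
                      trace_kind = tr$trace_kind, value_ppm = NA_real_,
                      ach_fit = NA_real_, r_squared = NA_real_,
                      n_points = NA_integer_, flag = "ok",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      if (tr$trace_kind == "transfer") {
        fit <- compute_eec(tr, ach_tol = config$ach_tol)
        if (fit$noe) {
          rec$flag <- "noe"
          log_add("INFO %s: no observable emission (background %.2f ppm)",
                  id, fit$background_ppm)
        } else {
          rec$value_ppm <- fit$eec_ppm
          rec$ach_fit <- fit$ach_fit
          rec$r_squared <- fit$r_squared
          rec$n_points <- fit$n_points
          log_add(paste0("INFO %s: background %.2f ppm, window %d-%d, ",
                         "EEC %.2f ppm, ACH %.2f /h, R2 %.4f"),
                  id, fit$background_ppm, fit$window[["start"]],
                  fit$window[["end"]], fit$eec_ppm, fit$ach_fit,
                  fit$r_squared)
        }
      } else {
        rec$value_ppm <- mean_concentration_between(tr)
        log_add("INFO %s: lid-open mean %.2f ppm", id, rec$value_ppm)
      }
      rec
    }, rmmeff_unfittable = function(e) {
      rec$flag <- "unfittable"
      log_add("WARN %s: %s", id, conditionMessage(e))
      rec
    }, error = function(e) {
      rec$flag <- "error"
      log_add("WARN %s: %s", id, conditionMessage(e))
      rec
    })
    fits[[length(fits) + 1L]] <- res
  }
  fits <- tibble::as_tibble(do.call(rbind, fits))

  ok <- fits[fits$flag == "ok" & !is.na(fits$value_ppm), ]
  summaries <- list()
  for (sid in sort(unique(ok$scenario_id))) {
    v <- ok$value_ppm[ok$scenario_id == sid]
    if (length(v) >= 2L && mean(v) > 0) {
      summaries[[as.character(sid)]] <- summarize_scenario(v, sid)
    } else {
      log_add("WARN scenario %s: %d usable replicate(s), not summarised",
              sid, length(v))
    }
  }
  noe_ids <- sort(unique(fits$scenario_id[fits$flag == "noe"]))
  noe_ids <- setdiff(noe_ids, ok$scenario_id)

  baseline_for <- function(s) {
    kind <- fits$trace_kind[match(s$scenario_id, fits$scenario_id)]
    bid <- if (identical(kind, "drain_flush")) config$baseline_drain else
      config$baseline_transfer
    summaries[[as.character(bid)]]
  }
  reductions <- list()
  baselines <- list()
  for (s in summaries) {
    if (s$scenario_id %in% c(config$baseline_transfer,
                             config$baseline_drain)) {
      baselines[[length(baselines) + 1L]] <- s
      next
    }
    b <- baseline_for(s)
    if (is.null(b)) {
      log_add("WARN scenario %d: baseline summary unavailable, skipped",
              s$scenario_id)
      next
    }
    red <- emission_reduction(s, b)
    reductions[[length(reductions) + 1L]] <- red
    log_add("INFO scenario %d vs %d: min %.1f%%, optimal %.1f%%, mean %.1f%%",
            red$scenario_id, red$baseline_id, red$min_percent,
            red$max_percent, red$mean_percent)
  }

  report <- build_comparison_report(reductions, baselines = baselines,
                                    noe_ids = noe_ids)
  for (i in which(report$below_expected)) {
    log_add("WARN scenario %d: mean reduction %.1f%% below expected low bound %.0f%%",
            report$scenario_id[i], report$mean_reduction_percent[i],
            report$expected_low_percent[i])
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fits, file.path(config$out_dir, "fits.csv"),
                   row.names = FALSE)
  sum_df <- do.call(rbind, lapply(summaries, as.data.frame))
  if (is.null(sum_df)) {
    sum_df <- data.frame(scenario_id = integer(), n = integer(),
                         mean_ppm = numeric(), min_ppm = numeric(),
                         max_ppm = numeric(), cv_percent = numeric())
  }
  utils::write.csv(sum_df, file.path(config$out_dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass2_df(report)),
                   file.path(config$out_dir, "report.csv"),
                   row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(config$out_dir, "report.txt"))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(list(fits = fits, summaries = summaries,
                 reductions = reductions, report = report,
                 log_lines = log_lines))
}

# strip the rmm_report class so write.csv sees a plain data frame
unclass2_df <- function(x) {
  class(x) <- setdiff(class(x), "rmm_report")
  x
}
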