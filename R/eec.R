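#' Estimate the ambient background concentration of a trace
#'
#' The background is the median concentration over the pre-event window
#' `[0, t_start_s)`. The median is used because short positive spikes
#' (personnel movement, vapour pockets) must not inflate the baseline.
#'
#' @param trace A [concentration_trace()] with at least 10 samples before
#'   the event starts.
#' @return Background concentration in ppm.
#' @export
estimate_background <- function(trace) {
  stopifnot(inherits(trace, "conc_trace"))
  pre <- trace$conc_ppm[trace$times_s < trace$event$t_start_s]
  if (length(pre) < 10L) {
    stop(sprintf(paste0("only %d pre-event samples (need >= 10) - supply ",
                        "`background_ppm` manually"), length(pre)),
         call. = FALSE)
  }
  stats::median(pre)
}

# Positivity floor below which background-subtracted points are excluded
# from fitting: the log transform blows up as the signal approaches the
# background.
.positivity_floor <- function(excess) {
  max(0.1, 0.01 * max(excess))
}

# Log-linear OLS of log(excess) on time-in-minutes, via explicit sums so the
# window search can evaluate thousands of candidate windows cheaply.
# Returns c(intercept, slope, r_squared).
.ols_log <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y); syy <- sum(y * y)
  den <- n * sxx - sx * sx
  slope <- (n * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / n
  sst <- syy - sy * sy / n
  sse <- sst - slope * (sxy - sx * sy / n)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  c(intercept = intercept, slope = slope, r_squared = r2)
}

#' Select the post-event window for the decay fit
#'
#' The choice of the trendline points is constrained by the known room air
#' exchange: only windows whose fitted decay constant, converted to an air
#' exchange rate (60 k), lies within `ach_tol` of the trace's `target_ach`
#' are admissible. Candidate windows are enumerated on the sampling grid
#' (start offsets 0..`max_start_offset` samples after the event end, lengths
#' from `min_points` up to every contiguous point above the positivity
#' floor); among admissible candidates the longest wins, ties broken by the
#' highest log-space R-squared.
#'
#' @param trace A [concentration_trace()] with at least 10 post-event
#'   samples and `target_ach > 0`.
#' @param background_ppm Background to subtract before fitting.
#' @param ach_tol Admissibility tolerance on the implied air-exchange rate,
#'   1/h (default 1, matching the "11 +/- 1" operating band of a ventilated
#'   room).
#' @param max_start_offset Latest allowed window start, in samples after the
#'   first post-event sample.
#' @param min_points Minimum window length in samples.
#' @param min_r_squared Minimum log-space R-squared for a candidate to be
#'   admissible (default 0.9). Short noisy windows can match any decay
#'   constant by chance; requiring the window to actually look log-linear
#'   suppresses such spurious matches, so a trace whose true decay
#'   contradicts `target_ach` is reported unfittable rather than fitted on
#'   a lucky segment.
#' @return A list with integer indices `start`, `end` into the trace, the
#'   floor used, and the candidate count; class `decay_window`.
#' @export
select_decay_window <- function(trace, background_ppm, ach_tol = 1,
                                max_start_offset = 10L, min_points = 5L,
                                min_r_squared = 0.9) {
  stopifnot(inherits(trace, "conc_trace"))
  if (trace$target_ach <= 0) {
    stop("`target_ach` must be positive for window selection", call. = FALSE)
  }
  t_end <- trace$event$t_end_s
  post <- which(trace$times_s >= t_end)
  if (length(post) < 10L) {
    stop("need at least 10 post-event samples", call. = FALSE)
  }
  excess <- trace$conc_ppm[post] - background_ppm
  floor_ppm <- .positivity_floor(excess)
  adm <- excess >= floor_ppm
  x_all <- (trace$times_s[post] - t_end) / 60  # minutes from transfer end
  y_all <- ifelse(adm, log(pmax(excess, floor_ppm * 1e-12)), NA_real_)

  best <- NULL          # admissible: longest, then best r2
  closest <- NULL       # diagnostics if nothing admissible
  target <- trace$target_ach
  for (off in 0:max_start_offset) {
    s <- 1L + off
    if (s > length(post) || !adm[s]) next
    run_end <- s
    while (run_end < length(post) && adm[run_end + 1L]) run_end <- run_end + 1L
    if (run_end - s + 1L < min_points) next
    for (e in seq(s + min_points - 1L, run_end)) {
      fit <- .ols_log(x_all[s:e], y_all[s:e])
      ach_fit <- -fit[["slope"]] * 60
      cand <- list(start = s, end = e, n = e - s + 1L,
                   ach_fit = ach_fit, r_squared = fit[["r_squared"]])
      if (abs(ach_fit - target) <= ach_tol &&
          fit[["r_squared"]] >= min_r_squared) {
        if (is.null(best) || cand$n > best$n ||
            (cand$n == best$n && cand$r_squared > best$r_squared)) {
          best <- cand
        }
      } else if (is.null(closest) ||
                 abs(ach_fit - target) < abs(closest$ach_fit - target)) {
        closest <- cand
      }
    }
  }
  if (is.null(best)) {
    msg <- if (is.null(closest)) {
      "no candidate window had enough points above the positivity floor"
    } else {
      sprintf(paste0("no window matches the air-exchange constraint ",
                     "(target %.2f +/- %.2f /h; best achieved %.2f /h)"),
              target, ach_tol, closest$ach_fit)
    }
    stop(structure(class = c("rmmeff_unfittable", "error", "condition"),
                   list(message = paste0("unfittable trace: ", msg),
                        call = NULL, best_ach_fit = closest$ach_fit %||% NA)))
  }
  structure(list(start = post[best$start], end = post[best$end],
                 floor_ppm = floor_ppm, ach_fit = best$ach_fit,
                 r_squared = best$r_squared),
            class = "decay_window")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the exponential decay and extrapolate to the end of transfer
#'
#' Ordinary least squares of `log(conc - background)` against time in
#' minutes from the event end fits the decay law `y = y0 exp(-k t)`. The
#' intercept exponentiated is the extrapolated concentration at the moment
#' the transfer was completed; `60 k` is the implied room air-exchange rate
#' per hour.
#'
#' @param trace A [concentration_trace()].
#' @param window A window from [select_decay_window()], or a list with
#'   integer `start` and `end` indices into the trace (at least 3 points,
#'   all above background).
#' @param background_ppm Background subtracted before the log transform.
#' @return An object of class `decay_fit` with fields `eec_ppm`,
#'   `k_per_min`, `ach_fit`, `window`, `background_ppm`, `r_squared`,
#'   `n_points`, `noe`.
#' @export
fit_decay <- function(trace, window, background_ppm) {
  stopifnot(inherits(trace, "conc_trace"))
  idx <- seq(window$start, window$end)
  if (length(idx) < 3L) stop("window must contain >= 3 points", call. = FALSE)
  excess <- trace$conc_ppm[idx] - background_ppm
  if (any(excess <= 0)) {
    stop("window contains non-positive background-subtracted values",
         call. = FALSE)
  }
  x <- (trace$times_s[idx] - trace$event$t_end_s) / 60
  fit <- stats::lm.fit(cbind(1, x), log(excess))
  intercept <- fit$coefficients[[1L]]
  slope <- fit$coefficients[[2L]]
  y <- log(excess)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  structure(
    list(eec_ppm = exp(intercept), k_per_min = -slope,
         ach_fit = 60 * -slope, window = c(start = window$start,
                                           end = window$end),
         background_ppm = background_ppm, r_squared = r2,
         n_points = length(idx), noe = FALSE,
         scenario_id = trace$scenario_id, replicate = trace$replicate),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (isTRUE(x$noe)) {
    cat("<decay_fit> no observable emission above background\n")
  } else {
    cat(sprintf(
      "<decay_fit> EEC %.1f ppm, ACH %.2f /h (k = %.4f /min), R2 %.4f, %d pts\n",
      x$eec_ppm, x$ach_fit, x$k_per_min, x$r_squared, x$n_points))
  }
  invisible(x)
}

#' Extrapolated concentration for a transfer trace
#'
#' Single public entry point for transfer traces: estimates the background,
#' selects the air-exchange-constrained decay window and fits the
#' exponential. If no post-event sample rises above the background by more
#' than three pre-event standard deviations, the trace carries no observable
#' emission and the extrapolated concentration is reported as not
#' determinable (`noe = TRUE`, `eec_ppm = NA`).
#'
#' @param trace A [concentration_trace()] of kind `"transfer"`.
#' @param ach_tol Air-exchange admissibility tolerance, 1/h.
#' @param background_ppm Optional externally supplied background; by default
#'   estimated from the pre-event window.
#' @return A `decay_fit`; see [fit_decay()].
#' @examples
#' tr <- simulate_scenario(1, no_noise())
#' compute_eec(tr)
#' @export
compute_eec <- function(trace, ach_tol = 1, background_ppm = NULL) {
  stopifnot(inherits(trace, "conc_trace"))
  if (trace$trace_kind != "transfer") {
    stop("compute_eec expects a transfer trace; use ",
         "mean_concentration_between() for drain/flush traces",
         call. = FALSE)
  }
  bg <- background_ppm %||% estimate_background(trace)
  pre <- trace$conc_ppm[trace$times_s < trace$event$t_start_s]
  pre_sd <- if (length(pre) >= 2L) stats::sd(pre) else 0
  post <- trace$conc_ppm[trace$times_s >= trace$event$t_end_s]
  if (!any(post > bg + 3 * pre_sd)) {
    return(structure(
      list(eec_ppm = NA_real_, k_per_min = NA_real_, ach_fit = NA_real_,
           window = c(start = NA_integer_, end = NA_integer_),
           background_ppm = bg, r_squared = NA_real_, n_points = 0L,
           noe = TRUE, scenario_id = trace$scenario_id,
           replicate = trace$replicate),
      class = "decay_fit"))
  }
  window <- select_decay_window(trace, bg, ach_tol = ach_tol)
  fit_decay(trace, window, bg)
}

#' Nonlinear least-squares refinement of a decay fit
#'
#' Refits `y = y0 exp(-k t)` to the background-subtracted concentrations of
#' the already-selected window by nonlinear least squares in linear space,
#' started at the log-linear estimates. Log-linear OLS defines the reference
#' numbers of this package (it is the transparent, spreadsheet-reproducible
#' estimator); the refinement weights large concentrations more heavily and
#' is offered for sensitivity analysis. `r_squared` of the result is
#' computed in linear space.
#'
#' @param trace The [concentration_trace()] the fit came from.
#' @param fit A `decay_fit` from [fit_decay()] or [compute_eec()] (not a
#'   no-observable-emission result).
#' @return A `decay_fit` with refined `eec_ppm`, `k_per_min`, `ach_fit`.
#' @export
refine_decay_fit <- function(trace, fit) {
  stopifnot(inherits(trace, "conc_trace"), inherits(fit, "decay_fit"))
  if (isTRUE(fit$noe)) {
    stop("cannot refine a no-observable-emission result", call. = FALSE)
  }
  idx <- seq(fit$window[["start"]], fit$window[["end"]])
  x <- (trace$times_s[idx] - trace$event$t_end_s) / 60
  y <- trace$conc_ppm[idx] - fit$background_ppm
  # Levenberg-Marquardt: robust on near-zero-residual (clean) windows where
  # plain Gauss-Newton stalls
  m <- minpack.lm::nlsLM(y ~ y0 * exp(-k * x),
                         start = list(y0 = fit$eec_ppm, k = fit$k_per_min))
  co <- stats::coef(m)
  res <- y - co[["y0"]] * exp(-co[["k"]] * x)
  sst <- sum((y - mean(y))^2)
  out <- fit
  out$eec_ppm <- co[["y0"]]
  out$k_per_min <- co[["k"]]
  out$ach_fit <- 60 * co[["k"]]
  out$r_squared <- if (sst > 0) 1 - sum(res^2) / sst else 1
  out
}

#' Mean concentration between the event markers
#'
#' Evaluation rule for drain/flush traces, whose emission is too small and
#' short-lived for a decay fit: the arithmetic mean of all samples between
#' lid opening and lid closing, without background subtraction.
#'
#' @param trace A [concentration_trace()] of kind `"drain_flush"`.
#' @return Mean concentration in ppm.
#' @export
mean_concentration_between <- function(trace) {
  stopifnot(inherits(trace, "conc_trace"))
  if (trace$trace_kind != "drain_flush") {
    stop("mean_concentration_between expects a drain_flush trace",
         call. = FALSE)
  }
  sel <- trace$times_s >= trace$event$t_start_s &
    trace$times_s <= trace$event$t_end_s
  if (!any(sel)) stop("no samples between the event markers", call. = FALSE)
  mean(trace$conc_ppm[sel])
}

#' Summarise replicate emission values for one scenario
#'
#' Collects the per-replicate emission values of a scenario (extrapolated
#' concentrations for transfer scenarios, lid-open means for drain/flush)
#' into the summary the effectiveness formulas consume: arithmetic mean,
#' extrema, and the coefficient of variation computed with the sample (n-1)
#' standard deviation.
#'
#' @param values_ppm Replicate values, all finite and non-negative; at least
#'   two (the study design used a minimum of three repetitions).
#' @param scenario_id Identifier carried into reports.
#' @return An object of class `scenario_summary` with fields `scenario_id`,
#'   `values_ppm`, `mean_ppm`, `min_ppm`, `max_ppm`, `cv_percent`, `n`.
#' @examples
#' summarize_scenario(c(454, 424, 410, 430, 553), scenario_id = 1)
#' @export
summarize_scenario <- function(values_ppm, scenario_id = NA_integer_) {
  values_ppm <- as.numeric(values_ppm)
  if (length(values_ppm) < 2L) {
    stop("need at least 2 replicate values", call. = FALSE)
  }
  if (!all(is.finite(values_ppm)) || any(values_ppm < 0)) {
    stop("replicate values must be finite and non-negative", call. = FALSE)
  }
  m <- mean(values_ppm)
  if (m == 0) {
    stop("mean of replicates is zero; coefficient of variation undefined",
         call. = FALSE)
  }
  structure(
    list(scenario_id = as.integer(scenario_id), values_ppm = values_ppm,
         mean_ppm = m, min_ppm = min(values_ppm), max_ppm = max(values_ppm),
         cv_percent = 100 * stats::sd(values_ppm) / m,
         n = length(values_ppm)),
    class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf(
    "<scenario_summary> #%s: n = %d, mean %.1f ppm (%.0f-%.0f), CV %.1f%%\n",
    ifelse(is.na(x$scenario_id), "?", x$scenario_id), x$n, x$mean_ppm,
    x$min_ppm, x$max_ppm, x$cv_percent))
  cat("  values:", paste(signif(x$values_ppm, 4), collapse = ", "), "ppm\n")
  invisible(x)
}

#' @export
as.data.frame.scenario_summary <- function(x, ...) {
  data.frame(scenario_id = x$scenario_id, n = x$n, mean_ppm = x$mean_ppm,
             min_ppm = x$min_ppm, max_ppm = x$max_ppm,
             cv_percent = x$cv_percent)
}
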