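#' Construct a concentration-time trace
#'
#' The basic unit of raw input: a regularly sampled airborne concentration
#' time series (IR-probe style) together with the event markers and scenario
#' metadata the downstream fit needs. For transfer traces the event marks the
#' start and end of the solvent transfer (the fit's time origin is the end);
#' for drain/flush traces it marks lid opening and closing.
#'
#' @param times_s Sample times in seconds, strictly increasing, on a constant
#'   grid (interval may vary by at most 1%).
#' @param conc_ppm Concentrations in ppm; finite and non-negative.
#' @param event A [transfer_event()].
#' @param target_ach Expected room air-exchange rate in 1/h (about 1 with
#'   room ventilation off, 11 +/- 1 with ventilation on).
#' @param trace_kind `"transfer"` (decay-fit evaluation) or `"drain_flush"`
#'   (mean-concentration evaluation).
#' @param scenario_id,replicate Optional identifiers carried into reports.
#' @return An object of class `conc_trace`.
#' @seealso [simulate_trace()], [compute_eec()], [mean_concentration_between()]
#' @export
concentration_trace <- function(times_s, conc_ppm, event, target_ach,
                                trace_kind = c("transfer", "drain_flush"),
                                scenario_id = NA_integer_,
                                replicate = NA_integer_) {
  trace_kind <- match.arg(trace_kind)
  times_s <- as.numeric(times_s)
  conc_ppm <- as.numeric(conc_ppm)
  if (length(times_s) != length(conc_ppm)) {
    stop("`times_s` and `conc_ppm` must have the same length", call. = FALSE)
  }
  if (length(times_s) < 2L) {
    stop("a trace needs at least two samples", call. = FALSE)
  }
  if (!all(is.finite(times_s)) || !all(is.finite(conc_ppm))) {
    stop("times and concentrations must be finite", call. = FALSE)
  }
  dt <- diff(times_s)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop(sprintf("sample times must be strictly increasing (sample %d)", bad),
         call. = FALSE)
  }
  if (diff(range(dt)) > 0.01 * stats::median(dt)) {
    stop("sampling interval must be constant to within 1%", call. = FALSE)
  }
  if (any(conc_ppm < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  stopifnot(inherits(event, "transfer_event"))
  if (!is.numeric(target_ach) || !is.finite(target_ach) || target_ach < 0) {
    stop("`target_ach` must be a finite non-negative number", call. = FALSE)
  }
  structure(
    list(times_s = times_s, conc_ppm = conc_ppm, event = event,
         target_ach = target_ach, trace_kind = trace_kind,
         scenario_id = as.integer(scenario_id),
         replicate = as.integer(replicate)),
    class = "conc_trace"
  )
}

#' Source event markers for a trace
#'
#' For transfer traces `t_start_s`/`t_end_s` are the opening and closing of
#' the transfer (spigot or pump); for drain/flush traces they are lid opening
#' and closing. Time zero of the decay fit is `t_end_s`.
#'
#' @param t_start_s,t_end_s Event times in seconds, `0 <= t_start_s < t_end_s`.
#' @return An object of class `transfer_event`.
#' @export
transfer_event <- function(t_start_s, t_end_s) {
  if (!is.finite(t_start_s) || !is.finite(t_end_s)) {
    stop("event times must be finite", call. = FALSE)
  }
  if (t_start_s < 0 || t_start_s >= t_end_s) {
    stop("need 0 <= t_start_s < t_end_s", call. = FALSE)
  }
  structure(list(t_start_s = as.numeric(t_start_s),
                 t_end_s = as.numeric(t_end_s)),
            class = "transfer_event")
}

#' @export
print.conc_trace <- function(x, ...) {
  cat(sprintf(
    "<conc_trace> %s scenario %s rep %s: %d samples @ %.0f s, %.0f-%.0f s\n",
    x$trace_kind,
    ifelse(is.na(x$scenario_id), "?", x$scenario_id),
    ifelse(is.na(x$replicate), "?", x$replicate),
    length(x$times_s), stats::median(diff(x$times_s)),
    min(x$times_s), max(x$times_s)))
  cat(sprintf("  event %.0f-%.0f s, target ACH %.1f /h, conc %.2f-%.2f ppm\n",
              x$event$t_start_s, x$event$t_end_s, x$target_ach,
              min(x$conc_ppm), max(x$conc_ppm)))
  invisible(x)
}

#' @export
as.data.frame.conc_trace <- function(x, ...) {
  data.frame(time_s = x$times_s, conc_ppm = x$conc_ppm)
}
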