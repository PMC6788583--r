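#' Physical parameters of the simulated room and transfer
#'
#' Describes a single well-mixed (one-box) room in which a solvent transfer
#' emits vapour at a constant rate while the source is on, and ventilation
#' removes it as a first-order loss towards the ambient background:
#' \deqn{dC/dt = S \cdot 1_{[t_{start}, t_{end}]}(t) - \lambda (C - B)}
#' with \eqn{\lambda} the air-exchange rate and \eqn{B} the background.
#' The source term is expressed directly as a concentration-equivalent rate
#' (ppm/min delivered to the mixed volume), deliberately abstracting away
#' evaporation physics.
#'
#' @param volume Room volume in m^3 (default 45, a small laboratory room).
#'   Carried as metadata; the concentration-equivalent source term already
#'   absorbs the volume.
#' @param ach Air-exchange rate in 1/h (about 1 with room ventilation off,
#'   11 with ventilation and fume hood on).
#' @param background_ppm Steady ambient concentration in ppm.
#' @param source_rate Emission rate during the source-on phase, ppm/min
#'   delivered to the well-mixed volume.
#' @param sampling_interval_s Seconds between samples (default 20, typical
#'   portable IR spectrometer logging).
#' @param duration_s Total simulated length in seconds.
#' @return An object of class `room_params`.
#' @export
room_params <- function(volume = 45, ach = 1, background_ppm = 0.5,
                        source_rate = 0, sampling_interval_s = 20,
                        duration_s = 3600) {
  vals <- c(volume = volume, ach = ach, background_ppm = background_ppm,
            source_rate = source_rate,
            sampling_interval_s = sampling_interval_s,
            duration_s = duration_s)
  if (!all(is.finite(vals))) {
    stop("all room parameters must be finite", call. = FALSE)
  }
  if (volume <= 0 || sampling_interval_s <= 0 || duration_s <= 0) {
    stop("volume, sampling_interval_s and duration_s must be positive",
         call. = FALSE)
  }
  if (ach < 0 || background_ppm < 0 || source_rate < 0) {
    stop("ach, background_ppm and source_rate must be non-negative",
         call. = FALSE)
  }
  structure(as.list(vals), class = "room_params")
}

#' Measurement-noise model for simulated traces
#'
#' Two noise components ride on the clean well-mixed-room signal:
#' multiplicative lognormal sample noise, and occasional transient positive
#' spikes emulating vapour pockets stirred up by personnel movement. A
#' spike's mean height scales with the current clean excess concentration
#' (no pockets when no vapour is present) and its probe signature washes
#' out over a short transit time (about 30 s, or faster if the room itself
#' turns over faster), giving the short peaks seen in real recordings.
#'
#' @param multiplicative_sd Standard deviation of the lognormal noise on the
#'   log scale (relative noise; default 0.05).
#' @param spike_rate_per_min Expected spike frequency (default 0.2/min).
#' @param spike_magnitude Mean spike height as a fraction of the clean
#'   excess-over-background concentration at the spike time (default 0.1).
#' @param seed Integer seed; the same seed always yields the same trace.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sd = 0.05, spike_rate_per_min = 0.2,
                        spike_magnitude = 0.1, seed = 1L) {
  vals <- c(multiplicative_sd, spike_rate_per_min, spike_magnitude)
  if (!all(is.finite(vals)) || any(vals < 0)) {
    stop("noise rates and sds must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(seed) || !is.finite(seed)) {
    stop("`seed` must be a finite integer", call. = FALSE)
  }
  structure(list(multiplicative_sd = multiplicative_sd,
                 spike_rate_per_min = spike_rate_per_min,
                 spike_magnitude = spike_magnitude,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' A noise model that leaves the clean signal untouched
#' @param seed Seed carried along for interface compatibility.
#' @return A `noise_model` with all noise components zero.
#' @export
no_noise <- function(seed = 1L) {
  noise_model(multiplicative_sd = 0, spike_rate_per_min = 0,
              spike_magnitude = 0, seed = seed)
}

# Closed-form solution of the one-box model on arbitrary times.
# Piecewise: flat background before the source, saturating rise during the
# source-on phase, pure exponential relaxation to background afterwards.
.clean_concentration <- function(t, params, event) {
  lam <- params$ach / 3600                  # per second
  s <- params$source_rate / 60              # ppm per second
  b <- params$background_ppm
  rise <- function(dt) {
    if (lam > 0) (s / lam) * (1 - exp(-lam * dt)) else s * dt
  }
  excess_end <- rise(event$t_end_s - event$t_start_s)
  out <- rep(b, length(t))
  on <- t >= event$t_start_s & t <= event$t_end_s
  post <- t > event$t_end_s
  out[on] <- b + rise(t[on] - event$t_start_s)
  out[post] <- b + excess_end * exp(-lam * (t[post] - event$t_end_s))
  out
}

#' Simulate an IR-probe-like concentration trace
#'
#' Samples the closed-form solution of the well-mixed-room balance
#' `dC/dt = source - lambda * (C - background)` on the sampling grid starting
#' at t = 0, adds decaying movement spikes, then applies multiplicative
#' lognormal noise. Deterministic for a fixed noise seed.
#'
#' @param params A [room_params()].
#' @param event A [transfer_event()] lying inside the simulated duration.
#' @param noise A [noise_model()]; use [no_noise()] for the clean signal.
#' @param trace_kind,scenario_id,replicate Metadata stored on the trace.
#' @return A [concentration_trace()] with `target_ach = params$ach`.
#' @examples
#' tr <- simulate_trace(room_params(ach = 11, source_rate = 120,
#'                                  duration_s = 1800),
#'                      transfer_event(240, 480), no_noise())
#' head(as.data.frame(tr))
#' @export
simulate_trace <- function(params, event, noise = noise_model(),
                           trace_kind = "transfer",
                           scenario_id = NA_integer_,
                           replicate = NA_integer_) {
  stopifnot(inherits(params, "room_params"), inherits(event, "transfer_event"))
  if (!inherits(noise, "noise_model")) stop("`noise` must be a noise_model")
  if (event$t_end_s >= params$duration_s) {
    stop("simulated duration too short to contain the source event",
         call. = FALSE)
  }
  times <- seq(0, params$duration_s, by = params$sampling_interval_s)
  clean <- .clean_concentration(times, params, event)
  lam <- params$ach / 3600
  b <- params$background_ppm

  conc <- withr::with_seed(noise$seed, {
    total <- clean
    # vapour-pocket spikes: Poisson arrivals, exponential heights scaled by
    # the clean excess at arrival. A pocket registers at the probe only
    # while it drifts past, so its trace signature washes out on a short
    # transit time scale (or the room time scale if that is faster); its
    # mixed-in vapour is negligible against the room inventory.
    n_spk <- stats::rpois(1L, noise$spike_rate_per_min *
                            params$duration_s / 60)
    if (n_spk > 0 && noise$spike_magnitude > 0) {
      t_spk <- sort(stats::runif(n_spk, 0, params$duration_s))
      excess_at <- pmax(.clean_concentration(t_spk, params, event) - b, 0)
      h <- stats::rexp(n_spk, rate = 1) * noise$spike_magnitude * excess_at
      lam_spk <- max(lam, 1 / 30)  # per second; ~30 s pocket transit
      for (i in seq_len(n_spk)) {
        after <- times >= t_spk[i]
        total[after] <- total[after] +
          h[i] * exp(-lam_spk * (times[after] - t_spk[i]))
      }
    }
    if (noise$multiplicative_sd > 0) {
      total <- total * stats::rlnorm(length(total), meanlog = 0,
                                     sdlog = noise$multiplicative_sd)
    }
    total
  })

  concentration_trace(times, conc, event, target_ach = params$ach,
                      trace_kind = trace_kind, scenario_id = scenario_id,
                      replicate = replicate)
}

#' Source rate that produces a given end-of-transfer excess concentration
#'
#' Inverts the rise phase of the one-box model: returns the constant
#' concentration-equivalent source rate (ppm/min) for which the excess over
#' background at the end of a source-on phase of `duration_min` minutes
#' equals `excess_ppm`, under air-exchange rate `ach`. On a noiseless trace
#' this end-of-transfer excess is exactly what the decay fit extrapolates to,
#' so this is the calibration handle of the scenario presets.
#'
#' @param excess_ppm Target excess concentration at source-off, ppm.
#' @param ach Air-exchange rate, 1/h.
#' @param duration_min Source-on duration, minutes.
#' @return Source rate in ppm/min.
#' @export
source_rate_for_eec <- function(excess_ppm, ach, duration_min) {
  stopifnot(excess_ppm >= 0, ach >= 0, duration_min > 0)
  lam <- ach / 60  # per minute
  if (lam == 0) return(excess_ppm / duration_min)
  excess_ppm * lam / (1 - exp(-lam * duration_min))
}

#' Source rate that produces a given mean excess over the source-on window
#'
#' Companion to [source_rate_for_eec()] for drain/flush style evaluation:
#' the time-averaged excess over the source-on interval itself (lid open to
#' lid close) equals `mean_excess_ppm`.
#'
#' @param mean_excess_ppm Target mean excess concentration, ppm.
#' @param ach Air-exchange rate, 1/h.
#' @param duration_min Source-on (lid-open) duration, minutes.
#' @return Source rate in ppm/min.
#' @export
source_rate_for_mean <- function(mean_excess_ppm, ach, duration_min) {
  stopifnot(mean_excess_ppm >= 0, ach >= 0, duration_min > 0)
  lam <- ach / 60
  if (lam == 0) return(2 * mean_excess_ppm / duration_min)
  # mean over [0, T] of (S/lam)(1 - exp(-lam t)) = (S/lam)(1 - (1-exp(-lam T))/(lam T))
  shape <- 1 - (1 - exp(-lam * duration_min)) / (lam * duration_min)
  mean_excess_ppm * lam / shape
}

#' Presets for the nine laboratory exposure scenarios
#'
#' One row per scenario of the solvent-transfer study design: gravity
#' transfer with and without enclosure/extraction (1-4), drum-pump transfer
#' (5-7) and drain/flush of a drum (8-9). Scenarios 1 and 8 are the
#' baselines (reduction factor 1). Each preset carries the room ventilation
#' state (air-exchange rate 1 or 11 per hour), the transfer duration (50 l
#' at 12.5 l/min gravity = 4 min, at 50 l/min drum pump = 1 min), and a
#' calibration target: the source rate of a simulated run is set so the
#' noiseless trace evaluates to the scenario's published mean value
#' (extrapolated concentration, or lid-open mean for scenario 9). The
#' reduction factor is that target relative to the 454 ppm gravity-transfer
#' baseline (scenario 9 relative to its own 53 ppm drain baseline).
#'
#' @return A tibble with columns `scenario_id`, `label`, `trace_kind`,
#'   `ach`, `transfer_duration_min`, `reduction_factor`, `target_ppm`,
#'   `baseline_id`.
#' @export
scenario_presets <- function() {
  p <- tibble::tibble(
    scenario_id = 1:9,
    label = c(
      "Baseline - open gravity transfer (splash loading), no ventilation",
      "Gravity transfer, partial enclosure (open fume hood), vented",
      "Gravity transfer, full enclosure (closed fume hood), vented",
      "Gravity transfer, local exhaust (elephant trunk), no enclosure",
      "Drum pump transfer (submerged loading), no ventilation",
      "Drum pump transfer, partial enclosure, vented",
      "Drum pump transfer, local exhaust, vented",
      "Drained container, no flushing, no ventilation (drain baseline)",
      "Drained and flushed container, no ventilation"),
    trace_kind = c(rep("transfer", 8L), "drain_flush"),
    ach = c(1, 11, 11, 11, 1, 11, 11, 1, 1),
    transfer_duration_min = c(4, 4, 4, 4, 1, 1, 1, 5, 10),
    target_ppm = c(454, 6, 0, 13, 29, 2, 5, 53, 2.5),
    baseline_id = c(NA, 1L, 1L, 1L, 1L, 1L, 1L, NA, 8L)
  )
  p$reduction_factor <- ifelse(p$scenario_id <= 7, p$target_ppm / 454,
                               p$target_ppm / 53)
  p$reduction_factor[p$scenario_id %in% c(1L, 8L)] <- 1
  p
}

# Room/event pair for one preset row. Background and pre-event margin are
# fixed across scenarios; total duration gives the slow (ACH 1) decays room
# to express themselves and the fast ones time to return to background.
.preset_run <- function(preset, background_ppm = 0.5, pre_event_s = 240) {
  dur_min <- preset$transfer_duration_min
  target_excess <- max(preset$target_ppm - background_ppm *
                         (preset$trace_kind == "drain_flush"), 0)
  src <- if (preset$trace_kind == "drain_flush") {
    source_rate_for_mean(target_excess, preset$ach, dur_min)
  } else {
    source_rate_for_eec(preset$target_ppm, preset$ach, dur_min)
  }
  duration_s <- pre_event_s + dur_min * 60 + if (preset$ach > 5) 1800 else 3300
  params <- room_params(ach = preset$ach, background_ppm = background_ppm,
                        source_rate = src, duration_s = duration_s)
  event <- transfer_event(pre_event_s, pre_event_s + dur_min * 60)
  list(params = params, event = event)
}

#' Simulate one scenario replicate from its preset
#'
#' @param scenario_id Scenario number 1-9, see [scenario_presets()].
#' @param noise A [noise_model()]; its seed fixes the replicate.
#' @param replicate Replicate identifier stored on the trace.
#' @param background_ppm Ambient concentration, ppm.
#' @return A [concentration_trace()].
#' @export
simulate_scenario <- function(scenario_id, noise = noise_model(),
                              replicate = 1L, background_ppm = 0.5) {
  presets <- scenario_presets()
  if (!scenario_id %in% presets$scenario_id) {
    stop("unknown scenario_id: ", scenario_id, call. = FALSE)
  }
  preset <- presets[presets$scenario_id == scenario_id, ]
  run <- .preset_run(preset, background_ppm = background_ppm)
  simulate_trace(run$params, run$event, noise,
                 trace_kind = preset$trace_kind,
                 scenario_id = scenario_id, replicate = replicate)
}

#' Simulate replicate traces for a set of scenario presets
#'
#' Per-trace seeds are derived deterministically from the base seed in
#' `noise` (`seed + 1000 * scenario_id + replicate`), so the whole set is
#' reproducible and replicates differ from each other whenever the noise is
#' non-zero.
#'
#' @param scenario_ids Scenarios to simulate (default all nine).
#' @param n_replicates Replicates per scenario (at least 1; the study design
#'   used a minimum of three).
#' @param noise Base [noise_model()]; its seed anchors the whole set.
#' @param background_ppm Ambient concentration, ppm.
#' @return A list of [concentration_trace()] objects, one per
#'   (scenario, replicate).
#' @export
generate_scenario_set <- function(scenario_ids = 1:9, n_replicates = 3L,
                                  noise = noise_model(),
                                  background_ppm = 0.5) {
  if (length(scenario_ids) == 0L) {
    stop("`scenario_ids` must not be empty", call. = FALSE)
  }
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  out <- list()
  for (sid in scenario_ids) {
    for (rep_i in seq_len(n_replicates)) {
      nm <- noise
      nm$seed <- as.integer(noise$seed + 1000L * sid + rep_i)
      out[[length(out) + 1L]] <- simulate_scenario(
        sid, noise = nm, replicate = rep_i, background_ppm = background_ppm)
    }
  }
  out
}
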