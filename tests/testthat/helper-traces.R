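# A trace whose post-event limb is an exact exponential y0 * exp(-k t) above
# a known background; the pre-event part is flat at the peak so fit_decay /
# select_decay_window can be exercised with a supplied background.
pure_decay_trace <- function(y0 = 100, k_per_min = 11 / 60, bg = 0,
                             dt = 20, t_end = 100, n_post = 60,
                             target_ach = 60 * k_per_min) {
  times <- seq(0, t_end + n_post * dt, by = dt)
  conc <- ifelse(times < t_end, bg + y0,
                 bg + y0 * exp(-k_per_min * (times - t_end) / 60))
  concentration_trace(times, conc, transfer_event(t_end / 2, t_end),
                      target_ach = target_ach)
}

# Independent window-selection oracle: exhaustive enumeration with lm() per
# candidate, replicating the documented admissibility and tie-break rules.
naive_select_window <- function(trace, bg, ach_tol = 1, max_off = 10L,
                                min_pts = 5L, min_r2 = 0.9) {
  post <- which(trace$times_s >= trace$event$t_end_s)
  excess <- trace$conc_ppm[post] - bg
  floor_ppm <- max(0.1, 0.01 * max(excess))
  adm <- excess >= floor_ppm
  best <- NULL
  for (off in 0:max_off) {
    s <- 1L + off
    if (s > length(post) || !adm[s]) next
    e_max <- s
    while (e_max < length(post) && adm[e_max + 1L]) e_max <- e_max + 1L
    if (e_max - s + 1L < min_pts) next
    for (e in seq(s + min_pts - 1L, e_max)) {
      x <- (trace$times_s[post[s:e]] - trace$event$t_end_s) / 60
      y <- log(excess[s:e])
      m <- stats::lm(y ~ x)
      ach_fit <- -stats::coef(m)[[2L]] * 60
      if (abs(ach_fit - trace$target_ach) > ach_tol) next
      r2 <- summary(m)$r.squared
      if (r2 < min_r2) next
      n <- e - s + 1L
      if (is.null(best) || n > best$n ||
          (n == best$n && r2 > best$r2)) {
        best <- list(start = post[s], end = post[e], n = n, r2 = r2)
      }
    }
  }
  best
}

# Brute-force numerical integration of the one-box balance, segment by
# segment so each piece is smooth (source constant within a segment), fixed
# 0.05 s fourth-order Runge-Kutta steps. Returns concentrations at `times`.
ode_oracle <- function(params, event, times) {
  lam <- params$ach / 3600
  bg <- params$background_ppm
  run_seg <- function(c0, t0, t1, src) {
    grid <- seq(t0, t1, by = 0.05)
    rhs <- function(t, y, p) list(src - lam * (y - bg))
    deSolve::ode(c(C = unname(c0)), grid, rhs, NULL, method = "rk4")
  }
  segs <- list(
    run_seg(bg, 0, event$t_start_s, 0),
    NULL, NULL)
  segs[[2]] <- run_seg(segs[[1]][nrow(segs[[1]]), "C"], event$t_start_s,
                       event$t_end_s, params$source_rate / 60)
  segs[[3]] <- run_seg(segs[[2]][nrow(segs[[2]]), "C"], event$t_end_s,
                       params$duration_s, 0)
  tt <- c(segs[[1]][, "time"], segs[[2]][, "time"], segs[[3]][, "time"])
  cc <- c(segs[[1]][, "C"], segs[[2]][, "C"], segs[[3]][, "C"])
  vapply(times, function(x) cc[which.min(abs(tt - x))], numeric(1))
}

# Direct transcription of the three effectiveness formulas, kept independent
# of emission_reduction().
direct_reductions <- function(x, b) {
  c(min = (1 - max(x) / min(b)) * 100,
    opt = (1 - min(x) / max(b)) * 100,
    mean = (1 - mean(x) / mean(b)) * 100)
}
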