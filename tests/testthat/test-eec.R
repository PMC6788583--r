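test_that("background is the median of the pre-event window", {
  times <- seq(0, 2000, by = 20)
  event <- transfer_event(400, 700)
  flat <- concentration_trace(times, rep(1, length(times)), event, 11)
  expect_equal(estimate_background(flat), 1)

  conc <- rep(2, length(times))
  conc[5] <- 50  # a movement spike must not shift the estimate
  conc[times >= 400] <- 40
  spiky <- concentration_trace(times, conc, event, 11)
  expect_equal(estimate_background(spiky), 2)

  short <- concentration_trace(times, rep(1, length(times)),
                               transfer_event(100, 700), 11)
  expect_error(estimate_background(short), "pre-event samples")
})

test_that("background estimate round-trips through the simulator", {
  params <- room_params(ach = 11, background_ppm = 1.5, source_rate = 90,
                        duration_s = 1800)
  tr <- simulate_trace(params, transfer_event(300, 540),
                       noise_model(seed = 3))
  expect_lt(abs(estimate_background(tr) - 1.5) / 1.5, 0.05)
})

test_that("perfect decay selects all post-event points above the floor", {
  tr <- pure_decay_trace(y0 = 100, k_per_min = 11 / 60, n_post = 40)
  w <- select_decay_window(tr, background_ppm = 0)
  post <- which(tr$times_s >= tr$event$t_end_s)
  adm <- post[tr$conc_ppm[post] >= max(0.1, 0.01 * 100)]
  expect_equal(w$start, adm[1])
  expect_equal(w$end, adm[length(adm)])
})

test_that("a decay violating the air-exchange constraint is unfittable", {
  tr <- pure_decay_trace(y0 = 100, k_per_min = 22 / 60, n_post = 40,
                         target_ach = 11)
  err <- expect_error(select_decay_window(tr, background_ppm = 0),
                      class = "rmmeff_unfittable")
  expect_match(conditionMessage(err), "best achieved")
})

test_that("window selection agrees with an exhaustive lm-based oracle", {
  for (seed in c(2, 9, 17)) {
    tr <- simulate_scenario(2, noise_model(seed = seed))
    bg <- estimate_background(tr)
    got <- select_decay_window(tr, bg)
    ref <- naive_select_window(tr, bg)
    expect_equal(got$start, ref$start)
    expect_equal(got$end, ref$end)
    expect_lt(abs(got$ach_fit - 11), 1 + 1e-9)
  }
})

test_that("fit_decay recovers an exact synthetic exponential", {
  tr <- pure_decay_trace(y0 = 100, k_per_min = 0.1833, n_post = 40,
                         target_ach = 11)
  w <- list(start = which(tr$times_s >= tr$event$t_end_s)[1],
            end = length(tr$times_s))
  fit <- fit_decay(tr, w, background_ppm = 0)
  expect_equal(fit$eec_ppm, 100, tolerance = 1e-10)
  expect_equal(signif(fit$ach_fit, 3), 11.0)
  expect_equal(fit$ach_fit, 60 * fit$k_per_min)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # adding a known background and supplying it must not change the fit
  shifted <- concentration_trace(tr$times_s, tr$conc_ppm + 2, tr$event,
                                 tr$target_ach)
  fit2 <- fit_decay(shifted, w, background_ppm = 2)
  expect_equal(fit2$eec_ppm, fit$eec_ppm, tolerance = 1e-10)
  expect_equal(fit2$k_per_min, fit$k_per_min, tolerance = 1e-10)
})

test_that("nonlinear refinement agrees with log-OLS on clean data", {
  tr <- simulate_scenario(2, no_noise())
  fit <- compute_eec(tr)
  ref <- refine_decay_fit(tr, fit)
  expect_equal(ref$eec_ppm, fit$eec_ppm, tolerance = 1e-6)
  expect_equal(ref$ach_fit, fit$ach_fit, tolerance = 1e-6)

  noisy <- simulate_scenario(2, noise_model(seed = 14))
  nfit <- compute_eec(noisy)
  nref <- refine_decay_fit(noisy, nfit)
  expect_lt(abs(nref$eec_ppm - nfit$eec_ppm) / nfit$eec_ppm, 0.1)
  flat <- compute_eec(simulate_scenario(3, no_noise()))
  expect_error(refine_decay_fit(simulate_scenario(3, no_noise()), flat),
               "no-observable-emission")
})

test_that("fit_decay rejects windows touching the background", {
  tr <- pure_decay_trace(y0 = 1, k_per_min = 11 / 60, n_post = 60)
  w <- list(start = which(tr$times_s >= tr$event$t_end_s)[1],
            end = length(tr$times_s))
  expect_error(fit_decay(tr, w, background_ppm = 0.5), "non-positive")
})

test_that("compute_eec recovers the calibrated baseline under noise", {
  fit <- compute_eec(simulate_scenario(1, noise_model(seed = 12)))
  expect_lt(abs(fit$eec_ppm - 454) / 454, 0.10)
})

test_that("traces without an excursion above background report NoE", {
  times <- seq(0, 3000, by = 20)
  flat <- concentration_trace(times, rep(1, length(times)),
                              transfer_event(400, 640), 11)
  fit <- compute_eec(flat)
  expect_true(fit$noe)
  expect_true(is.na(fit$eec_ppm))

  # full-enclosure scenario: zero source, clean trace
  fit3 <- compute_eec(simulate_scenario(3, no_noise()))
  expect_true(fit3$noe)
})

test_that("compute_eec refuses drain/flush traces", {
  tr <- simulate_scenario(9, no_noise())
  expect_error(compute_eec(tr), "drain")
})

test_that("lid-open mean concentration follows the arithmetic mean", {
  times <- seq(0, 400, by = 20)
  event <- transfer_event(100, 200)
  flat <- concentration_trace(times, rep(2.5, length(times)), event, 1,
                              trace_kind = "drain_flush")
  expect_equal(mean_concentration_between(flat), 2.5)

  conc <- rep(0, length(times))
  conc[times >= 100 & times <= 200] <- c(2, 3, 4, 3, 3, 3)[1:6]
  tr <- concentration_trace(times, conc, event, 1,
                            trace_kind = "drain_flush")
  expect_equal(mean_concentration_between(tr), mean(c(2, 3, 4, 3, 3, 3)))
})

test_that("flushed-drum simulation round-trips its lid-open mean", {
  clean <- mean_concentration_between(simulate_scenario(9, no_noise()))
  noisy <- mean_concentration_between(simulate_scenario(9,
                                                        noise_model(seed = 4)))
  expect_lt(abs(noisy - clean) / clean, 0.10)
  expect_equal(clean, 2.5, tolerance = 0.05)
})

test_that("scenario summaries reproduce mean, extrema and sample CV", {
  s <- summarize_scenario(c(12, 14, 13), 4)
  expect_equal(s$mean_ppm, 13)
  expect_equal(round(s$cv_percent, 1), 7.7)

  expect_equal(summarize_scenario(c(5, 5, 5))$cv_percent, 0)

  b <- summarize_scenario(c(454, 424, 410, 430, 553), 1)
  expect_equal(round(b$mean_ppm), 454)
  # two-pass variance oracle
  v <- c(454, 424, 410, 430, 553)
  cv_direct <- 100 * sqrt(sum((v - mean(v))^2) / (length(v) - 1)) / mean(v)
  expect_equal(b$cv_percent, cv_direct)
  expect_equal(round(b$cv_percent, 1), 12.7)
  expect_true(b$min_ppm <= b$mean_ppm && b$mean_ppm <= b$max_ppm)

  expect_error(summarize_scenario(5), "at least 2")
  expect_error(summarize_scenario(c(0, 0, 0)), "zero")
  expect_error(summarize_scenario(c(-1, 2)), "non-negative")
})
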