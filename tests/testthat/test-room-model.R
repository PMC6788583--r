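test_that("zero-source simulation stays at the background", {
  tr <- simulate_trace(room_params(source_rate = 0, background_ppm = 1,
                                   duration_s = 1200),
                       transfer_event(240, 480), no_noise(seed = 42))
  expect_equal(tr$conc_ppm, rep(1, length(tr$times_s)))
})

test_that("post-source relaxation follows the one-box closed form", {
  # with ventilation on, one minute after source-off the excess must have
  # decayed by exactly exp(-11/60)
  params <- room_params(ach = 11, background_ppm = 0, source_rate = 60,
                        duration_s = 1200)
  tr <- simulate_trace(params, transfer_event(240, 480), no_noise())
  c0 <- tr$conc_ppm[tr$times_s == 480]
  c60 <- tr$conc_ppm[tr$times_s == 540]
  expect_equal(c60, c0 * exp(-11 / 60), tolerance = 1e-12)
})

test_that("closed-form solution matches a numerical ODE oracle", {
  params <- room_params(ach = 11, background_ppm = 0.5, source_rate = 90,
                        duration_s = 1200)
  event <- transfer_event(240, 480)
  tr <- simulate_trace(params, event, no_noise())
  at_samples <- ode_oracle(params, event, tr$times_s)
  expect_equal(length(at_samples), length(tr$conc_ppm))
  expect_lt(max(abs(at_samples - tr$conc_ppm) / pmax(tr$conc_ppm, 1e-9)),
            1e-4)
})

test_that("noiseless excess concentration is linear in the source rate", {
  event <- transfer_event(240, 480)
  p1 <- room_params(ach = 11, background_ppm = 0.7, source_rate = 50,
                    duration_s = 1200)
  p2 <- room_params(ach = 11, background_ppm = 0.7, source_rate = 100,
                    duration_s = 1200)
  t1 <- simulate_trace(p1, event, no_noise())
  t2 <- simulate_trace(p2, event, no_noise())
  expect_equal(t2$conc_ppm - 0.7, 2 * (t1$conc_ppm - 0.7), tolerance = 1e-12)
})

test_that("noiseless post-source log decay is exactly linear with slope -ach", {
  tr <- simulate_scenario(5, no_noise())
  post <- tr$times_s > tr$event$t_end_s
  slope <- diff(log(tr$conc_ppm[post] - 0.5)) /
    diff(tr$times_s[post] / 3600)
  expect_equal(slope, rep(-1, length(slope)), tolerance = 1e-9)
})

test_that("simulation is deterministic for a fixed seed, varies across seeds", {
  params <- room_params(ach = 11, source_rate = 90, duration_s = 1200)
  event <- transfer_event(240, 480)
  a <- simulate_trace(params, event, noise_model(seed = 7))
  b <- simulate_trace(params, event, noise_model(seed = 7))
  c <- simulate_trace(params, event, noise_model(seed = 8))
  expect_identical(a$conc_ppm, b$conc_ppm)
  expect_false(identical(a$conc_ppm, c$conc_ppm))
  expect_true(all(a$conc_ppm >= 0))
})

test_that("invalid simulator inputs are rejected", {
  expect_error(room_params(volume = -1), "positive")
  expect_error(room_params(ach = NaN), "finite")
  expect_error(transfer_event(100, 100))
  expect_error(simulate_trace(room_params(duration_s = 300),
                              transfer_event(100, 400), no_noise()),
               "too short")
})

test_that("scenario sets have one trace per preset/replicate and reproduce", {
  set1 <- generate_scenario_set(2, n_replicates = 3, noise_model(seed = 5))
  set2 <- generate_scenario_set(2, n_replicates = 3, noise_model(seed = 5))
  expect_length(set1, 3L)
  expect_identical(lapply(set1, `[[`, "conc_ppm"),
                   lapply(set2, `[[`, "conc_ppm"))
  expect_false(identical(set1[[1]]$conc_ppm, set1[[2]]$conc_ppm))
  expect_error(generate_scenario_set(integer(0)), "empty")
  expect_error(generate_scenario_set(1, n_replicates = 0), ">= 1")
})

test_that("scenario presets encode the study design", {
  p <- scenario_presets()
  expect_equal(nrow(p), 9L)
  expect_equal(p$reduction_factor[p$scenario_id %in% c(1, 8)], c(1, 1))
  expect_true(all(p$reduction_factor >= 0 & p$reduction_factor <= 1))
  expect_equal(p$transfer_duration_min[1:4], rep(4, 4))  # 50 l at 12.5 l/min
  expect_equal(p$transfer_duration_min[5:7], rep(1, 3))  # 50 l at 50 l/min
  expect_setequal(p$ach, c(1, 11))
})

test_that("baseline preset is calibrated to a 454 ppm extrapolated value", {
  fit <- compute_eec(simulate_scenario(1, no_noise()))
  expect_equal(fit$eec_ppm, 454, tolerance = 0.005)
  expect_equal(fit$ach_fit, 1, tolerance = 1e-6)
})

test_that("scenario-2 preset recovers its calibrated 6 ppm mean under noise", {
  fits <- lapply(generate_scenario_set(2, 3, noise_model(seed = 11)),
                 compute_eec)
  eecs <- vapply(fits, `[[`, numeric(1), "eec_ppm")
  cv <- sd(eecs) / mean(eecs)
  expect_lt(abs(mean(eecs) - 6), 3 * cv * 6 + 1e-9)
})
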