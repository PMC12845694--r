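test_that("candidates align with sine peaks, one per cycle", {
  clean <- sim_sine(duration_s = 60)
  fit <- run_filter(clean, kf_config(horizon_steps = 14))
  cand <- detect_candidates(fit$trace, gating_config(warmup_s = 0),
                            horizon_steps = 14)
  # brute-force per-cycle argmax oracle on the clean signal
  v <- clean$displacement_mm
  peaks <- vapply(0:11, function(cyc) {
    idx <- (cyc * 500 + 1):((cyc + 1) * 500)
    clean$time_s[idx[which.max(v[idx])]]
  }, numeric(1))
  # at most one candidate per cycle, each shortly before its peak
  expect_lte(nrow(cand), length(peaks))
  expect_gte(nrow(cand), length(peaks) - 2) # settling may skip early cycles
  for (tc in cand$time_s) {
    gap <- peaks - tc
    expect_true(any(gap > -0.05 & gap < 0.5))
  }
})

test_that("a monotone ramp yields no instantaneous candidates", {
  tr <- tibble::tibble(
    time_s = seq(0, 10, by = 0.01),
    xr_mm = seq(0, 10, by = 0.01),
    vr_mms = rep(1, 1001)
  )
  cand <- detect_candidates(tr, gating_config(warmup_s = 0), horizon_steps = 0)
  expect_equal(nrow(cand), 0)
})

test_that("template learning averages normalized cycles", {
  cyc <- 5 * (1 - cos(2 * pi * seq(0, 1, length.out = 500))) / 2
  tpl <- learn_template(replicate(5, cyc, simplify = FALSE))
  expect_true(tpl$ready)
  expect_equal(tpl$n_cycles, 5)
  expect_equal(tpl$mean_amplitude_mm, 5, tolerance = 1e-4)
  expect_equal(tpl$mean_period_s, 5)
  # identical cycles: template equals any one normalized cycle
  ref <- approx(seq(0, 1, length.out = 500), cyc / 5,
                xout = seq(0, 1, length.out = 100))$y
  expect_equal(tpl$shape, ref, tolerance = 1e-4)
  # self-similarity of 1.0 on the prefix up to the peak
  val <- validate_event(NULL, tpl, cyc[1:250], gating_config())
  expect_true(val$valid)
  expect_equal(val$score, 1, tolerance = 1e-4)

  # alternating 8/12 mm cycles average to 10 mm
  c8 <- 8 * (1 - cos(2 * pi * seq(0, 1, length.out = 500))) / 2
  c12 <- 12 * (1 - cos(2 * pi * seq(0, 1, length.out = 500))) / 2
  tpl2 <- learn_template(list(c8, c12, c8, c12))
  expect_equal(tpl2$mean_amplitude_mm, 10, tolerance = 1e-4)

  # fewer than 2 cycles: not ready, primary-only validation flagged
  tpl0 <- learn_template(list(cyc))
  expect_false(tpl0$ready)
  v0 <- validate_event(NULL, tpl0, cyc, gating_config())
  expect_true(v0$valid)
  expect_false(v0$template_ready)
})

test_that("template of a seeded regular pattern matches the raised-cosine shape", {
  b <- sim_breathing("regular", duration_s = 60, amplitude_jitter_frac = 0,
                     period_jitter_frac = 0, seed = 9)
  # segment exact valley-to-valley cycles from the construction (500 samples)
  v <- b$displacement_mm
  cycles <- lapply(0:9, function(j) v[(j * 500 + 1):((j + 1) * 500)])
  tpl <- learn_template(cycles)
  ref <- (1 - cos(2 * pi * seq(0, 1, length.out = 100))) / 2
  expect_gt(cor(tpl$shape, ref), 0.99)
})

test_that("dual validation rejects artifact cycles", {
  gcfg <- gating_config()
  cyc <- 10 * (1 - cos(2 * pi * seq(0, 1, length.out = 500))) / 2
  tpl <- learn_template(replicate(5, cyc, simplify = FALSE))

  # pulse artifact: amplitude 3x the template mean -> amplitude band
  val <- validate_event(NULL, tpl, cyc[1:250] * 3, gcfg)
  expect_false(val$valid)
  expect_equal(val$reason, "amplitude_band")

  # cycle stretched to twice the template period -> period band
  slow <- 10 * (1 - cos(2 * pi * seq(0, 0.5, length.out = 1000))) / 2
  val2 <- validate_event(NULL, tpl, slow, gcfg)
  expect_false(val2$valid)
  expect_equal(val2$reason, "period_band")
})

test_that("mode A trails the true peak, mode B anticipates it", {
  truth <- sim_sine(duration_s = 60)
  delayed <- apply_latency(truth, 0.2)
  gold <- annotate_gold(truth)
  gold <- gold[gold >= 10]

  evA <- run_gating(delayed, mode = "A")
  pmA <- prompt_metrics(evA, gold, 0.3)
  # prompts trail truth by the latency plus the small causal-detector lag
  expect_gt(pmA$dt_mean_ms, 180)
  expect_lt(pmA$dt_mean_ms, 320)

  evB <- run_gating(delayed, mode = "B")
  pmB <- prompt_metrics(evB, gold, 0.3)
  expect_lt(pmB$dt_mean_ms, 0)
  expect_equal(pmB$n_prompts, length(gold))

  # flat signal: no events in either mode
  flat <- resp_signal(rep(1, 3000))
  expect_equal(nrow(run_gating(flat, "A")), 0)
  expect_equal(nrow(run_gating(flat, "B")), 0)
})

test_that("events respect the refractory period and per-cycle uniqueness", {
  m <- sim_sine(duration_s = 120) |> add_noise(0.3, seed = 10) |>
    apply_latency(0.2)
  ev <- run_gating(m, mode = "B")
  expect_true(all(diff(ev$t_prompt_s) >= 2.0))
  # one prompt per post-warmup cycle (22 full cycles after 10 s)
  expect_equal(nrow(ev), 22)
})

test_that("gating is causal: truncating the input preserves earlier events", {
  m <- sim_sine(duration_s = 80) |> add_noise(0.3, seed = 12) |>
    apply_latency(0.2)
  ev_full <- run_gating(m, mode = "B")
  m_short <- resp_signal(m$displacement_mm[1:5000], dt = 0.01,
                         meta = signal_meta(m))
  ev_short <- run_gating(m_short, mode = "B")
  keep <- ev_full$t_prompt_s <= 49 # margin of one horizon before the cut
  expect_equal(ev_short$t_prompt_s, ev_full$t_prompt_s[keep], tolerance = 1e-12)
})
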