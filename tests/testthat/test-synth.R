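test_that("MUAP templates are peak-normalized, near zero-mean and deterministic", {
  tpl <- make_muap_template(10, 2, 1024)
  expect_length(tpl$samples, 10)           # round(10 ms * 1024 Hz / 1000)
  expect_equal(max(abs(tpl$samples)), 1)
  expect_lte(abs(mean(tpl$samples)), 0.05)
  expect_identical(tpl$samples, make_muap_template(10, 2, 1024)$samples)

  tri <- make_muap_template(15, 3, 1024)
  expect_length(tri$samples, round(15 * 1024 / 1000))
  expect_equal(max(abs(tri$samples)), 1)
  expect_lte(abs(mean(tri$samples)), 0.05)

  expect_error(make_muap_template(-3), "positive")
  expect_error(make_muap_template(30), "\\[5, 20\\]")
  expect_error(make_muap_template(10, 4), "n_phases")
  expect_error(make_muap_template(10, 2, 800), "900")
})

test_that("a single deterministic firing reproduces the scaled template", {
  tpl <- make_muap_template(10, 2, 1024)
  src <- muscle_source(2.5, firing_rate = 5, jitter_cv = 0,
                       template = tpl, seed_offset = 1)
  # rate 5 => inter-spike 0.2 s; first spike uniform in [0, 0.2), so a
  # 0.2 s recording holds exactly one firing
  rec <- simulate_recording(list(src), 1, duration_s = 0.2, fs = 1024,
                            noise_rms = 0, seed = 7)
  nz <- which(rec$samples != 0)
  expect_lte(length(nz), length(tpl$samples))
  expect_equal(max(abs(rec$samples)), 2.5)      # gain recovered exactly
  seg <- rec$samples[nz[1]:(nz[1] + length(tpl$samples) - 1)]
  expect_equal(seg, 2.5 * tpl$samples, tolerance = 1e-12)
})

test_that("recording length, seeding and input validation behave as specified", {
  src <- muscle_source(1, 10, template = make_muap_template())
  rec <- simulate_recording(list(src), 1, duration_s = 7.5, fs = 1024,
                            noise_rms = 0.2, seed = 3)
  expect_length(rec$samples, 7680)             # 7.5 s at 1024 samples/s

  rec2 <- simulate_recording(list(src), 1, duration_s = 7.5, fs = 1024,
                             noise_rms = 0.2, seed = 3)
  expect_identical(rec$samples, rec2$samples)
  rec3 <- simulate_recording(list(src), 1, duration_s = 7.5, fs = 1024,
                             noise_rms = 0.2, seed = 4)
  expect_false(identical(rec$samples, rec3$samples))

  expect_error(simulate_recording(list(), 1, 1, 1024), "non-empty")
  expect_error(simulate_recording(list(src), 1, -2, 1024), "duration_s")
  expect_error(simulate_recording(list(src), 1, 1, 1024, noise_rms = -1),
               "noise_rms")
})

test_that("noise-only recordings hit the requested RMS", {
  silent <- muscle_source(1, 0, template = make_muap_template())
  rec <- simulate_recording(list(silent), 1, duration_s = 8, fs = 1024,
                            noise_rms = 0.1, seed = 5)
  expect_lt(abs(sqrt(mean(rec$samples^2)) - 0.1) / 0.1, 0.05)
})

test_that("simulation is additive over sources (superposition)", {
  tpl <- make_muap_template()
  a <- muscle_source(1.0, 12, template = tpl, seed_offset = 11)
  b <- muscle_source(2.0, 8, template = tpl, seed_offset = 22)
  both <- simulate_recording(list(a, b), 1, 3, 1024, 0, seed = 9)
  only_a <- simulate_recording(list(a), 1, 3, 1024, 0, seed = 9)
  only_b <- simulate_recording(list(b), 1, 3, 1024, 0, seed = 9)
  expect_equal(both$samples, only_a$samples + only_b$samples,
               tolerance = 1e-12)
})

test_that("MUAP trains are sparse at the default rates", {
  ds <- generate_dataset(reps = 1, flexion_s = 5, noise_rms = 0, seed = 21)
  active_frac <- vapply(ds$recordings[1:4], function(r) mean(r$samples != 0),
                        numeric(1))
  expect_true(all(active_frac < 0.5))
})

test_that("the default protocol yields 4 x 12 labeled flexions plus background", {
  ds <- generate_dataset(seed = 2)
  labs <- vapply(ds$recordings, function(r) r$label, character(1))
  expect_equal(sum(labs != "background"), 48)
  expect_equal(unname(table(labs[labs != "background"])), rep(12L, 4),
               ignore_attr = TRUE)
  expect_gte(sum(labs == "background"), 1)

  ds2 <- generate_dataset(seed = 2)
  expect_identical(lapply(ds$recordings, `[[`, "samples"),
                   lapply(ds2$recordings, `[[`, "samples"))

  expect_error(generate_dataset(amplitude_gains = c(1, 1, 2, 3), seed = 1),
               "distinct")
  expect_error(generate_dataset(amplitude_gains = c(1, 2), seed = 1),
               "one entry per class")
})

test_that("per-class amplitude tracks the volume-conduction gains", {
  gains <- c(1, 1.5, 2.25, 3.375)
  # sparse firing keeps MUAPs from superposing, so peak amplitudes are
  # uncontaminated readouts of the per-class gain
  ds <- generate_dataset(reps = 2, flexion_s = 3, noise_rms = 0,
                         amplitude_gains = gains, active_rate = 6,
                         background_rate = 0, seed = 31)
  labs <- vapply(ds$recordings, function(r) r$label, character(1))
  mean_rect <- vapply(paste0("class", 1:4), function(k) {
    mean(vapply(ds$recordings[labs == k],
                function(r) mean(abs(r$samples)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rect) > 0))

  # largest detected peaks scale linearly with the gains
  peaks <- vapply(paste0("class", 1:4), function(k) {
    max(vapply(ds$recordings[labs == k],
               function(r) max(abs(r$samples)), numeric(1)))
  }, numeric(1))
  r2 <- summary(lm(peaks ~ gains))$r.squared
  expect_gt(r2, 0.99)
})
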