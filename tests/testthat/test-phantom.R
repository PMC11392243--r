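test_that("generated loops have the configured frame count and value range", {
  for (fpc in c(2, 8)) {
    for (nc in c(1, 2)) {
      out <- generate_sequence(tiny_config(frames_per_cycle = fpc, n_cycles = nc,
                                           seed = 3), "A2C")
      expect_length(out$sequence$frames, fpc * nc)
      expect_length(out$truth$wall_masks, fpc * nc)
      rng <- range(unlist(out$sequence$frames))
      expect_gte(rng[1], 0)
      expect_lte(rng[2], 1)
    }
  }
})

test_that("same config and seed give bit-identical frames; noise is seeded", {
  cfg <- tiny_config(seed = 5)
  a <- generate_sequence(cfg, "A4C")
  b <- generate_sequence(cfg, "A4C")
  expect_identical(a$sequence$frames, b$sequence$frames)
  c <- generate_sequence(tiny_config(seed = 6), "A4C")
  expect_false(identical(a$sequence$frames, c$sequence$frames))
})

test_that("wall pixels are brighter than background before noise", {
  out <- generate_sequence(tiny_config(speckle_sigma = 0, seed = 2), "A4C")
  fr <- out$sequence$frames[[1]]
  m <- out$truth$wall_masks[[1]] > 0
  expect_gt(mean(fr[m]), 0.7)
  expect_lt(mean(fr[!m]), 0.2)
})

test_that("hypokinesia scales the true segment amplitudes", {
  cfg <- tiny_config(hypokinetic_segments = 3, hypokinesia_factor = 0.2, seed = 1)
  out <- generate_sequence(cfg, "A4C")
  amp <- out$truth$segment_amplitudes
  expect_equal(unname(amp["r3"]), 0.2 * cfg$base_amplitude)
  expect_equal(unname(amp["l1"]), cfg$base_amplitude)
  expect_equal(out$truth$segment_labels[["r3"]], "hypokinetic")

  zero <- generate_sequence(tiny_config(hypokinetic_segments = 3,
                                        hypokinesia_factor = 0, seed = 1), "A4C")
  expect_equal(unname(zero$truth$segment_amplitudes["r3"]), 0)
})

test_that("lowering the hypokinesia factor strictly lowers affected amplitudes only", {
  amps <- lapply(c(0.8, 0.5, 0.2), function(f) {
    generate_sequence(tiny_config(hypokinetic_segments = c(2, 6),
                                  hypokinesia_factor = f, seed = 1),
                      "A4C")$truth$segment_amplitudes
  })
  affected <- c("r2", "l3")
  for (s in affected) {
    vals <- vapply(amps, `[[`, 0, s)
    expect_true(all(diff(vals) < 0))
  }
  for (s in setdiff(names(amps[[1]]), affected)) {
    expect_equal(length(unique(vapply(amps, `[[`, 0, s))), 1L)
  }
})

test_that("wall masks match the analytic annulus geometry exactly", {
  cfg <- tiny_config(speckle_sigma = 0, seed = 8)
  out <- generate_sequence(cfg, "A4C")
  # independent transcription of the geometry at the resting frame
  S <- cfg$image_size
  cy <- cfg$center[1]
  cx <- cfg$center[2]
  dy <- matrix(seq_len(S) - cy, S, S)
  dx <- matrix(seq_len(S) - cx, S, S, byrow = TRUE)
  rr <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dx, -dy) - cfg$rotation) %% (2 * pi)
  a0 <- cfg$opening_angle * pi / 180 / 2
  r_in <- cfg$mid_radius - cfg$wall_thickness / 2
  expected <- matrix(0L, S, S)
  expected[ang >= a0 & ang <= 2 * pi - a0 &
             rr >= r_in & rr <= r_in + cfg$wall_thickness] <- 1L
  expect_identical(out$truth$wall_masks[[1]], expected)
})

test_that("invalid phantom configurations name the offending field", {
  expect_error(tiny_config(frames_per_cycle = 1), "frames_per_cycle")
  expect_error(tiny_config(n_cycles = 0), "n_cycles")
  expect_error(tiny_config(hypokinesia_factor = 1.2), "hypokinesia_factor")
  expect_error(phantom_config(image_size = 64, base_amplitude = 20),
               "base_amplitude")
  expect_error(tiny_config(speckle_sigma = -1), "speckle_sigma")
  expect_error(tiny_config(segment_scales = rep(1, 5)), "segment_scales")
  expect_error(tiny_config(hypokinetic_segments = 9), "hypokinetic_segments")
})

test_that("cohorts have the requested composition and reproducible jitter", {
  coh <- generate_cohort(4, 3, tiny_config(hypokinesia_factor = 0.3), seed = 7)
  labs <- vapply(coh$subjects, `[[`, character(1), "label")
  expect_equal(sum(labs == "RWMA"), 4L)
  expect_equal(sum(labs == "non-RWMA"), 3L)
  for (s in coh$subjects) {
    n_hypo <- length(s$configs$A2C$hypokinetic_segments)
    if (s$label == "RWMA") expect_gte(n_hypo, 1L) else expect_equal(n_hypo, 0L)
    expect_identical(s$configs$A2C$hypokinetic_segments,
                     s$configs$A4C$hypokinetic_segments)
  }
  coh2 <- generate_cohort(4, 3, tiny_config(hypokinesia_factor = 0.3), seed = 7)
  expect_identical(coh, coh2)

  onlyneg <- generate_cohort(0, 5, tiny_config(), seed = 1)
  expect_true(all(vapply(onlyneg$subjects, `[[`, character(1), "label") == "non-RWMA"))

  one <- generate_cohort(1, 0, tiny_config(hypokinesia_factor = 0.2), seed = 2)
  tr <- phantom_realize(one$subjects[[1]])$A4C$truth
  hypo <- names(which(tr$segment_labels == "hypokinetic"))
  base <- one$subjects[[1]]$configs$A4C$base_amplitude
  expect_equal(unname(tr$segment_amplitudes[hypo]), rep(0.2 * base, length(hypo)))
})

test_that("realized cohort subjects carry per-view sequences with ground truth", {
  coh <- generate_cohort(1, 1, tiny_config(), seed = 3)
  views <- phantom_realize(coh$subjects[[2]])
  expect_named(views, c("A2C", "A4C"))
  expect_s3_class(views$A2C$sequence, "echo_sequence")
  expect_equal(views$A2C$sequence$view, "A2C")
  expect_equal(views$A4C$sequence$label, "non-RWMA")
  expect_length(views$A4C$truth$wall_masks, 16L)
})
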