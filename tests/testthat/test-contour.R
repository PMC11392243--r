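test_that("a symmetric wall mask yields equal arms and the analytic arc length", {
  cfg <- phantom_config(image_size = 128, frames_per_cycle = 8, n_cycles = 1,
                        wall_thickness = 8, base_amplitude = 4, mid_radius = 36,
                        speckle_sigma = 0, seed = 3)
  out <- generate_sequence(cfg, "A4C")
  ct <- extract_contour(out$truth$wall_masks[[1]])
  expect_lte(abs(ct$L - ct$R), 2)
  measured <- ct$arc[length(ct$arc)]
  expect_lt(abs(measured / out$truth$geometry$inner_arc_length - 1), 0.03)
})

test_that("degenerate masks are rejected with informative errors", {
  expect_error(extract_contour(matrix(0L, 16, 16)), "empty mask")
  expect_error(extract_contour(matrix(0L, 16, 16), frame_index = 4), "frame 4")
  two <- matrix(0L, 24, 24)
  two[3:6, 3:6] <- 1L
  two[15:18, 15:18] <- 1L
  expect_error(extract_contour(two), "components")
})

test_that("segment spans follow the 2/7,2/7,2/7,1/7 rule and tile both arms", {
  fake <- structure(list(L = 70, R = 70), class = "lv_contour")
  part <- partition_segments(fake)
  right <- part[part$side == "right", ]
  right <- right[order(right$segment_id), ]  # r1..r4 = base to apex
  expect_equal(right$end - right$start, c(20, 20, 20, 10))
  left <- part[part$side == "left", ]
  expect_equal(left$end - left$start, c(20, 20, 20, 10))

  small <- partition_segments(structure(list(L = 7, R = 7), class = "lv_contour"))
  expect_equal(small$end - small$start, c(2, 2, 2, 1, 2, 2, 2, 1))

  out <- tiny_sequence()
  ct <- extract_contour(out$truth$wall_masks[[1]])
  part2 <- partition_segments(ct)
  expect_equal(sum(part2$end - part2$start), ct$L + ct$R, tolerance = 1e-9)
  # spans tile each arm without overlap
  left2 <- part2[part2$side == "left", ]
  expect_equal(sort(left2$start), c(0, cumsum(c(2, 2, 2) / 7 * ct$L)), tolerance = 1e-9)
})

test_that("displacement is zero at the origin frame and 5 under a (3,4) translation", {
  out <- tiny_sequence()
  m1 <- out$truth$wall_masks[[1]]
  c1 <- extract_contour(m1)
  same <- displacement_curves(list(c1, c1))
  expect_true(all(same$values == 0))

  m2 <- matrix(0L, 64, 64)
  m2[4:64, 5:64] <- m1[1:61, 1:60]
  dc <- displacement_curves(list(c1, extract_contour(m2)))
  expect_true(all(dc$values[, 1] == 0))
  expect_equal(unname(dc$values[, 2]), rep(5, 8), tolerance = 0.05)
  expect_equal(unname(dc$maxima), rep(5, 8), tolerance = 0.05)
})

test_that("curves are invariant to a rigid translation of the whole loop", {
  cfg <- phantom_config(image_size = 128, frames_per_cycle = 8, n_cycles = 1,
                        wall_thickness = 8, base_amplitude = 4, mid_radius = 34,
                        speckle_sigma = 0, seed = 12)
  masks <- generate_sequence(cfg, "A4C")$truth$wall_masks[1:5]
  shifted <- lapply(masks, function(m) {
    s <- matrix(0L, 128, 128)
    s[7:128, 4:128] <- m[1:122, 1:125]
    s
  })
  d1 <- displacement_curves(lapply(masks, extract_contour))
  d2 <- displacement_curves(lapply(shifted, extract_contour))
  expect_equal(d1$values, d2$values, tolerance = 0.05)
})

test_that("a strongly hypokinetic segment shows a clearly reduced maximum", {
  cfg <- phantom_config(image_size = 128, frames_per_cycle = 12, n_cycles = 1,
                        wall_thickness = 8, base_amplitude = 6, mid_radius = 34,
                        speckle_sigma = 0, seed = 9,
                        hypokinetic_segments = 3, hypokinesia_factor = 0.2)
  out <- generate_sequence(cfg, "A4C")
  dc <- displacement_curves(contour_sequence(out$truth$wall_masks))
  hypo <- dc$maxima["r3"]
  others <- dc$maxima[setdiff(names(dc$maxima), "r3")]
  expect_lt(hypo, 0.5 * median(others))
})

test_that("displacement curves can be exported as tidy CSV", {
  out <- tiny_sequence()
  cons <- contour_sequence(out$truth$wall_masks[1:3])
  dc <- displacement_curves(cons)
  path <- withr::local_tempfile(fileext = ".csv")
  write_displacement_csv(dc, path, subject = "S1", view = "A4C")
  df <- read.csv(path)
  expect_equal(nrow(df), 8 * 3)
  expect_named(df, c("subject", "view", "segment", "frame", "displacement"))
  expect_true(all(df$displacement[df$frame == 1] == 0))
})
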