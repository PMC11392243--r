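test_that("the U-Net layer count follows the 5d-2 rule; default depth gives 23", {
  small <- build_segmenter(unet_config(depth = 3, base_channels = 2, input_size = 16))
  expect_equal(count_conv_layers(small), 13L)
  expect_error(unet_config(depth = 4, input_size = 100), "input_size")
})

test_that("mask size equals frame size and per-pixel class scores sum to one", {
  ef <- asNamespace("echoflow")
  seg <- build_segmenter(unet_config(depth = 2, base_channels = 2, input_size = 32),
                         seed = 4)
  x <- matrix(runif(32 * 32), 32, 32)
  prob <- ef$unet_predict_prob(seg, x)
  expect_equal(dim(prob), c(32L, 32L, 2L))
  expect_equal(prob[, , 1] + prob[, , 2], matrix(1, 32, 32), tolerance = 1e-12)
})

test_that("segment_sequence masks every frame and zeroes the background", {
  seg <- build_segmenter(unet_config(depth = 2, base_channels = 2, input_size = 64),
                         seed = 4)
  out <- tiny_sequence()
  sg <- segment_sequence(seg, out$sequence)
  expect_length(sg$masks, length(out$sequence$frames))
  for (t in c(1, 9)) {
    expect_equal(sg$masked$frames[[t]],
                 out$sequence$frames[[t]] * sg$masks[[t]])
    expect_true(all(sg$masked$frames[[t]][sg$masks[[t]] == 0] == 0))
  }
  # all-zero frame stays all-zero after masking
  zseq <- out$sequence
  zseq$frames <- list(matrix(0, 64, 64), matrix(0, 64, 64))
  zs <- segment_sequence(seg, zseq)
  expect_true(all(zs$masked$frames[[1]] == 0))

  bad <- out$sequence
  bad$frames[[2]] <- matrix(0, 32, 32)
  expect_error(segment_sequence(seg, bad), "frame 2")
})

test_that("re-applying the same masks is idempotent", {
  out <- tiny_sequence()
  masked <- apply_masks(out$sequence, out$truth$wall_masks)
  twice <- apply_masks(masked, out$truth$wall_masks)
  expect_identical(masked$frames, twice$frames)
  expect_error(apply_masks(out$sequence, out$truth$wall_masks[-1]), "one mask per frame")
})

test_that("pixel-wise evaluation equals brute-force pixel counting", {
  set.seed(5)
  pred <- list(matrix(sample(0:1, 256, TRUE), 16, 16))
  truth <- list(matrix(sample(0:1, 256, TRUE), 16, 16))
  ev <- evaluate_segmentation(pred, truth)
  tp <- sum(pred[[1]] == 1 & truth[[1]] == 1)
  tn <- sum(pred[[1]] == 0 & truth[[1]] == 0)
  fp <- sum(pred[[1]] == 1 & truth[[1]] == 0)
  fn <- sum(pred[[1]] == 0 & truth[[1]] == 1)
  expect_equal(ev$confusion$TP, tp)
  expect_equal(unname(ev$metrics["accuracy"]), 100 * (tp + tn) / 256)
  expect_equal(unname(ev$metrics["sensitivity"]), 100 * tp / (tp + fn))
  expect_equal(unname(ev$metrics["precision"]), 100 * tp / (tp + fp))

  perfect <- evaluate_segmentation(truth, truth)
  expect_equal(unname(perfect$metrics[c("sensitivity", "precision", "f1", "accuracy")]),
               rep(100, 4))
  expect_equal(perfect$dice, 1)

  flipped <- evaluate_segmentation(list(1L - truth[[1]]), truth)
  expect_equal(unname(flipped$metrics["sensitivity"]), 0)

  expect_error(evaluate_segmentation(pred, list(matrix(0, 8, 8))), "shapes differ")
  expect_error(evaluate_segmentation(pred, truth[c(1, 1)]), "counts differ")
})

test_that("training reduces the loss, respects epochs = 0, and is seed-deterministic", {
  out <- generate_sequence(tiny_config(image_size = 32, mid_radius = 9,
                                       wall_thickness = 4, base_amplitude = 2,
                                       seed = 13), "A4C")
  frames <- out$sequence$frames[1:8]
  masks <- out$truth$wall_masks[1:8]
  seg0 <- build_segmenter(unet_config(depth = 2, base_channels = 2, input_size = 32),
                          seed = 6)
  expect_identical(train_segmenter(seg0, frames, masks, epochs = 0L), seg0)
  expect_error(train_segmenter(seg0, list(), list(), epochs = 1), "empty")

  seg1 <- train_segmenter(seg0, frames, masks, epochs = 4, lr = 2e-3, seed = 2)
  h <- attr(seg1, "loss_history")
  expect_lt(h[length(h)], h[1])
  seg2 <- train_segmenter(seg0, frames, masks, epochs = 4, lr = 2e-3, seed = 2)
  expect_identical(h, attr(seg2, "loss_history"))
})
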