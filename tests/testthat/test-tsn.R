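test_that("snippet sampling yields k 10-channel stacks from equal-duration segments", {
  enc <- synthetic_encodings(74, size = 16)
  snips <- sample_snippets(enc, consensus_config(k = 7))
  expect_length(snips, 7L)
  for (i in seq_along(snips)) {
    expect_equal(dim(snips[[i]]$stack), c(16L, 16L, 10L))
    expect_equal(snips[[i]]$segment_index, i)
    expect_equal(diff(snips[[i]]$pair_indices), rep(1L, 4))  # consecutive pairs
  }
  # snippets stay inside their own temporal segment
  bounds <- floor(seq_len(7) * 74 / 7)
  starts <- c(0L, bounds[-7]) + 1L
  for (i in seq_along(snips)) {
    expect_gte(min(snips[[i]]$pair_indices), starts[i])
    expect_lte(max(snips[[i]]$pair_indices), bounds[i])
  }
})

test_that("zero slack forces offset 0 and short sequences are rejected", {
  enc <- synthetic_encodings(35, size = 8)
  snips <- sample_snippets(enc, consensus_config(k = 7, sampling_mode = "random"),
                           seed = 3)
  for (i in 1:7) expect_equal(snips[[i]]$pair_indices, (5 * (i - 1) + 1):(5 * i))

  expect_error(sample_snippets(synthetic_encodings(10, size = 8),
                               consensus_config(k = 7)),
               "35")
})

test_that("random sampling is seed-deterministic; center sampling needs no seed", {
  enc <- synthetic_encodings(60, size = 8)
  cfg <- consensus_config(k = 4, sampling_mode = "random")
  a <- sample_snippets(enc, cfg, seed = 5)
  b <- sample_snippets(enc, cfg, seed = 5)
  expect_identical(a, b)
  c1 <- sample_snippets(enc, consensus_config(k = 4))
  c2 <- sample_snippets(enc, consensus_config(k = 4))
  expect_identical(c1, c2)
})

test_that("decoded snippet values are zero-centred in [-1, 1]", {
  enc <- synthetic_encodings(10, size = 8, scale = 30)
  snips <- sample_snippets(enc, consensus_config(k = 2))
  vals <- unlist(lapply(snips, `[[`, "stack"))
  expect_gte(min(vals), -1)
  expect_lte(max(vals), 1)
})

test_that("shared weights give identical scores for identical snippets", {
  bb <- build_backbone(seed = 2)
  enc <- synthetic_encodings(10, size = 64)
  snips <- sample_snippets(enc, consensus_config(k = 2))
  dup <- rep(snips[1], 4)
  sc <- snippet_scores(bb, dup)
  expect_equal(dim(sc$scores), c(4L, 2L))
  for (i in 2:4) expect_identical(sc$scores[i, ], sc$scores[1, ])
  expect_identical(sc$consensus, sc$scores[1, ])  # average of identical rows
  expect_equal(sum(sc$probabilities), 1, tolerance = 1e-12)

  one <- snippet_scores(bb, snips[1])
  expect_identical(one$consensus, one$scores[1, ])

  again <- snippet_scores(bb, dup)
  expect_identical(sc$scores, again$scores)
})

test_that("the average consensus is order-invariant and idempotent", {
  expect_equal(segmental_consensus(rbind(c(0, 1), c(1, 0))), c(0.5, 0.5))
  set.seed(6)
  sc <- matrix(rnorm(14), 7, 2)
  g0 <- segmental_consensus(sc)
  for (i in 1:20) {
    expect_equal(segmental_consensus(sc[sample(7), ]), g0, tolerance = 1e-12)
  }
  s <- c(0.3, -1.2)
  expect_equal(segmental_consensus(matrix(rep(s, each = 5), 5)), s)
  expect_error(segmental_consensus(matrix(0, 0, 2)), "empty")
})

test_that("the video loss equals softmax cross-entropy with its known values", {
  expect_equal(tsn_loss(c(0, 0), c(1, 0)), log(2), tolerance = 1e-12)
  expect_lt(tsn_loss(c(10, -10), c(1, 0)), 1e-8)
  expect_gt(tsn_loss(c(-5, 5), c(1, 0)), 9)
  expect_error(tsn_loss(c(0, 0, 0), c(1, 0)), "length")
  expect_error(tsn_loss(c(0, 0), c(1, 1)), "one-hot")
  set.seed(7)
  for (i in 1:25) {
    G <- rnorm(4, sd = 3)
    y <- as.numeric(seq_len(4) == sample(4, 1))
    expect_equal(tsn_loss(G, y), eq3_reference(G, y), tolerance = 1e-12)
    expect_equal(tsn_loss(G, y), -log(exp(G[y == 1]) / sum(exp(G))), tolerance = 1e-12)
  }
})

test_that("backbone training lowers the consensus loss and respects lr = 0 and seeds", {
  items <- lapply(1:6, function(i) {
    list(encodings = synthetic_encodings(12, size = 64, seed = i,
                                         scale = if (i <= 3) 1 else 6),
         label = if (i <= 3) "non-RWMA" else "RWMA")
  })
  bb <- build_backbone(seed = 9)
  tr <- train_backbone(bb, items, consensus_config(k = 2, sampling_mode = "random"),
                       epochs = 3, lr = 2e-3, seed = 4)
  h <- attr(tr, "loss_history")
  expect_lt(h[3], h[1])

  frozen <- train_backbone(bb, items, consensus_config(k = 2), epochs = 1,
                           lr = 0, seed = 4)
  expect_identical(frozen$params, bb$params)

  tr2 <- train_backbone(bb, items, consensus_config(k = 2, sampling_mode = "random"),
                        epochs = 3, lr = 2e-3, seed = 4)
  expect_identical(h, attr(tr2, "loss_history"))

  onecls <- items[1:3]
  expect_error(train_backbone(bb, onecls, epochs = 1), "single class")
})

test_that("extracted motion features are 1024-long, deterministic, and input-sensitive", {
  bb <- build_backbone(seed = 10)
  enc_still <- lapply(synthetic_encodings(12, size = 64, scale = 1), function(e) {
    e$x_frame[] <- 128L
    e$y_frame[] <- 128L
    e
  })
  enc_move <- synthetic_encodings(12, size = 64, seed = 2, scale = 8)
  f_still <- extract_features(bb, enc_still, consensus_config(k = 2), view = "A2C")
  f_move <- extract_features(bb, enc_move, consensus_config(k = 2), view = "A4C")
  expect_length(f_still$values, 1024L)
  expect_length(f_move$values, 1024L)
  expect_equal(f_still$view, "A2C")
  expect_gt(sqrt(sum((f_still$values - f_move$values)^2)), 0)
  expect_identical(f_move$values,
                   extract_features(bb, enc_move, consensus_config(k = 2),
                                    view = "A4C")$values)
})
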