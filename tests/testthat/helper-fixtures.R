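# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain transcriptions / brute-force loops, independent of the package's
# computation paths.

# small, fast phantom settings used throughout the unit tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(image_size = 64, frames_per_cycle = 8, n_cycles = 2,
         wall_thickness = 5, base_amplitude = 3, mid_radius = 18,
         speckle_sigma = 0.2),
    list(...)
  )
  do.call(phantom_config, args)
}

# memoized fixtures (generated once per test run)
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_sequence <- function() {
  fixture("tiny_sequence", function() {
    generate_sequence(tiny_config(seed = 11), view = "A4C")
  })
}

# smoothed random texture for flow tests
textured_image <- function(n = 128, seed = 9) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  k <- matrix(1 / 25, 5, 5)
  m <- as.matrix(EBImage::filter2(EBImage::Image(m), k))
  as.matrix(EBImage::filter2(EBImage::Image(m), k))
}

shift_image <- function(m, dr, dc) {
  out <- matrix(mean(m), nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# exhaustive integer block matching: the (dx, dy) minimizing the SSD between
# frame2 and frame1 shifted by (dx, dy), over |shift| <= max_shift
block_match_flow <- function(f1, f2, max_shift = 6) {
  best <- c(NA, NA)
  best_ssd <- Inf
  n <- nrow(f1)
  ctr <- (max_shift + 1):(n - max_shift)
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      diff <- f2[ctr, ctr] - f1[ctr - dy, ctr - dx]
      ssd <- sum(diff^2)
      if (ssd < best_ssd) {
        best_ssd <- ssd
        best <- c(dx, dy)
      }
    }
  }
  list(u = best[1], v = best[2])
}

# literal transcription of the video-level loss formula
eq3_reference <- function(G, y) {
  -sum(vapply(seq_along(G), function(i) y[i] * (G[i] - log(sum(exp(G)))), 0))
}

# brute-force pair counting for the confusion matrix
brute_confusion <- function(truth, pred, positive = "RWMA") {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == positive && pred[i] == positive) tp <- tp + 1L
    if (truth[i] != positive && pred[i] != positive) tn <- tn + 1L
    if (truth[i] != positive && pred[i] == positive) fp <- fp + 1L
    if (truth[i] == positive && pred[i] != positive) fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# O(n^2) concordance count: P(random positive outscores random negative),
# ties counted 1/2
brute_auc <- function(scores, truth, positive = "RWMA") {
  pos <- which(truth == positive)
  neg <- which(truth != positive)
  s <- 0
  for (i in pos) {
    for (j in neg) {
      s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  s / (length(pos) * length(neg))
}

# well-separated two-class gaussian features for classifier-bank tests;
# the class shift is concentrated on the first four features so both
# axis-aligned and distance-based learners can exploit it
gaussian_features <- function(n_per_class = 15, p = 24, sep = 2.5, seed = 4) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class)
  shift_cols <- seq_len(min(4, p))
  x[n_per_class + seq_len(n_per_class), shift_cols] <-
    x[n_per_class + seq_len(n_per_class), shift_cols] + sep / 2
  labels <- rep(c("non-RWMA", "RWMA"), each = n_per_class)
  list(x = x, labels = labels)
}

# synthetic encoded flow-pair list (random smooth fields), for TSN tests
synthetic_encodings <- function(n_pairs, size = 64, seed = 1, scale = 3) {
  set.seed(seed)
  lapply(seq_len(n_pairs), function(t) {
    f <- structure(list(u = matrix(rnorm(size^2, sd = scale), size),
                        v = matrix(rnorm(size^2, sd = scale), size), t = t),
                   class = "ef_flow_field")
    encode_flow_frames(f, clip = 20)
  })
}
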