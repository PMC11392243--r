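# Temporal-segment-network feature engineering: sparse snippet sampling
# over the flow-frame sequence, shared-weight per-snippet scoring,
# segmental consensus, the softmax cross-entropy video loss, training, and
# 1024-d motion-feature extraction.

#' Segmental consensus configuration
#'
#' @param k Number of equal-duration temporal segments (snippets per
#'   video); 7 by default.
#' @param consensus_fn Aggregation rule; `"average"` is the supported
#'   default.
#' @param sampling_mode `"random"` (training: random snippet offset within
#'   each segment) or `"center"` (inference: deterministic central offset).
#' @return A `consensus_config`.
#' @export
consensus_config <- function(k = 7L, consensus_fn = "average",
                             sampling_mode = c("center", "random")) {
  sampling_mode <- match.arg(sampling_mode)
  if (k < 1) stop_config("k", "must be >= 1")
  if (consensus_fn != "average") stop_config("consensus_fn", "must be 'average'")
  structure(list(k = as.integer(k), consensus_fn = consensus_fn,
                 sampling_mode = sampling_mode),
            class = "consensus_config")
}

snippet_frames_per_snippet <- function() 5L

#' Sparse snippet sampling
#'
#' Divides the ordered flow-frame pairs into `k` equal-duration temporal
#' segments and takes one snippet -- 5 consecutive pairs, stacked as a
#' 10-channel array (x, y interleaved per pair, rescaled to zero-centred
#' values in `[-1, 1]` with the no-motion code 128 at exactly 0) -- from
#' each segment, at a random (training) or central (inference) valid
#' offset.
#'
#' @param encodings List of `ef_flow_encoding` pairs in temporal order.
#' @param config A [consensus_config()].
#' @param seed Seed used for random offsets (training mode).
#' @return List of `k` `ef_snippet`s (fields `stack`, `segment_index`,
#'   `pair_indices`).
#' @export
sample_snippets <- function(encodings, config = consensus_config(), seed = NULL) {
  n <- length(encodings)
  k <- config$k
  m <- snippet_frames_per_snippet()
  if (n < k * m) {
    stop(sprintf("sequence has %d flow-frame pairs; snippet sampling with k = %d needs at least %d",
                 n, k, k * m))
  }
  bounds <- as.integer((seq_len(k) * n) %/% k)
  starts <- c(0L, bounds[-k]) + 1L
  offsets <- with_seed(seed, {
    vapply(seq_len(k), function(i) {
      len <- bounds[i] - starts[i] + 1L
      slack <- len - m
      if (config$sampling_mode == "random") {
        starts[i] + sample.int(slack + 1L, 1L) - 1L
      } else {
        starts[i] + slack %/% 2L
      }
    }, integer(1))
  })
  lapply(seq_len(k), function(i) {
    idx <- offsets[i] + seq_len(m) - 1L
    d <- dim(encodings[[idx[1]]]$x_frame)
    stack <- array(0, c(d[1], d[2], 2L * m))
    for (p in seq_len(m)) {
      e <- encodings[[idx[p]]]
      stack[, , 2L * p - 1L] <- (e$x_frame - 128) / 128
      stack[, , 2L * p] <- (e$y_frame - 128) / 128
    }
    structure(list(stack = stack, segment_index = i, pair_indices = idx),
              class = "ef_snippet")
  })
}

#' Per-snippet class scores and their consensus
#'
#' Scores every snippet with the shared-weight backbone, aggregates the
#' score vectors with the segmental consensus, and applies softmax.
#'
#' @param backbone An `ef_backbone`.
#' @param snippets List of `ef_snippet`s.
#' @return An `ef_snippet_scores`: `scores` (k x C matrix), `consensus`,
#'   and `probabilities` (softmax of the consensus).
#' @export
snippet_scores <- function(backbone, snippets) {
  if (length(snippets) == 0L) stop("no snippets given")
  sc <- t(vapply(snippets, function(s) backbone_forward(backbone, s$stack)$scores,
                 numeric(backbone$n_classes)))
  G <- segmental_consensus(sc)
  structure(list(scores = sc, consensus = G, probabilities = softmax(G)),
            class = "ef_snippet_scores")
}

#' Segmental consensus
#'
#' Element-wise average of per-snippet score vectors; invariant to snippet
#' order.
#'
#' @param scores Matrix (snippets x classes) or list of score vectors.
#' @param config A [consensus_config()] (only the average rule is defined).
#' @return Consensus score vector.
#' @export
segmental_consensus <- function(scores, config = consensus_config()) {
  if (is.list(scores)) scores <- do.call(rbind, scores)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (nrow(scores) == 0L) stop("consensus of an empty score set is undefined")
  colMeans(scores)
}

#' Video-level softmax cross-entropy loss
#'
#' `L(y, G) = -sum_i y_i (G_i - log sum_j exp G_j)` for a one-hot label
#' `y` over the consensus scores `G`; identical to the softmax
#' cross-entropy `-log p_true`.
#'
#' @param G Consensus score vector.
#' @param y One-hot label vector of the same length.
#' @return Scalar loss (>= 0).
#' @export
tsn_loss <- function(G, y) {
  if (length(G) != length(y)) stop("G and y differ in length")
  if (!all(y %in% c(0, 1)) || sum(y) != 1) stop("y must be one-hot")
  -sum(y * (G - log_sum_exp(G)))
}

#' Train the temporal backbone with segmental consensus
#'
#' TSN-style training: per labelled sequence, `k` snippets are sampled at
#' random offsets, scored with shared weights, averaged, and the consensus
#' cross-entropy gradient is split equally across snippets. One Adam step
#' per sequence; sequences are shuffled per epoch.
#'
#' @param backbone An `ef_backbone`.
#' @param items List of training items, each `list(encodings = <flow-frame
#'   pair list>, label = <class label>)`.
#' @param config A [consensus_config()] (k, sampling).
#' @param epochs Training epochs.
#' @param lr Adam learning rate; 0 leaves parameters unchanged.
#' @param seed Seed for shuffling and snippet offsets.
#' @param class_levels Class order mapped to score indices; defaults to the
#'   labels in byte (radix) order, independent of the locale.
#' @param verbose Print per-epoch loss.
#' @return Trained backbone with `loss_history` and `class_levels`
#'   attributes.
#' @export
train_backbone <- function(backbone, items, config = consensus_config(sampling_mode = "random"),
                           epochs = 3L, lr = 1e-3, seed = 1L,
                           class_levels = NULL, verbose = FALSE) {
  labels <- vapply(items, function(it) as.character(it$label), character(1))
  if (is.null(class_levels)) class_levels <- radix_sort(labels)
  if (length(class_levels) < 2L) {
    stop("training items contain a single class; need at least two")
  }
  if (length(class_levels) != backbone$n_classes) {
    stop("number of classes does not match the backbone head")
  }
  cfg <- config
  cfg$sampling_mode <- "random"
  flat <- nn_flatten_params(backbone$params)
  opt <- adam_init(flat)
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(items))
      losses <- numeric(length(ord))
      for (ii in seq_along(ord)) {
        it <- items[[ord[ii]]]
        snips <- sample_snippets(it$encodings, cfg,
                                 seed = sample.int(.Machine$integer.max, 1L))
        fws <- lapply(snips, function(s) backbone_forward(backbone, s$stack, want_cache = TRUE))
        sc <- t(vapply(fws, function(f) f$scores, numeric(backbone$n_classes)))
        G <- segmental_consensus(sc)
        y <- as.numeric(class_levels == it$label)
        losses[ii] <- tsn_loss(G, y)
        dG <- (softmax(G) - y) / length(snips)
        gacc <- NULL
        for (f in fws) {
          g <- backbone_backward(backbone, f$cache, dG)
          gflat <- nn_flatten_params(g)
          gacc <- if (is.null(gacc)) gflat else Map(`+`, gacc, gflat[names(gacc)])
        }
        if (lr > 0) {
          upd <- adam_step(flat, gacc[names(flat)], opt, lr = lr)
          flat <- upd$params
          opt <- upd$state
          backbone$params <- nn_unflatten_params(flat, backbone$params)
        }
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d: loss %.5f", ep, history[ep]))
    }
  })
  attr(backbone, "loss_history") <- history
  attr(backbone, "class_levels") <- class_levels
  backbone
}

#' Extract the 1024-d motion feature vector for one view sequence
#'
#' Deterministic inference path: `k` centrally sampled snippets, forward
#' through the backbone, and the segmental consensus (average) of the
#' penultimate-layer activations.
#'
#' @param backbone An `ef_backbone`.
#' @param encodings Flow-frame pair list for the sequence.
#' @param config A [consensus_config()].
#' @param view View tag stored on the result.
#' @return An `ef_motion_feature`: `values` (length 1024) and `view`.
#' @export
extract_features <- function(backbone, encodings, config = consensus_config(),
                             view = "A4C") {
  cfg <- config
  cfg$sampling_mode <- "center"
  snips <- sample_snippets(encodings, cfg)
  feats <- vapply(snips, function(s) backbone_forward(backbone, s$stack)$features,
                  numeric(backbone$feature_dim))
  structure(list(values = rowMeans(feats), view = view),
            class = "ef_motion_feature")
}
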