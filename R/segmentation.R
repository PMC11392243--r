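# Training and inference for the U-Net wall segmenter, plus pixel-wise
# evaluation against ground-truth masks.

#' Train a U-Net segmenter on labelled frames
#'
#' Per-frame Adam updates of pixel-wise softmax cross-entropy. Frames are
#' shuffled each epoch; everything is deterministic for a fixed seed (and
#' fixed BLAS/threading environment).
#'
#' @param segmenter An `ef_unet` from [build_segmenter()].
#' @param frames List of grayscale matrices in `[0, 1]` matching the
#'   segmenter's `input_size`.
#' @param masks List of binary matrices (1 = wall) paired with `frames`.
#' @param epochs Training epochs; 0 returns the segmenter unchanged.
#' @param lr Adam learning rate.
#' @param seed Seed controlling shuffling.
#' @param verbose Print per-epoch mean loss.
#' @return The trained segmenter, with a `loss_history` attribute (mean
#'   loss per epoch).
#' @export
train_segmenter <- function(segmenter, frames, masks, epochs = 10L, lr = 1e-3,
                            seed = 1L, verbose = FALSE) {
  stopifnot(inherits(segmenter, "ef_unet"))
  if (length(frames) == 0L) stop("training set is empty")
  if (length(frames) != length(masks)) stop("frames and masks differ in length")
  if (epochs == 0L) return(segmenter)

  flat <- nn_flatten_params(segmenter$params)
  opt <- adam_init(flat)
  history <- numeric(epochs)

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(frames))
      losses <- numeric(length(ord))
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        fw <- unet_forward(segmenter, frames[[i]], want_cache = TRUE)
        target <- masks[[i]] + 1L  # 1 = background, 2 = wall
        ce <- nn_pixel_ce(fw$logits, target)
        losses[ii] <- ce$loss
        g <- unet_backward(segmenter, fw$cache, ce$dlogits)
        gflat <- nn_flatten_params(g)
        upd <- adam_step(flat, gflat[names(flat)], opt, lr = lr)
        flat <- upd$params
        opt <- upd$state
        segmenter$params <- nn_unflatten_params(flat, segmenter$params)
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d: loss %.5f", ep, history[ep]))
    }
  })
  segmenter$epochs_trained <- segmenter$epochs_trained + epochs
  attr(segmenter, "loss_history") <- history
  segmenter
}

# foreground probability map for a single frame
unet_predict_prob <- function(segmenter, frame) {
  logits <- unet_forward(segmenter, frame)$logits
  d <- dim(logits)
  lm <- matrix(logits, d[1] * d[2], d[3])
  mx <- lm[, 1]
  for (k in seq_len(d[3])[-1]) mx <- pmax(mx, lm[, k])
  e <- exp(lm - mx)
  p <- e / rowSums(e)
  array(p, d)
}

# keep only the largest connected component of a binary mask
largest_component <- function(mask) {
  if (!any(mask > 0)) return(mask)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab == keep] <- 1L
  out
}

#' Segment an echo sequence
#'
#' Runs the segmenter on every frame, binarises the wall probability at 0.5,
#' keeps the largest connected component (suppressing speckle islands), and
#' zeroes the background of each frame.
#'
#' @param segmenter A trained `ef_unet`.
#' @param sequence An `echo_sequence` whose frames match the segmenter's
#'   input size.
#' @param threshold Foreground probability threshold.
#' @return List with `masks` (list of binary matrices) and `masked` (the
#'   sequence with background zeroed).
#' @export
segment_sequence <- function(segmenter, sequence, threshold = 0.5) {
  stopifnot(inherits(segmenter, "ef_unet"))
  frames <- sequence$frames
  sz <- segmenter$config$input_size
  for (t in seq_along(frames)) {
    if (!all(dim(frames[[t]]) == c(sz, sz))) {
      stop(sprintf("frame %d is %dx%d but the segmenter expects %dx%d",
                   t, nrow(frames[[t]]), ncol(frames[[t]]), sz, sz))
    }
  }
  masks <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    prob <- unet_predict_prob(segmenter, frames[[t]])
    fg <- prob[, , dim(prob)[3]]  # last class = wall
    m <- matrix(0L, sz, sz)
    m[fg >= threshold] <- 1L
    masks[[t]] <- largest_component(m)
  }
  list(masks = masks, masked = apply_masks(sequence, masks))
}

#' Apply binary masks to an echo sequence
#'
#' Multiplies each frame by its mask (background to zero). Idempotent:
#' applying the same masks twice leaves the frames unchanged.
#'
#' @param sequence An `echo_sequence`.
#' @param masks List of binary matrices, one per frame.
#' @return The masked `echo_sequence`.
#' @export
apply_masks <- function(sequence, masks) {
  if (length(masks) != length(sequence$frames)) {
    stop("need exactly one mask per frame")
  }
  out <- sequence
  for (t in seq_along(masks)) {
    if (!all(dim(masks[[t]]) == dim(sequence$frames[[t]]))) {
      stop(sprintf("mask %d does not match its frame's shape", t))
    }
    out$frames[[t]] <- sequence$frames[[t]] * masks[[t]]
  }
  out
}

#' Pixel-wise segmentation evaluation
#'
#' Pools pixel confusion counts over all frames (predicted vs ground-truth
#' wall masks) and reports sensitivity, precision, F1 and accuracy.
#'
#' @param predicted,truth Lists of binary matrices of equal length/shape.
#' @return A list with the pooled `confusion` counts, a `metrics` report
#'   (percent scale), and the mean per-frame Dice coefficient.
#' @export
evaluate_segmentation <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("mask counts differ")
  tp <- tn <- fp <- fn <- 0
  dice <- numeric(length(predicted))
  for (i in seq_along(predicted)) {
    p <- predicted[[i]]
    g <- truth[[i]]
    if (!all(dim(p) == dim(g))) stop(sprintf("mask %d shapes differ", i))
    tp_i <- sum(p == 1 & g == 1)
    fp_i <- sum(p == 1 & g == 0)
    fn_i <- sum(p == 0 & g == 1)
    tp <- tp + tp_i
    fp <- fp + fp_i
    fn <- fn + fn_i
    tn <- tn + sum(p == 0 & g == 0)
    dice[i] <- if (2 * tp_i + fp_i + fn_i == 0) 1 else 2 * tp_i / (2 * tp_i + fp_i + fn_i)
  }
  cm <- confusion_counts(tp, tn, fp, fn)
  list(confusion = cm, metrics = metrics(cm), dice = mean(dice))
}
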