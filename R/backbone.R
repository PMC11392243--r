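# Compact residual ConvNet backbone for the temporal (flow-stream) network.
# Input: one snippet, a (H, W, 10) stack of 5 consecutive horizontal/
# vertical flow-frame pairs. The penultimate activation -- the flattened
# 4x4x64 output of the final (adaptive) max pooling -- is the 1024-element
# motion feature vector; a linear head maps it to class scores. Sized for
# CPU training; an ImageNet-scale backbone is deliberately not shipped.

#' Build the temporal ConvNet backbone
#'
#' Architecture: 7x7/4 convolution (10 -> 16 channels), 2x2 max pool, two
#' residual blocks (16 -> 32 stride 2, 32 -> 64), adaptive 4x4 max pooling
#' and a linear head. The flattened pooled map has exactly
#' `4 * 4 * 64 = 1024` elements for any input size the pooling grid fits.
#'
#' @param in_channels Snippet channels (10 = 5 flow-frame pairs x 2
#'   components).
#' @param n_classes Output classes.
#' @param seed Weight initialisation seed.
#' @return An `ef_backbone` model.
#' @export
build_backbone <- function(in_channels = 10L, n_classes = 2L, seed = 1L) {
  params <- with_seed(seed, list(
    conv1 = nn_init_conv(7, 7, in_channels, 16),
    a1 = nn_init_conv(3, 3, 16, 32),
    a2 = nn_init_conv(3, 3, 32, 32),
    a_short = nn_init_conv(1, 1, 16, 32),
    b1 = nn_init_conv(3, 3, 32, 64),
    b2 = nn_init_conv(3, 3, 64, 64),
    b_short = nn_init_conv(1, 1, 32, 64),
    head = nn_init_linear(1024, n_classes)
  ))
  structure(list(params = params, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), feature_dim = 1024L),
            class = "ef_backbone")
}

backbone_forward <- function(model, x, want_cache = FALSE) {
  p <- model$params
  if (dim(x)[3] != model$in_channels) {
    stop(sprintf("snippet has %d channels but the backbone expects %d",
                 dim(x)[3], model$in_channels))
  }
  c1 <- nn_conv_fwd(x, p$conv1$w, p$conv1$b, 4L, 3L)
  r1 <- nn_relu(c1)
  pl <- nn_maxpool_fwd(r1, 2L, 2L, 2L, 2L)

  a1 <- nn_relu(nn_conv_fwd(pl$y, p$a1$w, p$a1$b, 2L, 1L))
  a2 <- nn_conv_fwd(a1, p$a2$w, p$a2$b, 1L, 1L)
  as_ <- nn_conv_fwd(pl$y, p$a_short$w, p$a_short$b, 2L, 0L)
  ra <- nn_relu(a2 + as_)

  b1 <- nn_relu(nn_conv_fwd(ra, p$b1$w, p$b1$b, 1L, 1L))
  b2 <- nn_conv_fwd(b1, p$b2$w, p$b2$b, 1L, 1L)
  bs <- nn_conv_fwd(ra, p$b_short$w, p$b_short$b, 1L, 0L)
  rb <- nn_relu(b2 + bs)

  ap <- nn_adaptive_maxpool_fwd(rb, 4L, 4L)
  features <- as.numeric(ap$y)
  scores <- as.numeric(features %*% p$head$w + p$head$b)
  cache <- NULL
  if (want_cache) {
    cache <- list(x = x, r1 = r1, pool = pl, a1 = a1, ra = ra, b1 = b1, rb = rb,
                  ap = ap, features = features)
  }
  list(scores = scores, features = features, cache = cache)
}

# dscores: gradient at the class scores; dfeatures: optional extra gradient
# injected directly at the feature vector
backbone_backward <- function(model, cache, dscores, dfeatures = NULL) {
  p <- model$params
  g <- list()
  g$head <- list(w = outer(cache$features, dscores),
                 b = dscores)
  dfeat <- as.numeric(p$head$w %*% dscores)
  if (!is.null(dfeatures)) dfeat <- dfeat + dfeatures
  dap <- array(dfeat, c(4, 4, 64))
  drb <- nn_maxpool_bwd(dap, cache$ap$idx, dim(cache$rb))
  drb <- nn_relu_bwd(drb, cache$rb)
  bw2 <- nn_conv_bwd(cache$b1, p$b2$w, drb, 1L, 1L)
  g$b2 <- list(w = bw2$dw, b = bw2$db)
  db1 <- nn_relu_bwd(bw2$dx, cache$b1)
  bw1 <- nn_conv_bwd(cache$ra, p$b1$w, db1, 1L, 1L)
  g$b1 <- list(w = bw1$dw, b = bw1$db)
  bws <- nn_conv_bwd(cache$ra, p$b_short$w, drb, 1L, 0L)
  g$b_short <- list(w = bws$dw, b = bws$db)
  dra <- bw1$dx + bws$dx
  dra <- nn_relu_bwd(dra, cache$ra)
  aw2 <- nn_conv_bwd(cache$a1, p$a2$w, dra, 1L, 1L)
  g$a2 <- list(w = aw2$dw, b = aw2$db)
  da1 <- nn_relu_bwd(aw2$dx, cache$a1)
  aw1 <- nn_conv_bwd(cache$pool$y, p$a1$w, da1, 2L, 1L)
  g$a1 <- list(w = aw1$dw, b = aw1$db)
  aws <- nn_conv_bwd(cache$pool$y, p$a_short$w, dra, 2L, 0L)
  g$a_short <- list(w = aws$dw, b = aws$db)
  dpool <- aw1$dx + aws$dx
  dr1 <- nn_maxpool_bwd(dpool, cache$pool$idx, dim(cache$r1))
  dr1 <- nn_relu_bwd(dr1, cache$r1)
  cw1 <- nn_conv_bwd(cache$x, p$conv1$w, dr1, 4L, 3L)
  g$conv1 <- list(w = cw1$dw, b = cw1$db)
  g
}
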