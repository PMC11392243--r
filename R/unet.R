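# U-Net: contracting path of double 3x3 convolutions with 2x2 max pooling,
# symmetric expansive path with nearest-neighbour upsampling + convolution
# and skip concatenations, and a final 1x1 classification convolution.
# Convolutions use "same" padding so the output mask has the input's size.
# At the default depth of 5 the network has 2*5 + 3*4 + 1 = 23 convolutional
# layers.

#' U-Net configuration
#'
#' @param depth Number of resolution levels (default 5 gives the classic
#'   23-convolution architecture).
#' @param base_channels Channels at the first level; doubled per level.
#' @param input_size Frame side length; must be divisible by
#'   `2^(depth - 1)`.
#' @param n_classes Output classes (2 = wall vs background).
#' @param in_channels Input channels (1 for grayscale echo frames).
#' @return A `unet_config` object.
#' @export
unet_config <- function(depth = 5L, base_channels = 64L, input_size = 224L,
                        n_classes = 2L, in_channels = 1L) {
  cfg <- list(depth = as.integer(depth), base_channels = as.integer(base_channels),
              input_size = as.integer(input_size), n_classes = as.integer(n_classes),
              in_channels = as.integer(in_channels))
  if (cfg$depth < 2) stop_config("depth", "must be >= 2")
  if (cfg$input_size %% 2^(cfg$depth - 1) != 0) {
    stop_config("input_size", sprintf("must be divisible by 2^(depth-1) = %d",
                                      2^(cfg$depth - 1)))
  }
  class(cfg) <- "unet_config"
  cfg
}

#' Build a U-Net segmenter
#'
#' Instantiates the contracting/expansive architecture with randomly
#' initialised (He-normal) weights.
#'
#' @param config A [unet_config()].
#' @param seed Seed for weight initialisation.
#' @return An `ef_unet` model object.
#' @export
build_segmenter <- function(config = unet_config(), seed = 1L) {
  if (!inherits(config, "unet_config")) config <- do.call(unet_config, config)
  d <- config$depth
  ch <- config$base_channels * 2^(seq_len(d) - 1)
  params <- with_seed(seed, {
    p <- list(enc = vector("list", d), dec = vector("list", d - 1))
    for (l in seq_len(d)) {
      cin <- if (l == 1) config$in_channels else ch[l - 1]
      p$enc[[l]] <- list(conv1 = nn_init_conv(3, 3, cin, ch[l]),
                         conv2 = nn_init_conv(3, 3, ch[l], ch[l]))
    }
    names(p$enc) <- paste0("enc", seq_len(d))
    for (l in seq_len(d - 1)) {
      p$dec[[l]] <- list(up = nn_init_conv(3, 3, ch[l + 1], ch[l]),
                         conv1 = nn_init_conv(3, 3, 2 * ch[l], ch[l]),
                         conv2 = nn_init_conv(3, 3, ch[l], ch[l]))
    }
    names(p$dec) <- paste0("dec", seq_len(d - 1))
    p$final <- nn_init_conv(1, 1, ch[1], config$n_classes)
    p
  })
  structure(list(config = config, params = params, epochs_trained = 0L),
            class = "ef_unet")
}

#' Count the convolutional layers of a segmenter
#'
#' Walks the parameter tree and counts 4-d weight arrays; used to assert
#' the architecture contract by introspection.
#'
#' @param model An `ef_unet`.
#' @return Integer layer count.
#' @export
count_conv_layers <- function(model) {
  n <- 0L
  walk <- function(p) {
    for (el in p) {
      if (is.list(el)) {
        if (!is.null(el$w) && length(dim(el$w)) == 4L) n <<- n + 1L else walk(el)
      }
    }
  }
  walk(model$params)
  n
}

unet_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] != cfg$input_size || dim(x)[2] != cfg$input_size) {
    stop(sprintf("frame is %dx%d but the segmenter expects %dx%d",
                 dim(x)[1], dim(x)[2], cfg$input_size, cfg$input_size))
  }
  cache <- list(x = x, enc = vector("list", d), pool = vector("list", d - 1),
                dec = vector("list", d - 1))
  cur <- x
  skips <- vector("list", d)
  for (l in seq_len(d)) {
    a1 <- nn_conv_fwd(cur, p$enc[[l]]$conv1$w, p$enc[[l]]$conv1$b, 1L, 1L)
    r1 <- nn_relu(a1)
    a2 <- nn_conv_fwd(r1, p$enc[[l]]$conv2$w, p$enc[[l]]$conv2$b, 1L, 1L)
    r2 <- nn_relu(a2)
    skips[[l]] <- r2
    if (want_cache) cache$enc[[l]] <- list(x_in = cur, r1 = r1, r2 = r2)
    if (l < d) {
      pl <- nn_maxpool_fwd(r2, 2L, 2L, 2L, 2L)
      if (want_cache) cache$pool[[l]] <- list(idx = pl$idx, xdim = dim(r2))
      cur <- pl$y
    }
  }
  cur <- skips[[d]]
  for (l in rev(seq_len(d - 1))) {
    up <- nn_upsample2_fwd(cur)
    ua <- nn_conv_fwd(up, p$dec[[l]]$up$w, p$dec[[l]]$up$b, 1L, 1L)
    ur <- nn_relu(ua)
    skip <- skips[[l]]
    cat_ <- array(0, c(dim(ur)[1], dim(ur)[2], dim(ur)[3] + dim(skip)[3]))
    cat_[, , seq_len(dim(ur)[3])] <- ur
    cat_[, , dim(ur)[3] + seq_len(dim(skip)[3])] <- skip
    a1 <- nn_conv_fwd(cat_, p$dec[[l]]$conv1$w, p$dec[[l]]$conv1$b, 1L, 1L)
    r1 <- nn_relu(a1)
    a2 <- nn_conv_fwd(r1, p$dec[[l]]$conv2$w, p$dec[[l]]$conv2$b, 1L, 1L)
    r2 <- nn_relu(a2)
    if (want_cache) {
      cache$dec[[l]] <- list(up = up, ur = ur, cat = cat_, r1 = r1, r2 = r2,
                             n_up = dim(ur)[3])
    }
    cur <- r2
  }
  logits <- nn_conv_fwd(cur, p$final$w, p$final$b, 1L, 0L)
  if (want_cache) cache$pre_final <- cur
  list(logits = logits, cache = if (want_cache) cache else NULL)
}

unet_backward <- function(model, cache, dlogits) {
  p <- model$params
  d <- model$config$depth
  g <- list(enc = vector("list", d), dec = vector("list", d - 1))
  names(g$enc) <- names(p$enc)
  names(g$dec) <- names(p$dec)

  bf <- nn_conv_bwd(cache$pre_final, p$final$w, dlogits, 1L, 0L)
  g$final <- list(w = bf$dw, b = bf$db)
  dcur <- bf$dx

  dskips <- vector("list", d)
  for (l in seq_len(d - 1)) {
    cc <- cache$dec[[l]]
    dr2 <- nn_relu_bwd(dcur, cc$r2)
    b2 <- nn_conv_bwd(cc$r1, p$dec[[l]]$conv2$w, dr2, 1L, 1L)
    dr1 <- nn_relu_bwd(b2$dx, cc$r1)
    b1 <- nn_conv_bwd(cc$cat, p$dec[[l]]$conv1$w, dr1, 1L, 1L)
    dcat <- b1$dx
    n_up <- cc$n_up
    dur <- dcat[, , seq_len(n_up), drop = FALSE]
    dskips[[l]] <- dcat[, , n_up + seq_len(dim(dcat)[3] - n_up), drop = FALSE]
    dua <- nn_relu_bwd(dur, cc$ur)
    bu <- nn_conv_bwd(cc$up, p$dec[[l]]$up$w, dua, 1L, 1L)
    g$dec[[l]] <- list(up = list(w = bu$dw, b = bu$db),
                       conv1 = list(w = b1$dw, b = b1$db),
                       conv2 = list(w = b2$dw, b = b2$db))
    dcur <- nn_upsample2_bwd(bu$dx)  # gradient w.r.t. the level-(l+1) output
  }
  dskips[[d]] <- dcur

  for (l in rev(seq_len(d))) {
    dr2 <- dskips[[l]]
    if (l < d) {
      # gradient arriving through the pooling path of the deeper level
      dpool <- nn_maxpool_bwd(g$pool_carry, cache$pool[[l]]$idx, cache$pool[[l]]$xdim)
      dr2 <- dr2 + dpool
    }
    cc <- cache$enc[[l]]
    dr2 <- nn_relu_bwd(dr2, cc$r2)
    b2 <- nn_conv_bwd(cc$r1, p$enc[[l]]$conv2$w, dr2, 1L, 1L)
    dr1 <- nn_relu_bwd(b2$dx, cc$r1)
    b1 <- nn_conv_bwd(cc$x_in, p$enc[[l]]$conv1$w, dr1, 1L, 1L)
    g$enc[[l]] <- list(conv1 = list(w = b1$dw, b = b1$db),
                       conv2 = list(w = b2$dw, b = b2$db))
    g$pool_carry <- b1$dx  # flows into the shallower level's pooled output
  }
  g$pool_carry <- NULL
  g
}
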