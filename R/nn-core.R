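# Shared pieces of the package's small network engine: parameter
# initialisation, the Adam optimizer, and elementwise ops. Convolution and
# pooling kernels live in src/nn.cpp. Models (U-Net segmenter, temporal
# backbone, MLP) hand-write their forward/backward passes on top of these.

nn_init_conv <- function(kh, kw, cin, cout) {
  # He-normal, fan_in = kh*kw*cin
  w <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

nn_init_linear <- function(n_in, n_out) {
  list(w = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

nn_relu <- function(x) nn_relu_cpp(x)

nn_relu_bwd <- function(dy, y) nn_relu_bwd_cpp(dy, y)

# Adam over a flat named list of parameter arrays. `state` is NULL on the
# first call. Gradients must mirror the structure of `params`.
adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# flatten nested parameter lists (e.g. params$enc1$conv1$w) into a flat
# named list for the optimizer, and back
nn_flatten_params <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p)) {
      out <- c(out, nn_flatten_params(p, key))
    } else {
      out[[key]] <- p
    }
  }
  out
}

nn_unflatten_params <- function(flat, skeleton) {
  assign_one <- function(sk, prefix) {
    for (nm in names(sk)) {
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      if (is.list(sk[[nm]])) {
        sk[[nm]] <- assign_one(sk[[nm]], key)
      } else {
        sk[[nm]] <- flat[[key]]
      }
    }
    sk
  }
  assign_one(skeleton, "")
}

# softmax cross-entropy over per-pixel class maps; logits (H, W, C),
# target integer matrix (H, W) with classes 1..C. Returns loss and dlogits.
nn_pixel_ce <- function(logits, target) {
  d <- dim(logits)
  n_px <- d[1] * d[2]
  lm <- matrix(logits, n_px, d[3])
  mx <- lm[, 1]
  for (k in seq_len(d[3])[-1]) mx <- pmax(mx, lm[, k])
  e <- exp(lm - mx)
  z <- rowSums(e)
  p <- e / z
  idx <- cbind(seq_len(n_px), as.integer(target))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dp <- p
  dp[idx] <- dp[idx] - 1
  dlogits <- array(dp / n_px, d)
  list(loss = loss, dlogits = dlogits, prob = array(p, d))
}
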