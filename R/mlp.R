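# Single-hidden-layer perceptron classifier used in the detection bank,
# built on the package's network engine (full-batch Adam on softmax
# cross-entropy). Handles wide inputs (2048 features) that quadratic-memory
# quasi-Newton fitters cannot.

mlp_fit <- function(x, y, hidden = 128L, epochs = 100L, lr = 1e-3, seed = 1L) {
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y, levels = radix_sort(y))
  lev <- levels(y)
  if (length(lev) != 2L) stop("MLP classifier expects two classes")
  yi <- as.integer(y)
  n <- nrow(x)
  onehot <- matrix(0, n, 2)
  onehot[cbind(seq_len(n), yi)] <- 1

  params <- with_seed(seed, list(l1 = nn_init_linear(ncol(x), hidden),
                                 l2 = nn_init_linear(hidden, 2L)))
  flat <- nn_flatten_params(params)
  opt <- adam_init(flat)
  for (ep in seq_len(epochs)) {
    h <- x %*% flat$l1.w
    h <- sweep(h, 2, flat$l1.b, "+")
    hr <- nn_relu(h)
    s <- sweep(hr %*% flat$l2.w, 2, flat$l2.b, "+")
    mx <- pmax(s[, 1], s[, 2])
    e <- exp(s - mx)
    p <- e / rowSums(e)
    ds <- (p - onehot) / n
    g <- list(l1.w = NULL, l1.b = NULL, l2.w = crossprod(hr, ds),
              l2.b = colSums(ds))
    dh <- ds %*% t(flat$l2.w)
    dh[hr <= 0] <- 0
    g$l1.w <- crossprod(x, dh)
    g$l1.b <- colSums(dh)
    upd <- adam_step(flat, g[names(flat)], opt, lr = lr)
    flat <- upd$params
    opt <- upd$state
  }
  structure(list(flat = flat, levels = lev, hidden = hidden), class = "ef_mlp")
}

mlp_prob <- function(model, x) {
  x <- as.matrix(x)
  h <- sweep(x %*% model$flat$l1.w, 2, model$flat$l1.b, "+")
  hr <- nn_relu(h)
  s <- sweep(hr %*% model$flat$l2.w, 2, model$flat$l2.b, "+")
  mx <- pmax(s[, 1], s[, 2])
  e <- exp(s - mx)
  p <- e / rowSums(e)
  colnames(p) <- model$levels
  p
}
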