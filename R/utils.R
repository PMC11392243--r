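# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic code in the package funnels through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

softmax <- function(x) {
  z <- x - max(x)
  e <- exp(z)
  e / sum(e)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# stack a list of equally sized matrices into an (H, W, T) array
frames_to_array <- function(frames) {
  stopifnot(length(frames) >= 1L)
  d <- dim(frames[[1]])
  arr <- array(0, c(d[1], d[2], length(frames)))
  for (t in seq_along(frames)) arr[, , t] <- frames[[t]]
  arr
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Locale-independent label orderings. Results must not depend on LC_COLLATE,
# so class levels are never ordered with locale collation: byte (radix)
# order is used, and where the positive class is known it is placed last
# (the usual control-first convention of binary classification).
radix_sort <- function(x) sort(unique(as.character(x)), method = "radix")

class_level_order <- function(labels, positive = NULL) {
  lev <- radix_sort(labels)
  if (!is.null(positive) && positive %in% lev) {
    lev <- c(setdiff(lev, positive), positive)
  }
  lev
}
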