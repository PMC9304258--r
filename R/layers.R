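# Layer primitives and parameter-tree utilities for the network.
#
# Tensors are (H, W, C, N) arrays; convolution weights are (k*k*Cin) x Cout
# matrices (kernel-row fastest, then kernel-col, then input channel) matching
# the C++ kernels. Parameters live in nested lists whose numeric leaves are
# the trainables; tree utilities below map elementwise over them.

conv_param <- function(cin, cout, k = 3L, stride = 1L, pad = 1L) {
  # He-style initialization for PReLU-activated convolutions
  w <- matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
              k * k * cin, cout)
  list(w = w, b = numeric(cout), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}

deconv_param <- function(cin, cout, k = 4L, stride = 2L, pad = 1L) {
  w <- matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
              k * k * cin, cout)
  list(w = w, b = numeric(cout), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}

conv_f <- function(x, p) nn_conv_fwd(x, p$w, p$b, p$k, p$stride, p$pad)
conv_b <- function(x, p, dy) nn_conv_bwd(x, p$w, dy, p$k, p$stride, p$pad)
deconv_f <- function(x, p) nn_deconv_fwd(x, p$w, p$b, p$k, p$stride, p$pad)
deconv_b <- function(x, p, dy) nn_deconv_bwd(x, p$w, dy, p$k, p$stride, p$pad)

prelu_f <- function(x, a) nn_prelu_fwd(x, a)

# returns list(dx, da); z is the pre-activation
prelu_b <- function(z, a, dy) nn_prelu_bwd(z, a, dy)

sigmoid_f <- function(x) 1 / (1 + exp(-x))

# concatenate (H,W,C,N) arrays along the channel axis
cat4 <- function(lst) {
  if (length(lst) == 1L) return(lst[[1L]])
  nn_cat_channels(lst)
}

# split along the channel axis into chunks of the given widths
split4 <- function(x, widths) nn_split_channels(x, as.integer(widths))

# --- parameter-tree utilities -----------------------------------------------
# Trainable leaves are the numeric entries named w (weights), b (biases) or
# a (PReLU slopes); structural scalars (k, stride, pad) are left untouched.
TRAINABLE_NAMES <- c("w", "b", "a")

p_walk <- function(params, grads, state_m, state_v, f) {
  # recursively update trainable leaves; returns list(params, m, v)
  if (is.list(params)) {
    for (nm in names(params)) {
      if (nm %in% TRAINABLE_NAMES && is.numeric(params[[nm]])) {
        r <- f(params[[nm]], grads[[nm]], state_m[[nm]], state_v[[nm]])
        params[[nm]] <- r$p; state_m[[nm]] <- r$m; state_v[[nm]] <- r$v
      } else if (is.list(params[[nm]])) {
        r <- p_walk(params[[nm]], grads[[nm]], state_m[[nm]], state_v[[nm]], f)
        params[[nm]] <- r$params; state_m[[nm]] <- r$m; state_v[[nm]] <- r$v
      }
    }
  }
  list(params = params, m = state_m, v = state_v)
}

p_zero_like <- function(params) {
  if (is.list(params)) {
    out <- params
    for (nm in names(params)) {
      if (nm %in% TRAINABLE_NAMES && is.numeric(params[[nm]])) {
        out[[nm]] <- params[[nm]] * 0
      } else if (is.list(params[[nm]])) {
        out[[nm]] <- p_zero_like(params[[nm]])
      }
    }
    return(out)
  }
  params
}

p_count <- function(params) {
  if (is.list(params)) {
    s <- 0
    for (nm in names(params)) {
      if (nm %in% TRAINABLE_NAMES && is.numeric(params[[nm]])) {
        s <- s + length(params[[nm]])
      } else if (is.list(params[[nm]])) {
        s <- s + p_count(params[[nm]])
      }
    }
    return(s)
  }
  0
}

# deterministic checksum over trainable leaves (reproducibility tests)
p_checksum <- function(params) {
  acc <- 0
  walk <- function(p) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (nm %in% TRAINABLE_NAMES && is.numeric(p[[nm]])) {
          acc <<- acc + sum(p[[nm]] * seq_along(p[[nm]]))
        } else if (is.list(p[[nm]])) walk(p[[nm]])
      }
    }
  }
  walk(params)
  acc
}
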