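# Small dilated-convolution residual network: the denoising regressor used by
# the Noise2Inverse trainer. Convolutions are expressed as sums of shifted
# feature maps times channel-mixing matrices, so forward and backward passes
# run through BLAS matrix products; gradients are hand-derived and exact.

#' Network architecture recipe
#'
#' A compact convolutional network in the spirit of mixed-scale dense nets:
#' a chain of 3x3 dilated convolutions with ReLU activations whose dilation
#' grows along the chain (capturing both fine and coarse noise structure with
#' few parameters), closed by a 1x1 projection added to the input (residual).
#' The final projection is zero-initialized, so an untrained network is
#' exactly the identity; training learns the noise to subtract.
#'
#' @param channels feature channels per hidden layer (`"sequential"`) or new
#'   feature maps added per layer (`"msd"` width).
#' @param depth number of hidden 3x3 layers.
#' @param dilations dilation per hidden layer (recycled to `depth`).
#' @param architecture `"sequential"` (plain chain) or `"msd"` (mixed-scale
#'   dense: every layer convolves the concatenation of the input and all
#'   previous feature maps, the architecture family the study's denoiser
#'   follows).
#' @param patch_size side of the square training crops.
#' @param crops_per_pair random crops drawn from each pair and slice per
#'   epoch.
#' @param lr Adam learning rate.
#' @return object of class `n2i_net_config`.
#' @export
n2i_net_config <- function(channels = 8L, depth = 4L,
                           dilations = c(1L, 2L, 3L, 4L),
                           architecture = c("sequential", "msd"),
                           patch_size = 32L, crops_per_pair = 4L, lr = 1e-3) {
  architecture <- match.arg(architecture)
  stopifnot_scalar(channels, "channels", min = 1, integer = TRUE)
  stopifnot_scalar(depth, "depth", min = 1, integer = TRUE)
  stopifnot_scalar(crops_per_pair, "crops_per_pair", min = 1, integer = TRUE)
  dil <- as.integer(rep_len(dilations, depth))
  structure(list(channels = as.integer(channels), depth = as.integer(depth),
                 dilations = dil, architecture = architecture,
                 patch_size = as.integer(patch_size),
                 crops_per_pair = as.integer(crops_per_pair), lr = lr),
            class = "n2i_net_config")
}

# Per-layer input/output channel counts for either architecture.
net_layer_dims <- function(config) {
  C <- config$channels
  if (config$architecture == "msd") {
    cin <- 1L + (seq_len(config$depth) - 1L) * C
    list(cin = cin, cout = rep(C, config$depth),
         n_final = 1L + config$depth * C)
  } else {
    list(cin = c(1L, rep(C, config$depth - 1L)),
         cout = rep(C, config$depth), n_final = C)
  }
}

# Parameter count (for documentation and sanity checks).
net_n_params <- function(config) {
  d <- net_layer_dims(config)
  sum(9 * d$cin * d$cout + d$cout) + d$n_final + 1L
}

# He-scaled random initialization; the output 1x1 conv starts at zero so the
# net is the identity map at epoch 0. Draws from the caller's RNG stream.
net_init <- function(config) {
  d <- net_layer_dims(config)
  layers <- vector("list", config$depth)
  for (l in seq_len(config$depth)) {
    cin <- d$cin[l]; cout <- d$cout[l]
    sd <- sqrt(2 / (9 * cin))
    layers[[l]] <- list(
      W = array(stats::rnorm(9 * cin * cout, sd = sd), c(3, 3, cin, cout)),
      b = numeric(cout),
      dil = config$dilations[l])
  }
  list(layers = layers,
       out = list(W = matrix(0, d$n_final, 1), b = 0),
       config = config)
}

# Shift a [ny, nx, C] stack by (di, dj) with zero fill.
.shift3 <- function(x, di, dj) {
  d <- dim(x)
  out <- array(0, d)
  i_dst <- max(1, 1 + di):min(d[1], d[1] + di)
  j_dst <- max(1, 1 + dj):min(d[2], d[2] + dj)
  if (length(i_dst) && length(j_dst))
    out[i_dst, j_dst, ] <- x[i_dst - di, j_dst - dj, , drop = FALSE]
  out
}

.flat <- function(x) matrix(x, prod(dim(x)[1:2]), dim(x)[3])

# One dilated 3x3 convolution via shifted BLAS products.
.conv3 <- function(h, W, b, dil) {
  d <- dim(h)[1:2]
  C_out <- dim(W)[4]
  zm <- matrix(rep(b, each = prod(d)), prod(d), C_out)
  for (ki in 1:3) for (kj in 1:3) {
    s <- .shift3(h, (ki - 2L) * dil, (kj - 2L) * dil)
    zm <- zm + .flat(s) %*% W[ki, kj, , ]
  }
  array(zm, c(d, C_out))
}

# Forward pass; returns prediction and the activations needed for backprop.
# "sequential": h_l feeds only layer l+1. "msd": each layer convolves the
# concatenation of the input and all previous feature maps (mixed-scale
# dense), and the 1x1 output reads the whole stack.
net_forward <- function(params, x, keep = FALSE) {
  d <- c(dim(x), 1L)[1:2]
  msd <- identical(params$config$architecture, "msd")
  h <- array(x, c(d, 1L))
  acts <- if (keep) list(h) else NULL
  pre <- if (keep) vector("list", length(params$layers)) else NULL
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    z <- .conv3(h, ly$W, ly$b, ly$dil)
    if (keep) pre[[l]] <- z
    new <- pmax(z, 0)
    h <- if (msd) {
      hh <- array(0, c(d, dim(h)[3] + dim(new)[3]))
      hh[, , seq_len(dim(h)[3])] <- h
      hh[, , dim(h)[3] + seq_len(dim(new)[3])] <- new
      hh
    } else new
    if (keep) acts[[l + 1L]] <- h
  }
  y <- matrix(.flat(h) %*% params$out$W + params$out$b, d[1], d[2]) + x
  if (keep) list(y = y, acts = acts, pre = pre) else y
}

# Gradient of one convolution: weight/bias gradients plus the gradient
# pushed back onto the layer's input stack.
.conv3_grad <- function(h_prev, dz, W, dil, want_input_grad = TRUE) {
  d <- dim(h_prev)[1:2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  dzm <- .flat(dz)
  gW <- array(0, dim(W))
  for (ki in 1:3) for (kj in 1:3) {
    s <- .shift3(h_prev, (ki - 2L) * dil, (kj - 2L) * dil)
    gW[ki, kj, , ] <- crossprod(.flat(s), dzm)
  }
  dh <- NULL
  if (want_input_grad) {
    dh <- array(0, c(d, cin))
    for (ki in 1:3) for (kj in 1:3) {
      back <- array(dzm %*% t(matrix(W[ki, kj, , ], cin, cout)), c(d, cin))
      dh <- dh + .shift3(back, -(ki - 2L) * dil, -(kj - 2L) * dil)
    }
  }
  list(W = gW, b = colSums(dzm), input = dh)
}

# Backward pass for 0.5 * mean((y - target)^2); returns gradients shaped
# like the parameters.
net_backward <- function(params, fw, target) {
  d <- dim(fw$y)
  npix <- prod(d)
  msd <- identical(params$config$architecture, "msd")
  dy <- (fw$y - target) / npix                       # d loss / d y
  last <- fw$acts[[length(fw$acts)]]
  g_out <- list(W = crossprod(.flat(last), as.vector(dy)), b = sum(dy))
  dstack <- array(as.vector(dy) %*% t(params$out$W), c(d, nrow(params$out$W)))
  g_layers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    cout <- dim(ly$W)[4]
    if (msd) {
      n_prev <- dim(fw$acts[[l]])[3]
      dnew <- dstack[, , n_prev + seq_len(cout), drop = FALSE]
      dz <- dnew * (fw$pre[[l]] > 0)
      g <- .conv3_grad(fw$acts[[l]], dz, ly$W, ly$dil,
                       want_input_grad = TRUE)
      g_layers[[l]] <- list(W = g$W, b = g$b)
      # dense connectivity: gradient flows both around and through the layer
      dstack <- dstack[, , seq_len(n_prev), drop = FALSE] + g$input
    } else {
      dz <- dstack * (fw$pre[[l]] > 0)
      g <- .conv3_grad(fw$acts[[l]], dz, ly$W, ly$dil,
                       want_input_grad = l > 1L)
      g_layers[[l]] <- list(W = g$W, b = g$b)
      if (l > 1L) dstack <- g$input
    }
  }
  list(layers = g_layers, out = g_out)
}

# In-place-style Adam update; state carries first/second moments and step.
adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params[c("layers", "out")]),
       v = zero_like(params[c("layers", "out")]), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(params$layers)) {
    for (nm in c("W", "b")) {
      u <- upd(params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$m$layers[[l]][[nm]], state$v$layers[[l]][[nm]])
      params$layers[[l]][[nm]] <- u$p
      state$m$layers[[l]][[nm]] <- u$m
      state$v$layers[[l]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(params$out[[nm]], grads$out[[nm]],
             state$m$out[[nm]], state$v$out[[nm]])
    params$out[[nm]] <- u$p
    state$m$out[[nm]] <- u$m
    state$v$out[[nm]] <- u$v
  }
  list(params = params, state = state)
}
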