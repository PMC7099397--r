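#' Classifier architecture configuration
#'
#' Two variants are provided. The \code{baseline} operates on 256 Hz
#' spectrograms with two convolution layers (11 filters of 3x11 then 11 of
#' 3x3, stride 1) followed by two vanilla recurrent layers; the
#' \code{lightweight} operates on 64 Hz spectrograms with a single 3x5x11
#' convolution and fused recurrent layers. Kernel sizes are
#' (frequency x time); batch normalization follows every layer. The
#' \code{full} profile uses 1760 hidden units per recurrent layer; the
#' \code{desk} profile (default) uses 64, suitable for CPU-scale
#' experiments.
#'
#' @param variant "baseline" or "lightweight"
#' @param profile "desk" (hidden = 64) or "full" (hidden = 1760;
#'   long-running, intended for GPU-class budgets)
#' @param rnn_hidden override the profile's hidden width
#' @param rnn_mode "reference" (stepwise) or "fused"; both compute the
#'   same recurrence
#' @return a \code{model_config} list
#' @export
model_config <- function(variant = c("lightweight", "baseline"),
                         profile = c("desk", "full"),
                         rnn_hidden = NULL, rnn_mode = NULL) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  hidden <- rnn_hidden %||% if (profile == "full") 1760L else 64L
  if (variant == "baseline") {
    conv <- list(list(kf = 3L, kt = 11L, filters = 11L, stride = 1L),
                 list(kf = 3L, kt = 3L, filters = 11L, stride = 1L))
    rate <- 256
    mode <- rnn_mode %||% "reference"
  } else {
    conv <- list(list(kf = 3L, kt = 5L, filters = 11L, stride = 1L))
    rate <- 64
    mode <- rnn_mode %||% "fused"
  }
  stopifnot(mode %in% c("reference", "fused"))
  structure(list(variant = variant, profile = profile,
                 sampling_rate = rate, conv_layers = conv,
                 rnn_layers = 2L, rnn_hidden = as.integer(hidden),
                 rnn_mode = mode, output_classes = 5L),
            class = "model_config")
}

#' Training recipe configuration
#'
#' Full-scale defaults follow the published recipe (baseline: learning
#' rate 5e-6, batch 1000, 400 epochs; lightweight: 1e-5, batch 900, 300
#' epochs; Xavier initialization, Adam, per-epoch normal-class
#' rebalancing, checkpoint selection by mean validation accuracy over the
#' N/S/V classes). The \code{desk} profile shrinks the schedule to a
#' CPU-scale run.
#'
#' @param variant "baseline" or "lightweight"
#' @param profile "desk" or "full"
#' @param learning_rate,batch_size,epochs optional overrides
#' @param validation_fraction held-out fraction for checkpoint selection
#' @param rebalance per-epoch majority-class downsampling on/off
#' @param seed base seed for initialization, shuffling and rebalancing
#' @return a \code{train_config} list
#' @export
train_config <- function(variant = c("lightweight", "baseline"),
                         profile = c("desk", "full"),
                         learning_rate = NULL, batch_size = NULL,
                         epochs = NULL, validation_fraction = 0.15,
                         rebalance = TRUE, seed = 1L) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  if (profile == "full") {
    lr <- if (variant == "baseline") 5e-6 else 1e-5
    bs <- if (variant == "baseline") 1000L else 900L
    ep <- if (variant == "baseline") 400L else 300L
  } else {
    lr <- 2e-3; bs <- 256L; ep <- 30L
  }
  structure(list(init = "xavier", optimizer = "adam",
                 learning_rate = learning_rate %||% lr,
                 batch_size = as.integer(batch_size %||% bs),
                 epochs = as.integer(epochs %||% ep),
                 validation_fraction = validation_fraction,
                 rebalance = rebalance,
                 selection_classes = c("N", "S", "V"),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Parameter count of a configured network
#'
#' Closed-form count of trainable parameters (convolution kernels and
#' biases, batch-norm scales/offsets, recurrent input/recurrent/bias
#' weights, output layer) for a given input frequency-bin count.
#'
#' @param config a \code{\link{model_config}}
#' @param n_bins spectrogram frequency bins at the network input
#' @return integer parameter count
#' @export
n_parameters <- function(config, n_bins = NULL) {
  n_bins <- n_bins %||% (stft_params(config$sampling_rate)$window %/% 2 + 1)
  total <- 0L
  f <- n_bins; ci <- 1L
  for (cl in config$conv_layers) {
    total <- total + cl$kf * cl$kt * ci * cl$filters + cl$filters +
      2L * cl$filters
    f <- f - cl$kf + 1L
    ci <- cl$filters
  }
  d <- f * ci
  h <- config$rnn_hidden
  for (l in seq_len(config$rnn_layers)) {
    total <- total + d * h + h * h + h + 2L * h
    d <- h
  }
  total + h * config$output_classes + config$output_classes
  }

# Build initialized weights. Returns list(params, running) where running
# holds the batch-norm moving statistics (not optimized).
build_beat_net <- function(config, n_bins, seed = 1L) {
  f <- n_bins
  for (cl in config$conv_layers) {
    f <- f - cl$kf + 1L
    if (f < 1L)
      stopf("input with %d frequency bins incompatible with conv kernels",
            n_bins)
  }
  set.seed(seed)
  params <- list(); running <- list()
  ci <- 1L; f <- n_bins
  for (k in seq_along(config$conv_layers)) {
    cl <- config$conv_layers[[k]]
    fan_in <- cl$kf * cl$kt * ci
    fan_out <- cl$kf * cl$kt * cl$filters
    params[[paste0("conv", k, "_w")]] <-
      array(xavier_init(fan_in, fan_out, cl$kf * cl$kt * ci * cl$filters),
            c(cl$kf, cl$kt, ci, cl$filters))
    params[[paste0("conv", k, "_b")]] <- numeric(cl$filters)
    params[[paste0("conv", k, "_g")]] <- rep(1, cl$filters)
    params[[paste0("conv", k, "_be")]] <- numeric(cl$filters)
    running[[paste0("conv", k)]] <- list(mean = numeric(cl$filters),
                                         var = rep(1, cl$filters))
    ci <- cl$filters; f <- f - cl$kf + 1L
  }
  d <- f * ci
  h <- config$rnn_hidden
  for (l in seq_len(config$rnn_layers)) {
    params[[paste0("rnn", l, "_wx")]] <- matrix(xavier_init(d, h, d * h), d, h)
    params[[paste0("rnn", l, "_wh")]] <- matrix(xavier_init(h, h, h * h), h, h)
    params[[paste0("rnn", l, "_b")]] <- numeric(h)
    params[[paste0("rnn", l, "_g")]] <- rep(1, h)
    params[[paste0("rnn", l, "_be")]] <- numeric(h)
    running[[paste0("rnn", l)]] <- list(mean = numeric(h), var = rep(1, h))
    d <- h
  }
  params$out_w <- matrix(xavier_init(h, config$output_classes,
                                     h * config$output_classes),
                         h, config$output_classes)
  params$out_b <- numeric(config$output_classes)
  list(params = params, running = running, n_bins = n_bins)
}

# reshape helpers between (F,T,C,B) conv space and (positions x channels)
conv_to_mat <- function(z) {
  d <- dim(z)
  m <- aperm(z, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}
mat_to_conv <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1, 2, 4, 3))
}

# valid-position mask for conv space (F,T,C,B) collapsed rows (f,t,b)
conv_valid_mask <- function(Fo, Tt, lengths) {
  tm <- outer(seq_len(Tt), lengths, `<=`)     # T x B
  rep_f <- tm[rep(seq_len(Tt), each = Fo), , drop = FALSE]  # (F*T) x B
  as.vector(rep_f)
}

rnn_valid_mask <- function(B, Tt, lengths) {
  # rows of the (B*T x H) matrix are b fastest, then t
  as.vector(outer(seq_len(B), seq_len(Tt),
                  function(b, t) t <= lengths[b]))
}

# Full forward pass. batch: (bins, T, B); lengths: true frame counts.
beat_net_forward <- function(net, config, batch, lengths, training = FALSE) {
  d <- dim(batch)
  Tt <- d[2]; B <- d[3]
  x <- array(batch, c(d[1], Tt, 1L, B))
  cache <- list(conv = list())
  p <- net$params
  for (k in seq_along(config$conv_layers)) {
    z <- conv2d_forward(x, p[[paste0("conv", k, "_w")]],
                        p[[paste0("conv", k, "_b")]])
    dz <- dim(z)
    zm <- conv_to_mat(z)
    valid <- conv_valid_mask(dz[1], dz[2], lengths)
    bn <- bn_forward(zm, p[[paste0("conv", k, "_g")]],
                     p[[paste0("conv", k, "_be")]], valid,
                     net$running[[paste0("conv", k)]], training)
    if (training) net$running[[paste0("conv", k)]] <- bn$running
    a <- pmax(bn$y, 0)
    a[!valid, ] <- 0                      # mask padded frames
    cache$conv[[k]] <- list(x = x, zdim = dz, bn = bn, valid = valid,
                            act = a)
    x <- mat_to_conv(a, dz)
  }
  dz <- dim(x)                            # (F', T, C, B)
  u <- aperm(x, c(4, 1, 3, 2))            # (B, F', C, T)
  dim(u) <- c(B, dz[1] * dz[3], Tt)       # (B, D, T)
  cache$u_dim <- dz
  h_in <- u
  cache$rnn <- list()
  for (l in seq_len(config$rnn_layers)) {
    w <- list(Wx = p[[paste0("rnn", l, "_wx")]],
              Wh = p[[paste0("rnn", l, "_wh")]],
              b = p[[paste0("rnn", l, "_b")]])
    h <- if (config$rnn_mode == "fused" || training)
      rnn_forward_fused(h_in, w) else rnn_forward_reference(h_in, w)
    hm <- aperm(h, c(1, 3, 2)); dim(hm) <- c(B * Tt, config$rnn_hidden)
    valid <- rnn_valid_mask(B, Tt, lengths)
    bn <- bn_forward(hm, p[[paste0("rnn", l, "_g")]],
                     p[[paste0("rnn", l, "_be")]], valid,
                     net$running[[paste0("rnn", l)]], training)
    if (training) net$running[[paste0("rnn", l)]] <- bn$running
    hn <- array(bn$y, c(B, Tt, config$rnn_hidden))
    hn <- aperm(hn, c(1, 3, 2))           # (B, H, T)
    cache$rnn[[l]] <- list(x = h_in, h = h, bn = bn, valid = valid, w = w)
    h_in <- hn
  }
  s <- matrix(0, B, config$rnn_hidden)
  for (b in seq_len(B)) s[b, ] <- h_in[b, , lengths[b]]
  logits <- sweep(s %*% p$out_w, 2, p$out_b, `+`)
  probs <- softmax_rows(logits)
  cache$s <- s
  cache$B <- B; cache$Tt <- Tt; cache$lengths <- lengths
  list(probs = probs, cache = cache, net = net)
}

# Backward pass; y is an index vector (1..5) aligned with the batch.
beat_net_backward <- function(net, config, cache, probs, y) {
  p <- net$params
  B <- cache$B; Tt <- cache$Tt; H <- config$rnn_hidden
  lengths <- cache$lengths
  grads <- lapply(p, function(q) q * 0)
  dlog <- probs
  dlog[cbind(seq_len(B), y)] <- dlog[cbind(seq_len(B), y)] - 1
  dlog <- dlog / B
  grads$out_w <- crossprod(cache$s, dlog)
  grads$out_b <- colSums(dlog)
  ds <- dlog %*% t(p$out_w)
  # scatter final-state gradient into the top recurrent layer's BN output
  dhn <- matrix(0, B * Tt, H)             # rows b-fastest then t
  dhn[(lengths - 1L) * B + seq_len(B), ] <- ds
  for (l in rev(seq_len(config$rnn_layers))) {
    rc <- cache$rnn[[l]]
    bnb <- bn_backward(dhn, rc$bn, p[[paste0("rnn", l, "_g")]], rc$valid)
    grads[[paste0("rnn", l, "_g")]] <- bnb$dgamma
    grads[[paste0("rnn", l, "_be")]] <- bnb$dbeta
    dh <- array(bnb$dx, c(B, Tt, H))
    dh <- aperm(dh, c(1, 3, 2))           # (B, H, T)
    rb <- rnn_backward(rc$x, rc$h, rc$w, dh)
    grads[[paste0("rnn", l, "_wx")]] <- rb$dWx
    grads[[paste0("rnn", l, "_wh")]] <- rb$dWh
    grads[[paste0("rnn", l, "_b")]] <- rb$db
    if (l > 1L) {
      dhn <- aperm(rb$dx, c(1, 3, 2))
      dim(dhn) <- c(B * Tt, H)
    } else {
      du <- rb$dx                          # (B, D, T)
    }
  }
  dz <- cache$u_dim                        # (F', T, C, B)
  dim(du) <- c(B, dz[1], dz[3], Tt)
  dx <- aperm(du, c(2, 4, 3, 1))           # (F', T, C, B)
  for (k in rev(seq_along(config$conv_layers))) {
    cc <- cache$conv[[k]]
    da <- conv_to_mat(dx)
    da[!cc$valid, ] <- 0
    da <- da * (cc$act > 0)                # ReLU gradient (post-mask act)
    bnb <- bn_backward(da, cc$bn, p[[paste0("conv", k, "_g")]], cc$valid)
    grads[[paste0("conv", k, "_g")]] <- bnb$dgamma
    grads[[paste0("conv", k, "_be")]] <- bnb$dbeta
    dzm <- mat_to_conv(bnb$dx, cc$zdim)
    cb <- conv2d_backward(cc$x, p[[paste0("conv", k, "_w")]], dzm)
    grads[[paste0("conv", k, "_w")]] <- cb$dw
    grads[[paste0("conv", k, "_b")]] <- cb$db
    dx <- cb$dx
    dim(dx) <- dim(cc$x)
  }
  grads
}

cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}
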