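#' Train a beat classifier
#'
#' Fits the configured convolutional-recurrent network to labeled
#' spectrogram segments. Each epoch the normal (N) class is freshly
#' downsampled to the non-N total (\code{\link{rebalance_epoch}});
#' instances are grouped into length buckets and zero-padded per bucket;
#' optimization is Adam on the softmax cross-entropy. After every epoch
#' the held-out split is scored and the checkpoint with the highest mean
#' validation accuracy over the N, S and V classes is retained. A fixed
#' seed makes the whole run reproducible.
#'
#' @param x list of spectrogram matrices (frequency bins x frames), e.g.
#'   the \code{spectrogram} fields of \code{\link{preprocess_record}}
#'   segments
#' @param labels AAMI class per instance ("N","S","V","F","Q")
#' @param model a \code{\link{model_config}}
#' @param train a \code{\link{train_config}}
#' @param verbose print a line per epoch
#' @return an object of class \code{beat_rnn} with elements
#'   \code{params}, \code{running} (batch-norm statistics),
#'   \code{model}, \code{train}, \code{history} (per-epoch loss and
#'   per-class validation accuracy), \code{best_epoch}, \code{classes}
#' @export
#' @seealso \code{\link{predict.beat_rnn}}
train_beat_classifier <- function(x, labels,
                                  model = model_config("lightweight"),
                                  train = train_config("lightweight"),
                                  verbose = FALSE) {
  stopifnot(is.list(x), length(x) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% AAMI_CLASSES))
    stopf("labels outside the AAMI class alphabet")
  if (length(unique(labels)) < 2L)
    stopf("training needs at least 2 classes")
  n_bins <- nrow(x[[1]])
  lens <- vapply(x, ncol, integer(1))
  seed <- train$seed
  y <- match(labels, AAMI_CLASSES)

  # stratified validation split
  set.seed(child_seed(seed, 11L))
  val_idx <- unlist(lapply(split(seq_along(y), labels), function(ix) {
    k <- max(1L, round(train$validation_fraction * length(ix)))
    if (length(ix) <= 1L) integer(0) else sample(ix, min(k, length(ix) - 1L))
  }))
  if (length(val_idx) == 0L) stopf("empty validation split")
  tr_idx <- setdiff(seq_along(y), val_idx)

  scheme <- bucket_scheme(lens[tr_idx])
  scheme$bucket_lengths[length(scheme$bucket_lengths)] <-
    max(scheme$bucket_lengths[length(scheme$bucket_lengths)], max(lens))
  net <- build_beat_net(model, n_bins, seed = child_seed(seed, 13L))
  opt <- adam_init(net$params)

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        acc_N = numeric(0), acc_S = numeric(0),
                        acc_V = numeric(0), acc_F = numeric(0),
                        acc_Q = numeric(0), mean_nsv = numeric(0))
  best <- list(score = -Inf, epoch = 0L, params = net$params,
               running = net$running)

  for (epoch in seq_len(train$epochs)) {
    use <- if (train$rebalance)
      tr_idx[rebalance_epoch(labels[tr_idx], epoch, child_seed(seed, 17L))]
    else tr_idx
    set.seed(child_seed(seed, 1000L + epoch))
    use <- sample(use)
    bids <- assign_buckets(lens[use], scheme)
    losses <- numeric(0)
    for (bk in sort(unique(bids))) {
      members <- use[bids == bk]
      blen <- scheme$bucket_lengths[bk]
      nb <- ceiling(length(members) / train$batch_size)
      for (part in seq_len(nb)) {
        sel <- members[((part - 1L) * train$batch_size + 1L):
                         min(part * train$batch_size, length(members))]
        pb <- pad_batch(x[sel], blen)
        fwd <- beat_net_forward(net, model, pb$batch, pb$true_lengths,
                                training = TRUE)
        net <- fwd$net
        losses <- c(losses, cross_entropy(fwd$probs, y[sel]))
        grads <- beat_net_backward(net, model, fwd$cache, fwd$probs, y[sel])
        st <- adam_step(net$params, grads, opt, train$learning_rate)
        net$params <- st$params; opt <- st$state
      }
    }
    val <- predict_internal(net, model, x[val_idx], type = "class")
    acc <- vapply(AAMI_CLASSES, function(cl) {
      ix <- labels[val_idx] == cl
      if (!any(ix)) NA_real_ else mean(val[ix] == cl)
    }, numeric(1))
    sel_cls <- intersect(train$selection_classes,
                         AAMI_CLASSES[!is.na(acc)])
    score <- mean(acc[sel_cls])
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = mean(losses),
                                acc_N = acc[["N"]], acc_S = acc[["S"]],
                                acc_V = acc[["V"]], acc_F = acc[["F"]],
                                acc_Q = acc[["Q"]], mean_nsv = score))
    if (!is.na(score) && score > best$score)
      best <- list(score = score, epoch = epoch, params = net$params,
                   running = net$running)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val N/S/V %.3f", epoch,
                      mean(losses), score))
  }
  net$params <- best$params
  net$running <- best$running
  structure(list(params = net$params, running = net$running,
                 n_bins = net$n_bins, model = model, train = train,
                 history = history, best_epoch = best$epoch,
                 best_score = best$score, classes = AAMI_CLASSES),
            class = "beat_rnn")
}

# inference over a list of spectrograms, batching by shared length groups
predict_internal <- function(net, config, x, type = c("class", "prob"),
                             batch_size = 512L) {
  type <- match.arg(type)
  lens <- vapply(x, ncol, integer(1))
  probs <- matrix(NA_real_, length(x), config$output_classes)
  for (L in unique(lens)) {
    ix_all <- which(lens == L)
    for (start in seq(1L, length(ix_all), by = batch_size)) {
      ix <- ix_all[start:min(start + batch_size - 1L, length(ix_all))]
      pb <- pad_batch(x[ix], L)
      fwd <- beat_net_forward(net, config, pb$batch, pb$true_lengths,
                              training = FALSE)
      probs[ix, ] <- fwd$probs
    }
  }
  if (type == "prob") {
    colnames(probs) <- AAMI_CLASSES
    return(probs)
  }
  cls <- AAMI_CLASSES[max.col(probs, ties.method = "first")]
  rmax <- apply(probs, 1, max)
  n_ties <- sum(rowSums(probs == rmax) > 1L)
  if (n_ties > 0L)
    message(sprintf("%d tie(s) broken toward the earlier AAMI class", n_ties))
  attr(cls, "n_ties") <- n_ties
  cls
}

#' Predict beat classes for new segments
#'
#' Runs the trained network in inference mode (frozen batch-norm
#' statistics, recurrence mode per the model config). The class is the
#' arg-max of the probability vector; exact ties break toward the earlier
#' class in the order N, S, V, F, Q and are counted in the \code{n_ties}
#' attribute.
#'
#' @param object a fitted \code{beat_rnn}
#' @param newdata list of spectrogram matrices (or a single matrix)
#' @param type "class" (default) or "prob"
#' @param ... unused
#' @return character vector of classes, or a probability matrix with one
#'   row per segment
#' @export
predict.beat_rnn <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  if (is.matrix(newdata)) newdata <- list(newdata)
  if (!is.list(newdata) || !all(vapply(newdata, is.matrix, logical(1))))
    stopf("newdata must be preprocessed spectrogram matrices; raw signals must go through preprocess_record()")
  if (nrow(newdata[[1]]) != object$n_bins)
    stopf("segments have %d frequency bins, model expects %d",
          nrow(newdata[[1]]), object$n_bins)
  predict_internal(object, object$model, newdata, match.arg(type))
}

#' @export
print.beat_rnn <- function(x, ...) {
  cat(sprintf("<beat_rnn> %s variant (%s profile), %d conv layer(s), %d x %d-unit RNN (%s)\n",
              x$model$variant, x$model$profile,
              length(x$model$conv_layers), x$model$rnn_layers,
              x$model$rnn_hidden, x$model$rnn_mode))
  cat(sprintf("  %s parameters; trained %d epoch(s); best epoch %d (val N/S/V %.4f)\n",
              format(n_parameters(x$model, x$n_bins), big.mark = ","),
              nrow(x$history), x$best_epoch, x$best_score))
  invisible(x)
}

#' @export
summary.beat_rnn <- function(object, ...) {
  h <- object$history
  cat("Training history (last epoch):\n")
  print(h[nrow(h), ], row.names = FALSE)
  cat(sprintf("\nBest checkpoint: epoch %d, mean N/S/V validation accuracy %.4f\n",
              object$best_epoch, object$best_score))
  best <- h[h$epoch == object$best_epoch, ]
  cat("Per-class validation accuracy at best epoch:\n")
  print(best[, c("acc_N", "acc_S", "acc_V", "acc_F", "acc_Q")],
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.beat_rnn <- function(object, ...) object$params

#' @export
plot.beat_rnn <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "Loss", ...)
  plot(h$epoch, h$mean_nsv, type = "l", xlab = "epoch",
       ylab = "mean N/S/V validation accuracy", main = "Validation",
       ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
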