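#' Build a bucket scheme from observed lengths
#'
#' Bucket boundaries are the \code{quantiles} of the training lengths,
#' rounded up to a multiple of \code{multiple} frames; the top bucket
#' always covers the maximum length. Instances are later assigned to the
#' smallest bucket that fits them, so padding is bounded by the
#' inter-quantile gaps.
#'
#' @param lengths integer vector of instance lengths (frames)
#' @param quantiles probabilities of the bucket boundaries
#' @param multiple round boundaries up to this multiple (default 8)
#' @return a \code{bucket_scheme} with strictly increasing
#'   \code{bucket_lengths}
#' @export
bucket_scheme <- function(lengths, quantiles = c(0.5, 0.75, 0.9, 0.99, 1),
                          multiple = 8L) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  q <- stats::quantile(lengths, quantiles, type = 1, names = FALSE)
  b <- unique(as.integer(ceiling(q / multiple) * multiple))
  b[length(b)] <- max(b[length(b)], max(lengths))
  structure(list(bucket_lengths = sort(unique(b))), class = "bucket_scheme")
}

#' Assign instances to buckets
#'
#' Each instance goes to the smallest bucket whose length is at least the
#' instance's length (closest-from-above): any smaller bucket would force
#' truncation.
#'
#' @param lengths integer vector of instance lengths
#' @param scheme a \code{\link{bucket_scheme}} (or a sorted integer vector
#'   of bucket lengths)
#' @return integer vector of bucket ids (indices into
#'   \code{bucket_lengths})
#' @export
assign_buckets <- function(lengths, scheme) {
  bl <- if (inherits(scheme, "bucket_scheme")) scheme$bucket_lengths
        else sort(as.integer(scheme))
  if (any(lengths > bl[length(bl)]))
    stopf("instance length %d exceeds largest bucket %d",
          max(lengths), bl[length(bl)])
  ids <- findInterval(lengths - 1L, bl) + 1L   # smallest bucket >= length
  as.integer(ids)
}

#' Zero-pad a batch of spectrogram grids to a bucket length
#'
#' @param instances list of matrices (bins x frames), all with the same
#'   number of rows and at most \code{bucket_length} columns
#' @param bucket_length target frame count
#' @return list with \code{batch} (array bins x bucket_length x n) and
#'   \code{true_lengths} (original frame counts); padded frames are
#'   exactly zero, so \code{\link{unpad_batch}} recovers the originals
#'   bit-exactly
#' @export
pad_batch <- function(instances, bucket_length) {
  stopifnot(length(instances) > 0)
  n_bins <- nrow(instances[[1]])
  lens <- vapply(instances, ncol, integer(1))
  if (any(lens > bucket_length))
    stopf("instance of %d frames exceeds bucket length %d", max(lens),
          bucket_length)
  batch <- array(0, dim = c(n_bins, bucket_length, length(instances)))
  for (i in seq_along(instances))
    batch[, seq_len(lens[i]), i] <- instances[[i]]
  list(batch = batch, true_lengths = lens)
}

#' Recover original instances from a padded batch
#' @param padded result of \code{\link{pad_batch}}
#' @return list of matrices with the padding removed
#' @export
unpad_batch <- function(padded) {
  n_bins <- dim(padded$batch)[1]
  lapply(seq_along(padded$true_lengths), function(i)
    matrix(padded$batch[, seq_len(padded$true_lengths[i]), i],
           nrow = n_bins))
}

#' Per-epoch majority-class rebalancing plan
#'
#' All non-N instances are kept every epoch; the N (majority) instances
#' are sampled without replacement down to the non-N total, with a fresh
#' draw per epoch (seeded by \code{seed} and \code{epoch}). If N is not
#' the majority, everything is kept and a warning logged (no upsampling).
#'
#' @param labels AAMI class per instance
#' @param epoch epoch number (>= 1); changes the N subset
#' @param seed base seed
#' @return integer vector of retained instance indices (an epoch plan)
#' @export
rebalance_epoch <- function(labels, epoch = 1L, seed = 1L) {
  idx_n <- which(labels == "N")
  idx_other <- which(labels != "N")
  if (length(idx_other) == 0L)
    stopf("rebalancing needs at least one non-N instance")
  k <- length(idx_other)
  if (length(idx_n) <= k) {
    if (length(idx_n) < k)
      warnf("N count %d below non-N total %d; keeping all N (no upsampling)",
            length(idx_n), k)
    return(sort(c(idx_n, idx_other)))
  }
  set.seed(child_seed(seed, epoch))
  sort(c(sample(idx_n, k), idx_other))
}
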