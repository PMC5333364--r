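# Jackknife error propagation on (correlated) Monte Carlo time series.

#' Jackknife estimate with contiguous blocks
#'
#' Partitions the observations into `n_blocks` contiguous blocks (contiguity
#' lets the blocks absorb autocorrelation), evaluates the estimator on each
#' leave-one-block-out subsample, and reports
#' \deqn{\sigma^2 = \frac{g-1}{g} \sum_i (\theta_i - \bar\theta)^2,}
#' where \eqn{g} is the number of blocks.  The reported value is the
#' full-sample estimate.  The estimator may return a vector; value and
#' sigma then have the same names.
#'
#' @param x sample sequence: vector, matrix or data frame (rows =
#'   observations, chronological order).
#' @param estimator function of the data returning a numeric scalar or
#'   vector.
#' @param n_blocks number of blocks (>= 2; default 20).
#' @param ... further arguments passed to `estimator`.
#' @return object of class `jackknife_estimate`: `value`, `sigma`,
#'   `n_blocks`, `block_length`, `replicates` matrix.
#' @export
jackknife <- function(x, estimator, n_blocks = 20, ...) {
  n <- NROW(x)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2) stop("need at least 2 blocks")
  if (n < n_blocks) stop("fewer observations than blocks")
  take <- function(idx) if (is.null(dim(x))) x[idx] else x[idx, , drop = FALSE]
  bounds <- floor(seq(0, n, length.out = n_blocks + 1))
  full <- estimator(x, ...)
  reps <- matrix(NA_real_, n_blocks, length(full))
  colnames(reps) <- names(full)
  for (i in seq_len(n_blocks)) {
    drop_idx <- (bounds[i] + 1):bounds[i + 1]
    th <- tryCatch(estimator(take(-drop_idx), ...), error = function(e)
      stop("estimator failed on jackknife block ", i, ": ",
           conditionMessage(e)))
    reps[i, ] <- th
  }
  bar <- colMeans(reps)
  sig <- sqrt((n_blocks - 1) / n_blocks *
                colSums(sweep(reps, 2, bar)^2))
  names(sig) <- names(full)
  out <- list(value = full, sigma = sig, n_blocks = n_blocks,
              block_length = n / n_blocks, replicates = reps)
  class(out) <- "jackknife_estimate"
  out
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat(sprintf("jackknife_estimate (%d blocks of ~%g):\n", x$n_blocks,
              round(x$block_length, 1)))
  for (i in seq_along(x$value))
    cat(sprintf("  %s = %.6g +- %.3g\n",
                if (is.null(names(x$value))) as.character(i)
                else names(x$value)[i],
                x$value[i], x$sigma[i]))
  invisible(x)
}
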