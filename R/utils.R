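# Small numeric helpers shared across modules.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector (may contain `-Inf`).
#' @return `log(sum(exp(x)))` computed without overflow.
#' @export
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp for a matrix
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

# Gaussian kernel smoothing on a regular grid (reflecting edges); used only
# to LOCATE extrema, never to read values.
gaussian_smooth <- function(y, sd = 2) {
  if (sd <= 0) return(y)
  n <- length(y)
  half <- max(1L, ceiling(3 * sd))
  k <- exp(-0.5 * ((-half:half) / sd)^2)
  k <- k / sum(k)
  ypad <- c(rev(y[seq_len(half)]), y, rev(y[n - seq_len(half) + 1L]))
  as.numeric(stats::filter(ypad, k, sides = 2))[half + seq_len(n)]
}

# evaluate a function with a temporary RNG state derived from `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a character scalar, reported as 8 hex digits; used to tag
# run artifacts with the spec/config they came from.
fnv1a <- function(s) {
  bytes <- utf8ToInt(paste(s, collapse = "\n"))
  h <- 216613626
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# deterministic sub-seed derivation (kept below 2^31)
fold_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629 + 1
}
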