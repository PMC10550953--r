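#' Penalized least-squares changepoint detection
#'
#' Multivariate binary segmentation minimizing within-segment squared
#' error with a linear penalty per changepoint.  Columns are normalized
#' internally by a difference-based noise estimate, so the penalty is on
#' a unit-variance scale; `penalty_factor` multiplies the base
#' `2 * d * log(n)` penalty (1 reproduces a BIC-like criterion, larger
#' values segment more conservatively).
#'
#' @param x numeric vector or matrix (rows = ordered observations,
#'   columns = jointly segmented signals).
#' @param penalty_factor multiplier on the base penalty (default 1).
#' @param min_seg minimum segment length in observations (default 2).
#' @return integer vector of changepoint indices: each value i means a
#'   new segment starts at row i (1 < i <= n); empty if none.
#' @export
find_changepoints <- function(x, penalty_factor = 1, min_seg = 2) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 2 * min_seg) return(integer(0))
  sigma <- apply(x, 2, function(v) {
    s <- stats::mad(diff(v)) / sqrt(2)
    if (!is.finite(s) || s == 0) s <- stats::sd(v)
    if (!is.finite(s) || s == 0) s <- 1
    s
  })
  z <- sweep(x, 2, sigma, "/")
  penalty <- penalty_factor * 2 * d * log(n)
  cs <- apply(z, 2, cumsum)
  cs2 <- apply(z^2, 2, cumsum)
  cs <- rbind(0, cs); cs2 <- rbind(0, cs2)
  seg_cost <- function(a, b) { # rows a..b inclusive
    s <- cs[b + 1, ] - cs[a, ]
    s2 <- cs2[b + 1, ] - cs2[a, ]
    sum(s2 - s^2 / (b - a + 1))
  }
  out <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    seg <- stack[[1]]; stack <- stack[-1]
    a <- seg[1]; b <- seg[2]
    if (b - a + 1 < 2 * min_seg) next
    splits <- (a + min_seg - 1):(b - min_seg)
    if (length(splits) == 0) next
    lenL <- splits - a + 1; lenR <- b - splits
    costs <- numeric(length(splits))
    for (j in seq_len(d)) {
      sl <- cs[splits + 1, j] - cs[a, j]
      s2l <- cs2[splits + 1, j] - cs2[a, j]
      st <- cs[b + 1, j] - cs[a, j]
      s2t <- cs2[b + 1, j] - cs2[a, j]
      costs <- costs + (s2l - sl^2 / lenL) +
        ((s2t - s2l) - (st - sl)^2 / lenR)
    }
    best <- which.min(costs)
    gain <- seg_cost(a, b) - costs[best]
    if (gain > penalty) {
      t <- splits[best]
      out <- c(out, t + 1L)
      stack <- c(stack, list(c(a, t)), list(c(t + 1L, b)))
    }
  }
  sort(out)
}
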