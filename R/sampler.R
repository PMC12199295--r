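# Geometrically weighted rank sampling and the dynamic step-size controller.
#
# Given a similarity-ranked list of n items and a sampling ratio x in (0,1),
# ranks are weighted by a truncated geometric distribution with common ratio
#   r = x^(1 / (x * n)),   raw weight a_k = (1 - r) * r^(k - 1).
# The defining property: the raw cumulative weight of the top x*n ranks is
#   sum_{k<=xn} a_k = 1 - r^(xn) = 1 - x,
# i.e. a ratio of 0.1 puts 90% of the mass on the top 10% of the list, and
# 0.01 puts 99% on the top 1%, for any list size n. Weights are always
# renormalised over the n ranks (the truncated tail mass is x^(1/x),
# negligible for practical x but not exactly zero).

#' Geometric rank-sampling weights
#'
#' @param x Sampling ratio in (0, 1). Smaller values concentrate mass on
#'   top ranks; as `x` approaches 1 the weights approach uniform.
#' @param n List length (>= 1). Rank 1 is the most similar item.
#' @return An object of class `rx_rank_weights`: list with `x`, `n`, `r`
#'   (common ratio) and `weights` (length-`n` probability vector summing
#'   to 1, strictly decreasing for x < 1).
#' @examples
#' w <- geometric_weights(0.1, 1000)
#' sum(w$weights[1:100])   # ~0.90: top decile carries 90% of the mass
#' @export
geometric_weights <- function(x, n) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop("sampling ratio x must lie strictly in (0, 1)", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("list length n must be >= 1", call. = FALSE)
  r <- x^(1 / (x * n))
  raw <- (1 - r) * r^(seq_len(n) - 1)
  s <- sum(raw)
  weights <- if (s > 0) raw / s else c(1, rep(0, n - 1L))
  structure(list(x = x, n = n, r = r, weights = weights),
            class = "rx_rank_weights")
}

#' @export
print.rx_rank_weights <- function(x, ...) {
  cat("<rx_rank_weights> x=", x$x, " n=", x$n, " r=", signif(x$r, 6),
      "; top rank weight ", signif(x$weights[1], 4), "\n", sep = "")
  invisible(x)
}

#' Draw a rank from geometric rank weights
#'
#' @param w An `rx_rank_weights` object (or a ratio `x` together with `n`).
#' @param n Optional list length when `w` is given as a ratio.
#' @return A single rank in `1..n`, drawn with probability `w$weights`.
#' @export
sample_rank <- function(w, n = NULL) {
  if (is.numeric(w)) w <- geometric_weights(w, n)
  stopifnot(inherits(w, "rx_rank_weights"))
  if (w$n == 1L) return(1L)
  sample.int(w$n, 1L, prob = w$weights)
}

#' Dynamic sampling-ratio controller
#'
#' Holds the adaptive step-size state: the active sampling ratio starts at
#' the minimum `m`, increases by `s` after every rejected Monte Carlo
#' iteration (capped at `M`), and resets to `m` on acceptance.
#'
#' @param m Minimum ratio (default 0.01).
#' @param M Maximum ratio (default 0.2).
#' @param s Increment per rejection (default 0.002).
#' @param enabled If `FALSE`, [update_controller()] is a no-op and the ratio
#'   stays at its current value.
#' @return An object of class `rx_controller`.
#' @export
sampling_controller <- function(m = 0.01, M = 0.2, s = 0.002, enabled = TRUE) {
  stopifnot(m > 0, m <= M, M < 1, s > 0)
  structure(list(min = m, max = M, step = s, current = m, enabled = enabled),
            class = "rx_controller")
}

#' @export
print.rx_controller <- function(x, ...) {
  cat("<rx_controller> [", x$min, ", ", x$max, "] step ", x$step,
      "; current ", x$current, if (!x$enabled) " (disabled)", "\n", sep = "")
  invisible(x)
}

#' Update the controller after a Monte Carlo iteration
#'
#' @param ctrl An `rx_controller`.
#' @param accepted Was the previous iteration accepted?
#' @return The updated controller: reset to `m` on acceptance, increased by
#'   `s` (capped at `M`) on rejection; unchanged when disabled.
#' @export
update_controller <- function(ctrl, accepted) {
  stopifnot(inherits(ctrl, "rx_controller"))
  if (!ctrl$enabled) return(ctrl)
  ctrl$current <- if (accepted) ctrl$min else min(ctrl$current + ctrl$step,
                                                  ctrl$max)
  ctrl
}
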