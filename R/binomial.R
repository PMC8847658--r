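#' Log binomial tail (or point) probability
#'
#' Natural logarithm of `P(X >= k)` (mode `"tail"`, the default) or of
#' `P(X = k)` (mode `"pmf"`) for `X ~ Binomial(n, p)`.  The stability
#' probability pi of a ranked feature is `B(n, p, k)` with `n` the number of
#' windows, `p` the per-trial probability of the feature identity under the
#' independent-networks null, and `k` the modal count; the tail form is the
#' p value of observing a modal count at least as large by chance.
#'
#' Computation stays in log space throughout (via `pbinom(..., log.p)` /
#' `dbinom(..., log = TRUE)`), so there is no underflow even for
#' `n ~ 1e6` and the astronomically small probabilities that stable
#' recordings produce.
#'
#' @param n number of trials (windows), `n >= 1`.
#' @param p per-trial success probability, `0 < p < 1`.
#' @param k observed count, `0 <= k <= n`.
#' @param mode `"tail"` for `ln P(X >= k)`, `"pmf"` for `ln P(X = k)`.
#' @return The log probability, a nonpositive number (`0` for the tail at
#'   `k = 0`).  `ln_binomial_tail(n, p, n)` equals `n * log(p)` exactly.
#' @export
ln_binomial_tail <- function(n, p, k, mode = c("tail", "pmf")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n), is.numeric(p), is.numeric(k),
            length(n) == 1L, length(p) == 1L, length(k) == 1L,
            n >= 1, k >= 0, k <= n, n == floor(n), k == floor(k))
  if (!(p > 0 && p < 1)) stop("'p' must lie strictly in (0, 1)")
  if (mode == "pmf") return(stats::dbinom(k, n, p, log = TRUE))
  if (k == 0) return(0)
  if (k == n) return(n * log(p))
  stats::pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE)
}
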