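#' Window specification for sliding-window reconstruction
#'
#' Converts a window length in milliseconds into samples
#' (`floor(window_ms * rate / 1000)`) and the number of non-overlapping
#' windows that fit the recording (`floor(l / window_samples)`); trailing
#' samples beyond the last full window are discarded.
#'
#' @param recording a [recording].
#' @param window_ms window length in milliseconds.
#' @return An object of class `window_spec`: list with `window_ms`,
#'   `window_samples`, `n_windows`.
#' @export
make_window_spec <- function(recording, window_ms) {
  stopifnot(inherits(recording, "recording"),
            is.numeric(window_ms), length(window_ms) == 1L, window_ms > 0)
  ws <- floor(window_ms * recording$sampling_rate_hz / 1000)
  if (ws < 2)
    stop("window of ", window_ms, " ms at ", recording$sampling_rate_hz,
         " Hz yields ", ws, " sample(s); need at least 2")
  nw <- ncol(recording$data) %/% ws
  if (nw < 1L)
    stop("recording shorter than one window of ", ws, " samples")
  structure(list(window_ms = window_ms, window_samples = as.integer(ws),
                 n_windows = as.integer(nw)),
            class = "window_spec")
}

# Absolute Pearson correlation between the rows of Z (channels x samples).
# Zero-variance rows get weight 0 on all their links; the "degenerate"
# attribute carries the indices of such rows.  Diagonal is exactly 0.
.abs_corr <- function(Z) {
  Z <- Z - rowMeans(Z)
  S <- tcrossprod(Z)
  d <- sqrt(diag(S))
  degen <- which(d == 0)
  d[d == 0] <- 1
  W <- abs(S / outer(d, d))
  if (length(degen)) { W[degen, ] <- 0; W[, degen] <- 0 }
  # |r| can creep above 1 by an ulp; clamp so the [0,1] invariant is exact
  W[W > 1] <- 1
  diag(W) <- 0
  if (length(degen)) attr(W, "degenerate") <- degen
  W
}

#' Weighted functional network from one window of data
#'
#' Builds the fully connected weighted network whose link weight between
#' channels j and k is the absolute value of the Pearson correlation of
#' their samples in the window.  Constant (zero-variance) channels produce
#' weight 0 on all their links and raise a warning.
#'
#' @param window_data numeric matrix, N channels x w samples, w >= 2.
#' @param window_index integer position of the window in its sequence.
#' @return An object of class `weighted_network`: symmetric N x N matrix in
#'   `[0, 1]` with zero diagonal and a `window_index` attribute.
#' @export
correlation_network <- function(window_data, window_index = 1L) {
  stopifnot(is.matrix(window_data), is.numeric(window_data),
            ncol(window_data) >= 2L)
  W <- .abs_corr(window_data)
  if (!is.null(attr(W, "degenerate")))
    warning("constant channel(s) in window ", window_index, ": ",
            paste(attr(W, "degenerate"), collapse = ", "),
            "; their link weights set to 0")
  attr(W, "window_index") <- as.integer(window_index)
  class(W) <- c("weighted_network", class(W))
  W
}

#' Reconstruct the dynamic network series of a recording
#'
#' Splits the recording into non-overlapping windows of `window_ms`
#' milliseconds and builds one [correlation_network()] per window; window i
#' covers samples `[(i-1)*w + 1, i*w]`.
#'
#' @param recording a [recording].
#' @param window_ms window length in milliseconds.
#' @param weight_fun optional replacement connectivity estimator: a function
#'   `(N x w matrix) -> N x N symmetric weight matrix in [0,1]`.  The default
#'   (absolute Pearson correlation) is the only estimator shipped.
#' @return An object of class `dynamic_networks`: list with `subject_id`,
#'   `window_spec`, `channel_labels` and `networks` (list of
#'   `weighted_network`, length `n_windows`).
#' @export
reconstruct <- function(recording, window_ms, weight_fun = NULL) {
  spec <- make_window_spec(recording, window_ms)
  w <- spec$window_samples
  nets <- vector("list", spec$n_windows)
  for (i in seq_len(spec$n_windows)) {
    slice <- recording$data[, ((i - 1L) * w + 1L):(i * w), drop = FALSE]
    if (is.null(weight_fun)) {
      nets[[i]] <- suppressWarnings(correlation_network(slice, i))
    } else {
      W <- weight_fun(slice)
      attr(W, "window_index") <- i
      class(W) <- c("weighted_network", class(W))
      nets[[i]] <- W
    }
  }
  structure(list(subject_id = recording$subject_id, window_spec = spec,
                 channel_labels = recording$channel_labels, networks = nets),
            class = "dynamic_networks")
}

#' @export
print.dynamic_networks <- function(x, ...) {
  cat("<dynamic_networks> subject '", x$subject_id, "': ",
      length(x$networks), " networks of ", length(x$channel_labels),
      " nodes (window ", x$window_spec$window_ms, " ms = ",
      x$window_spec$window_samples, " samples)\n", sep = "")
  invisible(x)
}

#' Mean network over all windows
#'
#' Element-wise mean of the per-window weight matrices; used as the
#' reference network for the random-link classification baselines.
#'
#' @param recording a [recording].
#' @param window_ms reference window length in milliseconds.
#' @return Symmetric N x N matrix of mean absolute-correlation weights.
#' @export
mean_network <- function(recording, window_ms) {
  spec <- make_window_spec(recording, window_ms)
  w <- spec$window_samples
  acc <- matrix(0, nrow(recording$data), nrow(recording$data))
  for (i in seq_len(spec$n_windows)) {
    acc <- acc + .abs_corr(
      recording$data[, ((i - 1L) * w + 1L):(i * w), drop = FALSE])
  }
  acc / spec$n_windows
}
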