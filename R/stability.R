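#' Default window-length grid
#'
#' Log-spaced grid of window lengths in milliseconds used when none is
#' supplied: 30 points between 10 and 1000 ms, covering the range from
#' single high-frequency fluctuations up to second-scale averages.
#'
#' @param from,to grid end points in milliseconds.
#' @param length.out number of grid points.
#' @return Strictly increasing numeric vector of window lengths (ms).
#' @export
default_window_grid <- function(from = 10, to = 1000, length.out = 30) {
  exp(seq(log(from), log(to), length.out = length.out))
}

# One pass over the windows of a recording at a fixed window length:
# computes the absolute-correlation network per window and extracts the
# identity key of every requested feature (and, optionally, the
# strongest/second-strongest rank gap).  Shared by all profile functions so
# networks are built once per grid point.
.scan_windows <- function(recording, window_ms, features, gap = FALSE) {
  spec <- make_window_spec(recording, window_ms)
  w <- spec$window_samples
  N <- nrow(recording$data)
  pairs <- .link_pairs(N)
  fks <- lapply(features, feature_kind)
  keys <- lapply(fks, function(f) character(spec$n_windows))
  gaps <- if (gap) numeric(spec$n_windows) else NULL
  for (i in seq_len(spec$n_windows)) {
    W <- .abs_corr(recording$data[, ((i - 1L) * w + 1L):(i * w), drop = FALSE])
    wts <- W[pairs]
    for (fi in seq_along(fks)) {
      f <- fks[[fi]]
      keys[[fi]][i] <- switch(f$kind,
        strongest_link = {
          b <- pairs[which.max(wts), ]
          paste(b[1L], b[2L], sep = "-")
        },
        top_m_links = {
          sel <- sort(order(-wts, pairs[, 1L], pairs[, 2L])[seq_len(f$m)])
          paste(pairs[sel, 1L], pairs[sel, 2L], sep = "-", collapse = ";")
        },
        max_strength_node = paste0("n", which.max(rowSums(W))),
        max_clustering_node = paste0("n", which.max(local_clustering(W))))
    }
    if (gap) {
      s12 <- sort(wts, decreasing = TRUE)[1:2]
      gaps[i] <- if (s12[2L] > 0) log2(s12[1L] / s12[2L]) else NA_real_
    }
  }
  list(spec = spec, keys = keys, gaps = gaps)
}

# Stability result from a sequence of identity keys.
.stability_from_keys <- function(keys, feature, N) {
  f <- feature_kind(feature)
  modal <- .modal_identity(keys)
  n <- length(keys)
  p <- per_trial_probability(f, N)
  structure(
    list(feature = f, modal_identity = .parse_identity(modal$key),
         modal_key = modal$key, k = modal$k, n = n, p = p,
         ln_pi = ln_binomial_tail(n, p, modal$k)),
    class = "stability_result")
}

#' Stability of a ranked feature over one network series
#'
#' Extracts the feature identity in every window of a reconstructed
#' series, finds the modal identity (the one occurring most often; ties
#' break toward the lexicographically smallest), and scores its persistence
#' with the binomial null: `k` = modal count, `n` = number of windows,
#' `p` = [per_trial_probability()], `ln_pi` = [ln_binomial_tail()].
#'
#' @param series a [reconstruct()]ed `dynamic_networks` object.
#' @param feature a [feature_kind()] (or its name).
#' @param m set size when `feature = "top_m_links"`.
#' @return An object of class `stability_result`: list with `feature`,
#'   `modal_identity`, `k`, `n`, `p`, `ln_pi`.
#' @export
stability_at_window <- function(series, feature, m = NULL) {
  stopifnot(inherits(series, "dynamic_networks"))
  f <- feature_kind(feature, m)
  keys <- .identity_sequence(series$networks, f)
  .stability_from_keys(keys, f, length(series$channel_labels))
}

#' @export
print.stability_result <- function(x, ...) {
  id <- x$modal_key
  cat("<stability_result> ", x$feature$label, ": modal ", id,
      " seen k=", x$k, " of n=", x$n, " windows (p=",
      format(x$p, digits = 4), "), ln pi = ",
      format(x$ln_pi, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Fit a stability profile across window lengths
#'
#' The central estimator of the package.  For every window length in
#' `grid_ms` the recording is split into non-overlapping windows, one
#' absolute-Pearson-correlation network is built per window, the ranked
#' feature (strongest link, top-m link set, most central node, or node of
#' highest clustering) is extracted per window, and the persistence of the
#' modal identity is scored as the log binomial null probability
#' `ln pi = ln B(n, p, k)`.  The profile's minimum locates the timescale at
#' which the feature is most stable; more negative `ln pi` means more
#' stable.
#'
#' @param recording a [recording] (or a `dynamic_networks` series via
#'   [stability_at_window()] for a single window length).
#' @param feature feature kind; see [feature_kind()].
#' @param grid_ms strictly increasing vector of window lengths (ms);
#'   defaults to [default_window_grid()].  Entries too short to hold 2
#'   samples are skipped with a warning.
#' @param m set size for `"top_m_links"`.
#' @return An object of class `stability_profile`: list with `subject_id`,
#'   `feature`, `grid` (data frame with columns `window_ms`, `n_windows`,
#'   `modal`, `k`, `p`, `ln_pi`), `results` (the per-point
#'   `stability_result`s), `best_window_ms` and `min_ln_pi` (grid minimum of
#'   `ln_pi`, ties toward the smallest window).
#' @examples
#' rec <- generate_null(synthetic_spec(N = 8, duration_s = 4, seed = 1))
#' fit <- stability_profile(rec, "strongest_link", grid_ms = c(20, 50, 100))
#' fit
#' @export
stability_profile <- function(recording, feature, grid_ms = default_window_grid(),
                              m = NULL) {
  stopifnot(inherits(recording, "recording"))
  if (length(grid_ms) < 1L || is.unsorted(grid_ms, strictly = TRUE))
    stop("'grid_ms' must be non-empty and strictly increasing")
  f <- feature_kind(feature, m)
  pr <- .profile_many(recording, list(f), grid_ms)[[1L]]
  pr
}

# Profiles for several features in one pass over the windows.
.profile_many <- function(recording, features, grid_ms, gap = FALSE) {
  N <- nrow(recording$data)
  feasible <- logical(length(grid_ms))
  scans <- vector("list", length(grid_ms))
  for (g in seq_along(grid_ms)) {
    sc <- tryCatch(.scan_windows(recording, grid_ms[g], features, gap = gap),
                   error = function(e) e)
    if (inherits(sc, "error")) {
      warning("skipping window ", grid_ms[g], " ms: ", conditionMessage(sc))
    } else {
      feasible[g] <- TRUE
      scans[[g]] <- sc
    }
  }
  if (!any(feasible)) stop("no feasible window length in the grid")
  used <- which(feasible)
  out <- vector("list", length(features))
  for (fi in seq_along(features)) {
    results <- lapply(used, function(g)
      .stability_from_keys(scans[[g]]$keys[[fi]], features[[fi]], N))
    grid <- data.frame(
      window_ms = grid_ms[used],
      n_windows = vapply(results, `[[`, integer(1L), "n"),
      modal = vapply(results, `[[`, character(1L), "modal_key"),
      k = vapply(results, `[[`, integer(1L), "k"),
      p = vapply(results, `[[`, numeric(1L), "p"),
      ln_pi = vapply(results, `[[`, numeric(1L), "ln_pi"))
    best <- which.min(grid$ln_pi)       # first minimum = smallest window
    out[[fi]] <- structure(
      list(subject_id = recording$subject_id,
           feature = feature_kind(features[[fi]]),
           grid = grid, results = results,
           best_window_ms = grid$window_ms[best],
           min_ln_pi = grid$ln_pi[best]),
      class = "stability_profile")
  }
  if (gap) {
    attr(out, "gaps") <- lapply(scans[used], `[[`, "gaps")
    attr(out, "gap_window_ms") <- grid_ms[used]
  }
  out
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("<stability_profile> subject '", x$subject_id, "', feature ",
      x$feature$label, "\n", sep = "")
  cat("  ", nrow(x$grid), " window lengths in [",
      min(x$grid$window_ms), ", ", max(x$grid$window_ms), "] ms\n", sep = "")
  cat("  best window ", format(x$best_window_ms, digits = 4), " ms, min ln pi ",
      format(x$min_ln_pi, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
summary.stability_profile <- function(object, ...) {
  out <- object$grid
  best <- which.min(out$ln_pi)
  attr(out, "best_window_ms") <- out$window_ms[best]
  attr(out, "min_ln_pi") <- out$ln_pi[best]
  class(out) <- c("summary.stability_profile", "data.frame")
  out
}

#' @export
print.summary.stability_profile <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("best window:", format(attr(x, "best_window_ms"), digits = 4),
      "ms  min ln pi:", format(attr(x, "min_ln_pi"), digits = 6), "\n")
  invisible(x)
}

#' @export
coef.stability_profile <- function(object, ...) {
  c(best_window_ms = object$best_window_ms, min_ln_pi = object$min_ln_pi)
}

#' @export
plot.stability_profile <- function(x, ...) {
  graphics::plot(x$grid$window_ms, x$grid$ln_pi, type = "b", log = "x",
                 xlab = "window length (ms)", ylab = expression(ln ~ pi),
                 main = paste0(x$feature$label, " (", x$subject_id, ")"), ...)
  graphics::abline(v = x$best_window_ms, lty = 2, col = "grey50")
  invisible(x)
}

#' Rank-gap profile of the strongest link
#'
#' Per window, the distance between the strongest and second-strongest link
#' is `log2(s1 / s2)` with `s1 >= s2` the two largest link weights; the
#' profile reports the mean gap over windows at each window length.
#' Windows whose second-largest weight is zero are excluded from the mean
#' and counted in `n_excluded`.
#'
#' @param recording a [recording] with N >= 3 channels.
#' @param grid_ms window-length grid (ms).
#' @return An object of class `rank_gap_profile`: data frame with columns
#'   `window_ms`, `mean_gap`, `n_windows`, `n_excluded`.
#' @export
rank_gap_profile <- function(recording, grid_ms = default_window_grid()) {
  stopifnot(inherits(recording, "recording"), nrow(recording$data) >= 3L)
  prof <- .profile_many(recording, list(feature_kind("strongest_link")),
                        grid_ms, gap = TRUE)
  gaps <- attr(prof, "gaps")
  wms <- attr(prof, "gap_window_ms")
  out <- data.frame(
    window_ms = wms,
    mean_gap = vapply(gaps, function(g) mean(g, na.rm = TRUE), numeric(1L)),
    n_windows = vapply(gaps, length, integer(1L)),
    n_excluded = vapply(gaps, function(g) sum(is.na(g)), integer(1L)))
  class(out) <- c("rank_gap_profile", "data.frame")
  out
}

#' Six-metric stability summary of one subject
#'
#' Fits stability profiles for the three headline features -- strongest
#' link, most central (highest-strength) node, and highest-clustering node
#' -- in a single pass over the windows, and returns the six metrics used
#' for covariate analysis and classification: minimum `ln pi` and best
#' window length for each feature.
#'
#' @param recording a [recording].
#' @param grid_ms window-length grid (ms).
#' @return A one-row `data.frame` of class `stability_summary` with columns
#'   `subject_id`, then `<feature>_min_ln_pi` and `<feature>_best_window_ms`
#'   for `strongest_link`, `max_strength_node`, `max_clustering_node`.  The
#'   full profiles are attached as attribute `"profiles"`.
#' @export
stability_summary <- function(recording, grid_ms = default_window_grid()) {
  feats <- list(feature_kind("strongest_link"),
                feature_kind("max_strength_node"),
                feature_kind("max_clustering_node"))
  profs <- .profile_many(recording, feats, grid_ms)
  names(profs) <- vapply(feats, `[[`, character(1L), "kind")
  row <- data.frame(subject_id = recording$subject_id)
  for (nm in names(profs)) {
    row[[paste0(nm, "_min_ln_pi")]] <- profs[[nm]]$min_ln_pi
    row[[paste0(nm, "_best_window_ms")]] <- profs[[nm]]$best_window_ms
  }
  attr(row, "profiles") <- profs
  class(row) <- c("stability_summary", "data.frame")
  row
}

#' Names of the six stability-metric columns
#' @return Character vector of the six metric column names in a
#'   [stability_summary()] row.
#' @export
stability_metric_names <- function() {
  feats <- c("strongest_link", "max_strength_node", "max_clustering_node")
  as.vector(t(outer(feats, c("_min_ln_pi", "_best_window_ms"), paste0)))
}
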