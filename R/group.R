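# Group-level aggregation of per-subject stability profiles: mean curves,
# leave-one-subject-out envelopes, pooled intra-group stability, the
# upsampling split, and between-group comparison of optimal windows.

.check_aligned <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1L), "stability_profile")))
  g0 <- profiles[[1L]]$grid$window_ms
  for (p in profiles[-1L])
    if (!isTRUE(all.equal(p$grid$window_ms, g0)))
      stop("profiles must share one window grid")
  k0 <- profiles[[1L]]$feature$label
  for (p in profiles[-1L])
    if (p$feature$label != k0) stop("profiles must share one feature kind")
  g0
}

.mean_curve_summary <- function(profiles) {
  wms <- .check_aligned(profiles)
  mat <- vapply(profiles, function(p) p$grid$ln_pi, numeric(length(wms)))
  mean_ln_pi <- rowMeans(as.matrix(mat))
  best <- which.min(mean_ln_pi)
  list(window_ms = wms, mean_ln_pi = mean_ln_pi,
       best_window_ms = wms[best], min_ln_pi = mean_ln_pi[best])
}

#' Group-mean stability profile
#'
#' Pointwise mean over subjects of the per-subject `ln pi` curves; the peak
#' summaries (best window, minimum `ln pi`) are read off the mean curve.
#' Per-subject peaks are retained alongside, since group comparisons (KS
#' test, classification) operate on those.  With two or more subjects a
#' leave-one-subject-out envelope of the peak summaries is attached.
#'
#' @param profiles list of [stability_profile] objects on one shared grid
#'   and feature.
#' @param group group label stored on the result.
#' @return An object of class `group_profile`: list with `group`, `feature`,
#'   `grid` (window_ms, mean_ln_pi), `best_window_ms`, `min_ln_pi`,
#'   `per_subject` (data frame of per-subject peaks) and `envelope` (see
#'   [jackknife_envelope()]; `NULL` for a single subject).
#' @export
group_mean_profile <- function(profiles, group = "all") {
  if (length(profiles) == 0L) stop("empty group")
  s <- .mean_curve_summary(profiles)
  per_subject <- data.frame(
    subject_id = vapply(profiles, `[[`, character(1L), "subject_id"),
    best_window_ms = vapply(profiles, `[[`, numeric(1L), "best_window_ms"),
    min_ln_pi = vapply(profiles, `[[`, numeric(1L), "min_ln_pi"))
  structure(
    list(group = group, feature = profiles[[1L]]$feature,
         grid = data.frame(window_ms = s$window_ms, mean_ln_pi = s$mean_ln_pi),
         best_window_ms = s$best_window_ms, min_ln_pi = s$min_ln_pi,
         per_subject = per_subject,
         envelope = if (length(profiles) >= 2L) jackknife_envelope(profiles)),
    class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat("<group_profile> group '", x$group, "', feature ", x$feature$label,
      ", ", nrow(x$per_subject), " subjects\n", sep = "")
  cat("  mean-curve peak: best window ", format(x$best_window_ms, digits = 4),
      " ms, min ln pi ", format(x$min_ln_pi, digits = 6), "\n", sep = "")
  if (!is.null(x$envelope)) {
    e <- x$envelope
    cat("  leave-one-out envelope: window [",
        format(e["best_window_ms", "min"], digits = 4), ", ",
        format(e["best_window_ms", "max"], digits = 4), "] ms, ln pi [",
        format(e["min_ln_pi", "min"], digits = 6), ", ",
        format(e["min_ln_pi", "max"], digits = 6), "]\n", sep = "")
  }
  invisible(x)
}

#' Leave-one-subject-out envelope of group peak summaries
#'
#' Recomputes the group-mean curve with each subject deleted in turn and
#' returns the extrema of the resulting best window length and minimum
#' `ln pi` — a sensitivity band around the full-group values.
#'
#' @param profiles list of at least two aligned [stability_profile]s.
#' @return A 2 x 2 numeric matrix: rows `best_window_ms`, `min_ln_pi`;
#'   columns `min`, `max`.
#' @export
jackknife_envelope <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 subjects for an envelope")
  .check_aligned(profiles)
  loo <- vapply(seq_along(profiles), function(i) {
    s <- .mean_curve_summary(profiles[-i])
    c(s$best_window_ms, s$min_ln_pi)
  }, numeric(2L))
  out <- cbind(min = c(min(loo[1L, ]), min(loo[2L, ])),
               max = c(max(loo[1L, ]), max(loo[2L, ])))
  rownames(out) <- c("best_window_ms", "min_ln_pi")
  out
}

#' Pooled intra-group stability
#'
#' Measures whether the same link (or node) is the strongest one across the
#' subjects of a group: per window length, the per-window feature
#' identities of all subjects are pooled into a single trial sequence, the
#' globally modal identity is counted (`k`) over the pooled `n = sum of all
#' subjects' windows`, and a single `ln pi` is computed per group.
#'
#' @param recordings list of [recording]s (same channel count).
#' @param feature feature kind.
#' @param grid_ms window-length grid (ms).
#' @param m set size for `"top_m_links"`.
#' @return An object of class `intra_group_stability`: data frame with
#'   columns `window_ms`, `modal`, `k`, `n`, `p`, `ln_pi`.
#' @export
intra_group_stability <- function(recordings, feature,
                                  grid_ms = default_window_grid(), m = NULL) {
  stopifnot(length(recordings) >= 1L,
            all(vapply(recordings, inherits, logical(1L), "recording")))
  N <- nrow(recordings[[1L]]$data)
  if (!all(vapply(recordings, function(r) nrow(r$data), integer(1L)) == N))
    stop("all recordings must share the channel count")
  f <- feature_kind(feature, m)
  p <- per_trial_probability(f, N)
  rows <- lapply(grid_ms, function(wms) {
    keys <- tryCatch(
      unlist(lapply(recordings, function(r)
        .scan_windows(r, wms, list(f))$keys[[1L]]), use.names = FALSE),
      error = function(e) e)
    if (inherits(keys, "error")) {
      warning("skipping window ", wms, " ms: ", conditionMessage(keys))
      return(NULL)
    }
    modal <- .modal_identity(keys)
    data.frame(window_ms = wms, modal = modal$key, k = modal$k,
               n = length(keys), p = p,
               ln_pi = ln_binomial_tail(length(keys), p, modal$k))
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("no feasible window length in the grid")
  out <- do.call(rbind, rows)
  class(out) <- c("intra_group_stability", "data.frame")
  out
}

#' Split a recording into equal contiguous parts
#'
#' The upsampling device for small cohorts: each part of a subject's time
#' series is treated as an independent (virtual) subject.  Parts have
#' length `floor(l / parts)`; the remainder is discarded.
#'
#' @param recording a [recording].
#' @param parts number of parts (default 5).
#' @return List of `parts` [recording]s with subject ids suffixed
#'   `"_p<i>"`.
#' @export
upsample_split <- function(recording, parts = 5L) {
  stopifnot(inherits(recording, "recording"), parts >= 1L)
  l <- ncol(recording$data)
  len <- l %/% parts
  if (len < 2L) stop("recording too short to split into ", parts, " parts")
  lapply(seq_len(parts), function(i) {
    seg <- recording$data[, ((i - 1L) * len + 1L):(i * len), drop = FALSE]
    recording(seg, recording$sampling_rate_hz, recording$channel_labels,
              subject_id = paste0(recording$subject_id, "_p", i),
              condition_tag = recording$condition_tag)
  })
}

#' Compare optimal window lengths between two groups
#'
#' Two-sample Kolmogorov–Smirnov test on the per-subject best window
#' lengths (or any other per-subject summary) of two groups.
#'
#' @param group_a,group_b numeric vectors of per-subject values, length
#'   >= 2 each.
#' @return List with `statistic` (the KS D), `p_value`, `n_a`, `n_b`.
#' @export
compare_best_windows <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  kt <- suppressWarnings(stats::ks.test(group_a, group_b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(group_a), n_b = length(group_b))
}
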