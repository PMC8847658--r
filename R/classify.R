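# Binary group discrimination from the six stability metrics: random-forest
# classifier, leave-one-out cross-validation, repeated realisations,
# reference baselines and drop-one feature importance.  The feature count
# is kept at six in every mode so baselines carry the same amount of
# information.

.rf_defaults <- list(ntree = 100L)

# One leave-one-out pass: train on all subjects but one, predict the
# left-out subject; returns the hit rate.
.loo_once <- function(features, labels) {
  labels <- factor(labels)
  n <- nrow(features)
  hits <- logical(n)
  for (i in seq_len(n)) {
    tr <- features[-i, , drop = FALSE]
    tr_lab <- droplevels(labels[-i])
    if (nlevels(tr_lab) < 2L) { hits[i] <- FALSE; next }
    if (all(tr == rep(tr[1L, ], each = nrow(tr)))) {
      # uninformative (constant) features: predict the training majority
      tab <- table(tr_lab)
      hits[i] <- names(tab)[which.max(tab)] == as.character(labels[i])
      next
    }
    fit <- randomForest::randomForest(
      x = tr, y = tr_lab, ntree = .rf_defaults$ntree)
    hits[i] <- as.character(stats::predict(fit, features[i, , drop = FALSE])) ==
      as.character(labels[i])
  }
  mean(hits)
}

#' Build the subjects x 6 feature matrix for a classification mode
#'
#' * `"stability"` (and `"shuffled_labels"`): the six stability metrics of
#'   each subject — `ln pi` and best window length for the strongest link,
#'   the most central node and the highest-clustering node.
#' * `"random_links"`: the mean-over-windows weights of six links drawn
#'   uniformly at random (the same six links for every subject) from the
#'   subjects' mean networks.
#' * `"mixed_random"`: weights of two random links plus strength centrality
#'   and clustering coefficient of two random nodes, on the mean networks.
#'
#' Random draws consume the current RNG stream; seed upstream (the
#' classification drivers redraw once per realisation).
#'
#' @param summaries [stability_summary()] rows (data frame / list of rows);
#'   required for the stability modes.
#' @param mode one of `"stability"`, `"shuffled_labels"`, `"random_links"`,
#'   `"mixed_random"`.
#' @param mean_nets list of per-subject mean weight matrices (see
#'   [mean_network()]); required for the random modes.
#' @return Numeric matrix, subjects x 6.
#' @export
build_feature_matrix <- function(summaries = NULL,
                                 mode = c("stability", "shuffled_labels",
                                          "random_links", "mixed_random"),
                                 mean_nets = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("stability", "shuffled_labels")) {
    if (is.list(summaries) && !is.data.frame(summaries))
      summaries <- do.call(rbind, summaries)
    as.matrix(summaries[, stability_metric_names()])
  } else {
    if (is.null(mean_nets) || length(mean_nets) < 1L)
      stop("random modes need per-subject mean networks")
    N <- nrow(mean_nets[[1L]])
    pairs <- .link_pairs(N)
    if (mode == "random_links") {
      sel <- pairs[sample(nrow(pairs), 6L), , drop = FALSE]
      out <- t(vapply(mean_nets, function(W) W[sel], numeric(6L)))
      colnames(out) <- paste0("link_", sel[, 1L], "_", sel[, 2L])
      out
    } else {
      sel <- pairs[sample(nrow(pairs), 2L), , drop = FALSE]
      nodes <- sample(N, 2L)
      out <- t(vapply(mean_nets, function(W)
        c(W[sel], strength_centrality(W)[nodes], local_clustering(W)[nodes]),
        numeric(6L)))
      colnames(out) <- c(paste0("link_", sel[, 1L], "_", sel[, 2L]),
                         paste0("strength_n", nodes),
                         paste0("clustering_n", nodes))
      out
    }
  }
}

#' Leave-one-out classification accuracy over repeated realisations
#'
#' For each realisation, every subject is predicted by a random forest
#' (100 trees, default mtry) trained on all other subjects; the accuracy is
#' the fraction of correct predictions.  Realisations differ in the
#' forest's internal randomness (and in the label permutation when
#' `shuffle_labels = TRUE`, the chance baseline).
#'
#' @param features subjects x p numeric matrix.
#' @param labels two-class label vector, >= 2 subjects per class.
#' @param n_realisations number of repetitions (default 100).
#' @param seed integer seed; identical seeds give identical reports.
#' @param shuffle_labels permute the class labels independently in each
#'   realisation (random baseline).
#' @return An object of class `classification_report`: list with
#'   `mean_accuracy`, `sd_accuracy`, `accuracies`, `class_balance` (the
#'   majority-class rate) and `n_subjects`.
#' @export
loo_accuracy <- function(features, labels, n_realisations = 100L, seed = 1L,
                         shuffle_labels = FALSE) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  if (min(table(labels)) < 2L) stop("need at least 2 subjects per class")
  acc <- .with_seed(seed, vapply(seq_len(n_realisations), function(r) {
    lab <- if (shuffle_labels) sample(labels) else labels
    .loo_once(features, lab)
  }, numeric(1L)))
  structure(list(mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 accuracies = acc,
                 class_balance = max(table(labels)) / length(labels),
                 n_subjects = length(labels)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> ", x$n_subjects, " subjects, ",
      length(x$accuracies), " realisations\n", sep = "")
  cat("  accuracy ", format(x$mean_accuracy, digits = 4), " +/- ",
      format(x$sd_accuracy, digits = 3), " (majority-class rate ",
      format(x$class_balance, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Drop-one feature importance
#'
#' Importance of each of the six features as the drop in mean LOO accuracy
#' when an independent model is trained without it: `drop(f) = accuracy
#' with all six - accuracy with the other five`.  Larger drops mark more
#' informative features.
#'
#' @inheritParams loo_accuracy
#' @return Named numeric vector of accuracy drops (one per feature
#'   column), with the full six-feature mean accuracy as attribute
#'   `"full_accuracy"`.
#' @export
feature_importance_drop <- function(features, labels, n_realisations = 100L,
                                    seed = 1L) {
  features <- as.matrix(features)
  full <- loo_accuracy(features, labels, n_realisations, seed)$mean_accuracy
  drops <- vapply(seq_len(ncol(features)), function(j) {
    red <- loo_accuracy(features[, -j, drop = FALSE], labels,
                        n_realisations, seed + j)$mean_accuracy
    full - red
  }, numeric(1L))
  names(drops) <- colnames(features)
  attr(drops, "full_accuracy") <- full
  drops
}

#' Run one binary classification task in a given feature mode
#'
#' Convenience driver combining [build_feature_matrix()] and
#' [loo_accuracy()].  In the random-feature modes the six features are
#' redrawn once per realisation.
#'
#' @param summaries [stability_summary()] rows (stability modes).
#' @param labels two-class label vector aligned with the subjects.
#' @param mode feature mode; see [build_feature_matrix()].
#' @param mean_nets per-subject mean networks (random modes).
#' @param n_realisations,seed as in [loo_accuracy()].
#' @return A `classification_report`.
#' @export
classify_task <- function(summaries, labels,
                          mode = c("stability", "shuffled_labels",
                                   "random_links", "mixed_random"),
                          mean_nets = NULL, n_realisations = 100L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode %in% c("stability", "shuffled_labels")) {
    feats <- build_feature_matrix(summaries, "stability")
    return(loo_accuracy(feats, labels, n_realisations, seed,
                        shuffle_labels = mode == "shuffled_labels"))
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  acc <- .with_seed(seed, vapply(seq_len(n_realisations), function(r) {
    feats <- build_feature_matrix(mode = mode, mean_nets = mean_nets)
    .loo_once(feats, labels)
  }, numeric(1L)))
  structure(list(mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 accuracies = acc,
                 class_balance = max(table(labels)) / length(labels),
                 n_subjects = length(labels)),
            class = "classification_report")
}
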