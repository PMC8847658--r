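# Ranked per-window features: strongest link, top-m link sets, strength
# centrality and weighted local clustering.  Channel indices are 1-based;
# a link is the unordered pair (j, k), j < k.  All ties break toward the
# lexicographically smallest identity so that rankings are total and
# deterministic even on degenerate inputs.

# All links of an N-node network in lexicographic (j, k) order, as an
# L x 2 matrix, L = N (N - 1) / 2.
.link_pairs <- function(N) {
  j <- rep.int(seq_len(N - 1L), times = (N - 1L):1L)
  k <- unlist(lapply(seq_len(N - 1L), function(a) (a + 1L):N), use.names = FALSE)
  cbind(j = j, k = as.integer(k))
}

.link_weights <- function(net, pairs = .link_pairs(nrow(net))) {
  net[pairs]
}

#' Strongest link of a weighted network
#'
#' @param net symmetric N x N weight matrix (a `weighted_network`).
#' @return Integer pair `c(j, k)`, `j < k`, the link of maximal weight.
#'   Ties break toward the lexicographically smallest pair; an all-zero
#'   network returns `c(1, 2)` with attribute `degenerate = TRUE`.
#' @export
strongest_link <- function(net) {
  N <- nrow(net)
  stopifnot(N >= 2L)
  pairs <- .link_pairs(N)
  wts <- .link_weights(net, pairs)
  i <- which.max(wts)                      # first max = lexicographic smallest
  out <- pairs[i, ]
  if (wts[i] == 0) attr(out, "degenerate") <- TRUE
  out
}

#' The m largest-weight links of a network
#'
#' @param net symmetric weight matrix.
#' @param m number of links, `1 <= m <= N(N-1)/2`.
#' @return An m x 2 integer matrix of links in lexicographic order (the set
#'   identity does not depend on rank within the set).  Boundary ties break
#'   toward lexicographically smaller pairs.
#' @export
top_m_links <- function(net, m) {
  N <- nrow(net)
  L <- N * (N - 1L) / 2L
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m > L)
    stop("'m' must be in 1..", L)
  m <- as.integer(m)
  pairs <- .link_pairs(N)
  wts <- .link_weights(net, pairs)
  sel <- order(-wts, pairs[, 1L], pairs[, 2L])[seq_len(m)]
  pairs[sort(sel), , drop = FALSE]
}

#' Strength centrality
#'
#' Sum of the weights of the links incident to each node.
#'
#' @param net symmetric weight matrix with zero diagonal.
#' @return Numeric vector of length N.
#' @export
strength_centrality <- function(net) {
  unname(rowSums(net))
}

#' Weighted local clustering coefficient
#'
#' Geometric-mean triangle intensity around each node on weights normalised
#' by the network maximum: with `s = net / max(net)`,
#' `C_i = sum_{j != h != i} (s_ij s_ih s_jh)^(1/3) / ((N-1)(N-2))`.
#' On a uniform complete network every `C_i` is 1; an all-zero network
#' returns all zeros.
#'
#' @param net symmetric weight matrix with zero diagonal, N >= 3.
#' @return Numeric vector of length N in `[0, 1]`.
#' @export
local_clustering <- function(net) {
  N <- nrow(net)
  stopifnot(N >= 3L)
  mx <- max(net)
  if (mx == 0) return(numeric(N))
  A <- (net / mx)^(1 / 3)
  diag(A %*% A %*% A) / ((N - 1) * (N - 2))
}

#' Per-trial success probability under the independent-networks null
#'
#' Probability that a random draw reproduces a fixed feature identity when
#' consecutive networks are completely independent: the inverse of the
#' number of possible identities.  For the strongest link that is
#' `1 / (N(N-1)/2)`; for node features `1 / N`; for a top-m link set
#' `1 / choose(N(N-1)/2, m)`.
#'
#' @param feature a feature kind; see [feature_kind()].
#' @param N number of channels, N >= 3.
#' @return The per-trial probability p (0 < p < 1).
#' @export
per_trial_probability <- function(feature, N) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 3L)
  f <- feature_kind(feature)
  L <- N * (N - 1) / 2
  switch(f$kind,
         strongest_link = 1 / L,
         max_strength_node = ,
         max_clustering_node = 1 / N,
         top_m_links = {
           if (f$m < 1L || f$m > L) stop("'m' must be in 1..", L)
           exp(-lchoose(L, f$m))
         })
}

#' Feature-kind descriptors
#'
#' Normalises a feature specification to a canonical descriptor.  Accepted
#' kinds: `"strongest_link"`, `"max_strength_node"`, `"max_clustering_node"`
#' and `"top_m_links"` (which takes the set size `m`).
#'
#' @param feature a string naming the kind, or an existing descriptor.
#' @param m set size for `"top_m_links"`.
#' @return An object of class `feature_kind`: list with `kind`, optional
#'   `m`, and a `label` used in printed output.
#' @export
feature_kind <- function(feature, m = NULL) {
  if (inherits(feature, "feature_kind")) return(feature)
  kind <- match.arg(feature, c("strongest_link", "top_m_links",
                               "max_strength_node", "max_clustering_node"))
  if (kind == "top_m_links") {
    if (is.null(m)) stop("'top_m_links' needs the set size 'm'")
    m <- as.integer(m)
    label <- sprintf("top_%d_links", m)
  } else {
    m <- NULL
    label <- kind
  }
  structure(list(kind = kind, m = m, label = label), class = "feature_kind")
}

#' @export
print.feature_kind <- function(x, ...) {
  cat("<feature_kind>", x$label, "\n")
  invisible(x)
}

# Canonical string identity of one window's feature value, used for modal
# counting.  Links -> "j-k", nodes -> "n<j>", sets -> "j-k;j-k;...".
.identity_key <- function(value) {
  if (is.matrix(value)) {
    paste(paste(value[, 1L], value[, 2L], sep = "-"), collapse = ";")
  } else if (length(value) == 2L) {
    paste(value[1L], value[2L], sep = "-")
  } else {
    paste0("n", value)
  }
}

# Sort key under which the lexicographically smallest identity wins modal
# ties: zero-padded numeric fields so string order equals numeric order.
.identity_sort_key <- function(keys) {
  vapply(strsplit(gsub("n", "", keys), "[;-]"), function(parts)
    paste(formatC(as.integer(parts), width = 6, flag = "0"), collapse = ","),
    character(1L))
}

# Extract the per-window identity keys of a feature from a list of networks.
.identity_sequence <- function(networks, feature) {
  f <- feature_kind(feature)
  vapply(networks, function(net) {
    v <- switch(f$kind,
                strongest_link = strongest_link(net),
                top_m_links = top_m_links(net, f$m),
                max_strength_node = which.max(strength_centrality(net)),
                max_clustering_node = which.max(local_clustering(net)))
    .identity_key(v)
  }, character(1L))
}

# Modal identity and count of a key sequence, ties toward the smallest key.
.modal_identity <- function(keys) {
  tab <- table(keys)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) top <- top[order(.identity_sort_key(top))][1L]
  list(key = top, k = as.integer(max(tab)))
}

# Parse a canonical identity key back to its value.
.parse_identity <- function(key) {
  if (startsWith(key, "n")) return(as.integer(sub("^n", "", key)))
  pairs <- strsplit(strsplit(key, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- t(vapply(pairs, as.integer, integer(2L)))
  colnames(m) <- c("j", "k")
  if (nrow(m) == 1L) m[1L, ] else m
}
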