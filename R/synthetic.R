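#' Specification for a synthetic multichannel recording
#'
#' Describes a synthetic recording with known ground truth.  The defaults
#' emulate the resting-state acquisition the package targets: 32 channels
#' sampled at 500 Hz for 480 s (8 minutes, i.e. 240,000 samples per
#' channel) of unit-variance iid Gaussian noise.  Persistent structure can
#' be planted on top:
#'
#' * `planted_pairs` — list of pairs `list(j, k, rho, q, epoch_ms)`:
#'   channels j and k share a common latent Gaussian with mixing
#'   `sqrt(rho)` so their within-epoch correlation is `rho`; the recording
#'   is partitioned into epochs of `epoch_ms` and each epoch is
#'   independently active with probability `q` (outside active epochs the
#'   channels are plain noise).
#' * `planted_hub` — `list(hub, peripherals, rho)`: every peripheral
#'   channel mixes the hub's signal with coefficient `rho`, giving
#'   hub-peripheral correlation `rho` (and `rho^2` between peripherals);
#'   active throughout.
#'
#' @param N number of channels (>= 3).
#' @param duration_s recording length in seconds.
#' @param sampling_rate_hz sampling rate.
#' @param noise_sd standard deviation of the channel noise.
#' @param planted_pairs list of planted pair couplings (see above), or
#'   `NULL`.
#' @param planted_hub planted hub coupling, or `NULL`.
#' @param seed integer seed; every sample of the recording is a
#'   deterministic function of it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(N = 32, duration_s = 480, sampling_rate_hz = 500,
                           noise_sd = 1, planted_pairs = NULL,
                           planted_hub = NULL, seed = 1L) {
  stopifnot(N >= 3, duration_s > 0, sampling_rate_hz > 0, noise_sd > 0)
  norm_pair <- function(p) {
    p <- as.list(p)
    names(p) <- c("j", "k", "rho", "q", "epoch_ms")[seq_along(p)]
    p <- utils::modifyList(list(rho = 0.9, q = 1, epoch_ms = 30), p)
    if (p$j == p$k) stop("a planted pair must couple two distinct channels")
    stopifnot(p$j >= 1, p$k >= 1, p$j <= N, p$k <= N,
              p$rho > 0, p$rho <= 1, p$q > 0, p$q <= 1, p$epoch_ms > 0)
    if (p$j > p$k) { tmp <- p$j; p$j <- p$k; p$k <- tmp }
    p
  }
  if (!is.null(planted_pairs)) {
    if (!is.list(planted_pairs[[1L]])) planted_pairs <- list(planted_pairs)
    planted_pairs <- lapply(planted_pairs, norm_pair)
    ch <- unlist(lapply(planted_pairs, function(p) c(p$j, p$k)))
    if (anyDuplicated(ch)) stop("planted pairs must use distinct channels")
  }
  if (!is.null(planted_hub)) {
    names(planted_hub) <- c("hub", "peripherals", "rho")[seq_along(planted_hub)]
    stopifnot(planted_hub$hub >= 1, planted_hub$hub <= N,
              all(planted_hub$peripherals >= 1),
              all(planted_hub$peripherals <= N),
              !planted_hub$hub %in% planted_hub$peripherals,
              planted_hub$rho > 0, planted_hub$rho <= 1)
  }
  structure(list(N = as.integer(N), duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz, noise_sd = noise_sd,
                 planted_pairs = planted_pairs, planted_hub = planted_hub,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Run `expr` under a seeded RNG without disturbing the caller's stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a null (pure-noise) recording
#'
#' iid Gaussian samples on every channel; the realisation of the
#' independent-networks null hypothesis against which feature stability is
#' scored.  Fully reproducible from the spec seed.
#'
#' @param spec a [synthetic_spec()] without planted structure.
#' @return A [recording].
#' @export
generate_null <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$planted_pairs) || !is.null(spec$planted_hub))
    stop("spec has planted structure; use generate_planted()")
  l <- floor(spec$duration_s * spec$sampling_rate_hz)
  data <- .with_seed(spec$seed,
                     matrix(stats::rnorm(spec$N * l, sd = spec$noise_sd),
                            nrow = spec$N))
  recording(data, spec$sampling_rate_hz,
            subject_id = paste0("null_seed", spec$seed))
}

#' Generate a recording with planted persistent structure
#'
#' Starts from the null recording of the same spec seed and overwrites the
#' planted channels: within active epochs a coupled pair's channels are
#' `sqrt(rho) * z + sqrt(1 - rho) * e`, sharing the latent `z`, so their
#' population correlation is exactly `rho`; hub peripherals mix the hub
#' signal with coefficient `rho`.  All channels keep unit marginal
#' variance (times `noise_sd`).
#'
#' @param spec a [synthetic_spec()] with at least one planted pair or hub.
#' @return A list with `recording` (a [recording]) and `ground_truth`: the
#'   planted identities plus, per planted pair, the logical active-epoch
#'   mask over samples.
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$planted_pairs) && is.null(spec$planted_hub))
    stop("spec has no planted structure; use generate_null()")
  l <- floor(spec$duration_s * spec$sampling_rate_hz)
  gt <- list(planted_pairs = spec$planted_pairs, planted_hub = spec$planted_hub,
             masks = list())
  data <- .with_seed(spec$seed, {
    X <- matrix(stats::rnorm(spec$N * l), nrow = spec$N)
    for (pp in spec$planted_pairs) {
      epoch <- max(2L, floor(pp$epoch_ms * spec$sampling_rate_hz / 1000))
      n_epochs <- ceiling(l / epoch)
      active <- stats::runif(n_epochs) <= pp$q
      mask <- rep(active, each = epoch)[seq_len(l)]
      idx <- which(mask)
      if (length(idx)) {
        z <- stats::rnorm(length(idx))
        a <- sqrt(pp$rho); b <- sqrt(1 - pp$rho)
        X[pp$j, idx] <- a * z + b * stats::rnorm(length(idx))
        X[pp$k, idx] <- a * z + b * stats::rnorm(length(idx))
      }
      gt$masks[[length(gt$masks) + 1L]] <- mask
    }
    if (!is.null(spec$planted_hub)) {
      h <- spec$planted_hub
      zh <- X[h$hub, ]
      b <- sqrt(1 - h$rho^2)
      for (pn in h$peripherals)
        X[pn, ] <- h$rho * zh + b * stats::rnorm(l)
    }
    X * spec$noise_sd
  })
  rec <- recording(data, spec$sampling_rate_hz,
                   subject_id = paste0("planted_seed", spec$seed))
  list(recording = rec, ground_truth = gt)
}

#' Generate a group of synthetic subjects
#'
#' Derives one deterministic seed per subject from the template's master
#' seed and generates each subject from it.  Planted identities can be
#' shared across subjects (intra-group experiments) or re-randomised per
#' subject; coupling strength can be jittered between subjects.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param template a [synthetic_spec()] used for every subject.
#' @param shared_structure if `TRUE` (default) all subjects carry the
#'   template's planted identities; if `FALSE` each subject gets fresh
#'   uniformly drawn planted channel pairs of the same strength.
#' @param rho_jitter_sd between-subject standard deviation added to each
#'   planted coupling `rho` (clipped to (0.05, 1]).  Default 0.
#' @return A list of `n_subjects` elements; each is a [recording] for null
#'   templates, or a `list(recording, ground_truth)` for planted ones.
#' @export
generate_group <- function(n_subjects, template, shared_structure = TRUE,
                           rho_jitter_sd = 0) {
  stopifnot(inherits(template, "synthetic_spec"), n_subjects >= 1)
  lapply(seq_len(n_subjects), function(s) {
    sp <- template
    sp$seed <- (template$seed * 1000L + s) %% .Machine$integer.max
    null_spec <- is.null(sp$planted_pairs) && is.null(sp$planted_hub)
    if (!null_spec && (!shared_structure || rho_jitter_sd > 0)) {
      sp$planted_pairs <- .with_seed(sp$seed + 7L, lapply(sp$planted_pairs,
        function(pp) {
          if (!shared_structure) {
            jk <- sample(template$N, 2L)
            pp$j <- min(jk); pp$k <- max(jk)
          }
          if (rho_jitter_sd > 0)
            pp$rho <- min(1, max(0.05, pp$rho +
                                   stats::rnorm(1L, sd = rho_jitter_sd)))
          pp
        }))
    }
    out <- if (null_spec) generate_null(sp) else generate_planted(sp)
    id <- sprintf("synth%03d", s)
    if (inherits(out, "recording")) out$subject_id <- id
    else out$recording$subject_id <- id
    out
  })
}
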