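make_profiles <- function(seeds, N = 5, l = 600, grid = c(40, 100, 250)) {
  lapply(seeds, function(s)
    stability_profile(noise_recording(N = N, l = l, seed = s),
                      "strongest_link", grid_ms = grid))
}

test_that("group means average pointwise and identical subjects collapse", {
  p <- make_profiles(3)[[1]]
  gp <- group_mean_profile(list(p, p, p), group = "g")
  expect_equal(gp$grid$mean_ln_pi, p$grid$ln_pi)
  expect_equal(gp$best_window_ms, p$best_window_ms)
  env <- gp$envelope
  expect_equal(env["best_window_ms", "min"], env["best_window_ms", "max"])
  expect_equal(env["min_ln_pi", "min"], env["min_ln_pi", "max"])

  two <- make_profiles(c(5, 6))
  gp2 <- group_mean_profile(two)
  expect_equal(gp2$grid$mean_ln_pi,
               (two[[1]]$grid$ln_pi + two[[2]]$grid$ln_pi) / 2)
})

test_that("group mean over many subjects matches external averaging", {
  profs <- make_profiles(1:10)
  gp <- group_mean_profile(profs)
  ext <- rowMeans(vapply(profs, function(p) p$grid$ln_pi, numeric(3)))
  expect_equal(gp$grid$mean_ln_pi, unname(ext))
  best <- which.min(ext)
  expect_equal(gp$best_window_ms, profs[[1]]$grid$window_ms[best])
})

test_that("jackknife envelopes equal explicit leave-one-out recomputation", {
  profs <- make_profiles(11:15)
  env <- jackknife_envelope(profs)
  loo <- t(vapply(1:5, function(i) {
    m <- rowMeans(vapply(profs[-i], function(p) p$grid$ln_pi, numeric(3)))
    b <- which.min(m)
    c(profs[[1]]$grid$window_ms[b], m[b])
  }, numeric(2)))
  expect_equal(env["best_window_ms", ], c(min = min(loo[, 1]), max = max(loo[, 1])))
  expect_equal(env["min_ln_pi", ], c(min = min(loo[, 2]), max = max(loo[, 2])))
  expect_error(jackknife_envelope(profs[1]), "at least 2")
})

test_that("envelopes bracket the full-group value and catch outliers", {
  profs <- make_profiles(21:24)
  # an outlier subject: shift its curve far down at one grid point
  out <- profs[[1]]
  out$grid$ln_pi[2] <- -500
  profs[[1]] <- out
  gp <- group_mean_profile(profs)
  env <- gp$envelope
  expect_lte(env["min_ln_pi", "min"], gp$min_ln_pi)
  expect_gte(env["min_ln_pi", "max"], gp$min_ln_pi)
  expect_lte(env["best_window_ms", "min"], gp$best_window_ms)
  expect_gte(env["best_window_ms", "max"], gp$best_window_ms)
  # deleting the outlier must give the upper ln-pi bound
  m_wo <- rowMeans(vapply(profs[-1], function(p) p$grid$ln_pi, numeric(3)))
  expect_equal(env["min_ln_pi", "max"], min(m_wo))
})

test_that("intra-group pooling of one subject is bit-identical to per-subject", {
  rec <- noise_recording(N = 6, l = 600, seed = 31)
  pooled <- intra_group_stability(list(rec), "strongest_link",
                                  grid_ms = c(40, 100))
  solo <- stability_profile(rec, "strongest_link", grid_ms = c(40, 100))
  expect_identical(pooled$k, solo$grid$k)
  expect_identical(pooled$n, solo$grid$n)
  expect_identical(pooled$ln_pi, solo$grid$ln_pi)
  expect_identical(pooled$modal, solo$grid$modal)
})

test_that("pooled n is conserved and shared planted structure dominates", {
  recs <- lapply(1:3, function(s) noise_recording(N = 5, l = 400 + 100 * s,
                                                  seed = 60 + s))
  pooled <- intra_group_stability(recs, "strongest_link", grid_ms = c(50))
  expect_identical(pooled$n,
                   sum(vapply(recs, function(r)
                     ncol(r$data) %/% 25L, integer(1))))

  # four subjects sharing one planted pair: pooled ln pi far below any solo
  subs <- generate_group(4, synthetic_spec(N = 8, duration_s = 8, seed = 71,
                                           planted_pairs = list(list(2, 6, 0.9, 1, 30))))
  recs2 <- lapply(subs, `[[`, "recording")
  pooled2 <- intra_group_stability(recs2, "strongest_link", grid_ms = c(30))
  solos <- vapply(recs2, function(r)
    stability_profile(r, "strongest_link", grid_ms = c(30))$min_ln_pi,
    numeric(1))
  expect_identical(pooled2$modal, "2-6")
  expect_lt(pooled2$ln_pi, min(solos) * 2)
})

test_that("intra-group modal ties break lexicographically", {
  set.seed(83)
  base1 <- matrix(rnorm(4 * 200), nrow = 4); base1[2, ] <- base1[1, ]
  base2 <- matrix(rnorm(4 * 200), nrow = 4); base2[4, ] <- base2[3, ]
  recA <- recording(base1, 500, subject_id = "A")  # modal always (1,2)
  recB <- recording(base2, 500, subject_id = "B")  # modal always (3,4)
  pooled <- intra_group_stability(list(recA, recB), "strongest_link",
                                  grid_ms = c(100))
  expect_identical(pooled$modal, "1-2")
  expect_identical(pooled$k, 4L)   # equal counts, tie to the smaller pair
  expect_identical(pooled$n, 8L)
})

test_that("upsampling splits into equal parts with the remainder discarded", {
  rec <- recording(matrix(0.0 + seq_len(3 * 240000), nrow = 3), 500,
                   subject_id = "s")
  parts <- upsample_split(rec, 5)
  expect_length(parts, 5L)
  expect_true(all(vapply(parts, function(p) ncol(p$data), integer(1)) == 48000L))
  expect_identical(parts[[1]]$subject_id, "s_p1")
  expect_identical(unname(parts[[2]]$data), unname(rec$data[, 48001:96000]))

  rec11 <- recording(matrix(rnorm(33), nrow = 3), 500)
  p11 <- upsample_split(rec11, 5)
  expect_true(all(vapply(p11, function(p) ncol(p$data), integer(1)) == 2L))
})

test_that("upsampled parts recover the planted timescale like the whole", {
  sp <- synthetic_spec(N = 8, duration_s = 50, seed = 91,
                       planted_pairs = list(list(2, 6, 0.9, 0.8, 30)))
  rec <- generate_planted(sp)$recording
  grid <- c(10, 15, 22, 33, 49, 73, 110)
  whole <- stability_profile(rec, "strongest_link", grid_ms = grid)
  parts <- upsample_split(rec, 5)
  part_best <- vapply(parts, function(p)
    stability_profile(p, "strongest_link", grid_ms = grid)$best_window_ms,
    numeric(1))
  gi <- match(whole$best_window_ms, grid)
  lo <- grid[max(1, gi - 1)]; hi <- grid[min(length(grid), gi + 1)]
  expect_true(all(part_best >= lo & part_best <= hi))
})

test_that("KS comparison of best windows behaves at the extremes", {
  same <- compare_best_windows(c(20, 30, 40, 50), c(20, 30, 40, 50))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  far <- compare_best_windows(rep(10:19, 5), rep(100:109, 5))
  expect_equal(far$statistic, 1)
  # agreement with a manual ECDF-distance oracle
  set.seed(97)
  a <- rnorm(30); b <- rnorm(25, mean = 0.8)
  got <- compare_best_windows(a, b)
  grid <- sort(c(a, b))
  d <- max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x),
                      numeric(1))))
  expect_equal(got$statistic, d, tolerance = 1e-12)
})
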