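test_that("modal identity and count follow the tie rules", {
  nets <- replicate(5, net_with_strongest(8, c(3, 7)), simplify = FALSE)
  res <- stability_at_window(make_series(nets), "strongest_link")
  expect_identical(unname(res$modal_identity), c(3L, 7L))
  expect_identical(res$k, 5L)
  expect_identical(res$n, 5L)
  expect_equal(res$p, 1 / 28)
  expect_identical(res$ln_pi, 5 * log(1 / 28))

  nets2 <- list(net_with_strongest(4, c(1, 2)),
                net_with_strongest(4, c(1, 2)),
                net_with_strongest(4, c(2, 3)))
  res2 <- stability_at_window(make_series(nets2), "strongest_link")
  expect_identical(unname(res2$modal_identity), c(1L, 2L))
  expect_identical(res2$k, 2L)
  expect_identical(res2$n, 3L)

  # modal tie between (1,3) and (2,3): lexicographically smaller wins
  nets3 <- list(net_with_strongest(4, c(2, 3)),
                net_with_strongest(4, c(1, 3)))
  res3 <- stability_at_window(make_series(nets3), "strongest_link")
  expect_identical(unname(res3$modal_identity), c(1L, 3L))
})

test_that("profile and per-window routes agree", {
  rec <- noise_recording(N = 6, l = 600, seed = 13)
  fit <- stability_profile(rec, "strongest_link", grid_ms = c(40, 100))
  for (i in 1:2) {
    series <- reconstruct(rec, c(40, 100)[i])
    ref <- stability_at_window(series, "strongest_link")
    expect_identical(fit$grid$k[i], ref$k)
    expect_identical(fit$grid$n[i], ref$n)
    expect_identical(fit$grid$ln_pi[i], ref$ln_pi)
    expect_identical(fit$grid$modal[i], ref$modal_key)
  }
})

test_that("top-1 link-set stability is identical to strongest-link stability", {
  rec <- noise_recording(N = 6, l = 500, seed = 17)
  a <- stability_profile(rec, "strongest_link", grid_ms = c(30, 80, 160))
  b <- stability_profile(rec, "top_m_links", grid_ms = c(30, 80, 160), m = 1)
  expect_identical(a$grid$k, b$grid$k)
  expect_identical(a$grid$n, b$grid$n)
  expect_equal(a$grid$p, b$grid$p)
  expect_equal(a$grid$ln_pi, b$grid$ln_pi)
  expect_identical(a$best_window_ms, b$best_window_ms)
})

test_that("channel relabeling permutes identities but not k, n, p, ln_pi", {
  rec <- noise_recording(N = 6, l = 600, seed = 19)
  perm <- c(4, 6, 1, 3, 2, 5)
  recp <- recording(rec$data[perm, ], rec$sampling_rate_hz,
                    subject_id = "perm")
  for (feat in c("strongest_link", "max_strength_node",
                 "max_clustering_node")) {
    a <- stability_profile(rec, feat, grid_ms = c(50, 120))
    b <- stability_profile(recp, feat, grid_ms = c(50, 120))
    expect_identical(a$grid$k, b$grid$k)
    expect_identical(a$grid$n, b$grid$n)
    expect_equal(a$grid$p, b$grid$p)
    expect_equal(a$grid$ln_pi, b$grid$ln_pi)
  }
})

test_that("grid handling: single point, skipped infeasible entries, errors", {
  rec <- noise_recording(N = 4, l = 400, seed = 23)
  one <- stability_profile(rec, "strongest_link", grid_ms = c(60))
  expect_identical(one$best_window_ms, 60)
  expect_warning(
    fit <- stability_profile(rec, "strongest_link", grid_ms = c(2, 60)),
    "skipping")
  expect_identical(nrow(fit$grid), 1L)
  expect_error(suppressWarnings(
    stability_profile(rec, "strongest_link", grid_ms = c(1, 2))),
    "no feasible")
  expect_error(stability_profile(rec, "strongest_link", grid_ms = c(60, 30)),
               "strictly increasing")
})

test_that("null recordings show no deep stability minimum", {
  rec <- noise_recording(N = 8, l = 4000, seed = 29)
  fit <- stability_profile(rec, "strongest_link",
                           grid_ms = c(20, 60, 200, 600))
  # a planted recording at this size reaches ln pi < -1000 (see recovery
  # tests); the null stays orders of magnitude closer to zero
  expect_gt(fit$min_ln_pi, -60)
})

test_that("rank gaps match a per-window two-largest oracle", {
  set.seed(37)
  base <- matrix(rnorm(6 * 400), nrow = 6)
  base[2, ] <- base[1, ]          # duplicate pair: s1 = 1 exactly
  base[4, ] <- base[3, ]          # second duplicate pair: s2 = 1 exactly
  rec <- recording(base, 500, subject_id = "dup")
  rg <- rank_gap_profile(rec, grid_ms = c(40, 100))
  expect_equal(rg$mean_gap, c(0, 0))   # log2(1/1) in every window

  rec2 <- noise_recording(N = 5, l = 500, seed = 41)
  rg2 <- rank_gap_profile(rec2, grid_ms = c(50))
  series <- reconstruct(rec2, 50)
  gaps <- vapply(series$networks, function(W) {
    s <- sort(W[upper.tri(W)], decreasing = TRUE)[1:2]
    log2(s[1] / s[2])
  }, numeric(1))
  expect_equal(rg2$mean_gap, mean(gaps), tolerance = 1e-12)
  expect_identical(rg2$n_excluded, 0L)
})

test_that("stability summaries carry the six metrics and their profiles", {
  rec <- noise_recording(N = 5, l = 800, seed = 43)
  s <- stability_summary(rec, grid_ms = c(30, 80, 200))
  expect_identical(nrow(s), 1L)
  expect_true(all(stability_metric_names() %in% names(s)))
  profs <- attr(s, "profiles")
  expect_named(profs, c("strongest_link", "max_strength_node",
                        "max_clustering_node"))
  # summary row agrees with independently fitted single-feature profiles
  ref <- stability_profile(rec, "max_strength_node", grid_ms = c(30, 80, 200))
  expect_identical(s$max_strength_node_min_ln_pi, ref$min_ln_pi)
  expect_identical(s$max_strength_node_best_window_ms, ref$best_window_ms)
  expect_true(all(s[[paste0("strongest_link_min_ln_pi")]] <= 0))
})

test_that("planted persistent links are recovered near their epoch timescale", {
  sp <- synthetic_spec(N = 8, duration_s = 20, seed = 47,
                       planted_pairs = list(list(2, 6, 0.9, 0.8, 30)))
  g <- generate_planted(sp)
  fit <- stability_profile(g$recording, "strongest_link",
                           grid_ms = c(10, 15, 22, 33, 49, 73, 110, 240))
  expect_identical(fit$grid$modal[which.min(fit$grid$ln_pi)], "2-6")
  expect_gte(fit$best_window_ms, 15)
  expect_lte(fit$best_window_ms, 60)
})
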