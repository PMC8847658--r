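test_that("generation is seed-deterministic and seed-sensitive", {
  sp <- synthetic_spec(N = 5, duration_s = 2, seed = 7)
  a <- generate_null(sp)
  b <- generate_null(sp)
  expect_identical(a$data, b$data)
  c <- generate_null(synthetic_spec(N = 5, duration_s = 2, seed = 8))
  expect_false(identical(a$data, c$data))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_null(sp)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("null recordings look uncorrelated at the 1000-sample scale", {
  rec <- generate_null(synthetic_spec(N = 32, duration_s = 10, seed = 13))
  series <- reconstruct(rec, 2000)       # 1000-sample windows
  r <- unlist(lapply(series$networks, function(W) W[upper.tri(W)]))
  expect_gte(mean(r < 0.1), 0.99)
})

test_that("planted pairs dominate the per-window strongest link", {
  sp <- synthetic_spec(N = 8, duration_s = 12, seed = 17,
                       planted_pairs = list(list(3, 5, 0.95, 1, 30)))
  g <- generate_planted(sp)
  series <- reconstruct(g$recording, 30)
  ids <- vapply(series$networks,
                function(W) paste(strongest_link(W), collapse = "-"),
                character(1))
  expect_gte(mean(ids == "3-5"), 0.95)
  expect_identical(length(g$ground_truth$masks[[1]]), ncol(g$recording$data))
  expect_true(all(g$ground_truth$masks[[1]]))          # q = 1: always active
})

test_that("epoch masks follow the persistence fraction", {
  sp <- synthetic_spec(N = 6, duration_s = 60, seed = 19,
                       planted_pairs = list(list(1, 2, 0.9, 0.7, 30)))
  g <- generate_planted(sp)
  mask <- g$ground_truth$masks[[1]]
  expect_equal(mean(mask), 0.7, tolerance = 0.06)
  # within active samples the pair correlates near rho; outside, near zero
  r_on <- cor(g$recording$data[1, mask], g$recording$data[2, mask])
  r_off <- cor(g$recording$data[1, !mask], g$recording$data[2, !mask])
  expect_equal(r_on, 0.9, tolerance = 0.03)
  expect_lt(abs(r_off), 0.05)
})

test_that("vanishing coupling is indistinguishable from noise", {
  sp <- synthetic_spec(N = 6, duration_s = 20, seed = 23,
                       planted_pairs = list(list(1, 2, 1e-4, 1, 30)))
  g <- generate_planted(sp)
  r <- cor(g$recording$data[1, ], g$recording$data[2, ])
  expect_lt(abs(r), 0.03)
  expect_equal(sd(g$recording$data[1, ]), 1, tolerance = 0.03)
})

test_that("planted hubs become the modal max-strength node", {
  sp <- synthetic_spec(N = 10, duration_s = 12, seed = 29,
                       planted_hub = list(4, c(1, 2, 6, 8, 9), 0.9))
  g <- generate_planted(sp)
  series <- reconstruct(g$recording, 60)
  nodes <- vapply(series$networks,
                  function(W) which.max(strength_centrality(W)), integer(1))
  expect_identical(as.integer(names(which.max(table(nodes)))), 4L)
})

test_that("groups derive deterministic per-subject seeds", {
  tpl <- synthetic_spec(N = 6, duration_s = 4, seed = 31,
                        planted_pairs = list(list(2, 5, 0.9, 1, 30)))
  grp <- generate_group(3, tpl)
  expect_length(grp, 3L)
  expect_false(identical(grp[[1]]$recording$data, grp[[2]]$recording$data))
  # n_subjects = 1 equals generate_planted at the derived seed
  one <- generate_group(1, tpl)[[1]]
  tpl1 <- tpl; tpl1$seed <- tpl$seed * 1000L + 1L
  ref <- generate_planted(tpl1)
  expect_identical(one$recording$data, ref$recording$data)
  # shared structure keeps the planted identity; re-randomisation moves it
  expect_true(all(vapply(grp, function(s)
    identical(c(s$ground_truth$planted_pairs[[1]]$j,
                s$ground_truth$planted_pairs[[1]]$k), c(2, 5)), logical(1))))
  grp2 <- generate_group(6, tpl, shared_structure = FALSE)
  ids <- vapply(grp2, function(s)
    paste(s$ground_truth$planted_pairs[[1]]$j,
          s$ground_truth$planted_pairs[[1]]$k), character(1))
  expect_gt(length(unique(ids)), 1L)
})

test_that("spec validation rejects malformed planted structure", {
  expect_error(synthetic_spec(N = 5, planted_pairs = list(list(2, 2, 0.9))),
               "distinct channels")
  expect_error(synthetic_spec(N = 5, planted_pairs = list(list(1, 9, 0.9))))
  expect_error(synthetic_spec(N = 5, planted_hub = list(2, c(2, 3), 0.5)))
  expect_error(generate_null(synthetic_spec(
    N = 5, planted_pairs = list(list(1, 2, 0.5)))), "planted structure")
  expect_error(generate_planted(synthetic_spec(N = 5)), "no planted")
})
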