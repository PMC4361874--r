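defn <- default_bundle()

test_that("pair distances are plain Euclidean distances", {
  b <- make_ca_bundle(list(`3.50` = c(0, 0, 0), `3.52` = c(3, 4, 0),
                           `3.54` = c(0, 0, 0)), defn)
  expect_equal(pair_distance(b, "3.50", "3.52"), 5)
  expect_equal(pair_distance(b, "3.50", "3.54"), 0)
  expect_error(pair_distance(b, "3.50", "3.51"), "missing")
  # adjacent backbone neighbours of the ideal helix sit near 3.8 A
  ens <- generate_ensemble(generator_spec(n_members = 2, seed = 1,
                                          trans_sigma = 0, rot_sigma = 0,
                                          coord_sigma = 0), defn)
  expect_equal(pair_distance(ens$members[[1]], "3.50", "3.51"), 3.8,
               tolerance = 0.03)
})

test_that("score_set matches the brute-force oracle to 1e-9 relative", {
  tiny <- random_small_ensemble(defn, n_members = 5, n_positions = 12)
  stats <- score_set(tiny$ensemble, defn)
  pr <- enumerate_pairs(defn, tiny$ids)
  orc <- oracle_pair_stats(tiny$coords, pr)
  expect_equal(nrow(stats), nrow(orc))
  expect_equal(stats$mean, orc$mean, tolerance = 1e-9)
  expect_equal(stats$sd, orc$sd, tolerance = 1e-9)
  expect_equal(stats$min, orc$min, tolerance = 1e-9)
  expect_equal(stats$max, orc$max, tolerance = 1e-9)
  expect_equal(stats$score, orc$score, tolerance = 1e-9)
  expect_true(all(stats$min <= stats$mean & stats$mean <= stats$max))
})

test_that("an engineered pair with mean 20 A and SD 0.4 A scores 50", {
  m1 <- make_ca_bundle(list(`3.50` = c(0, 0, 0), `6.50` = c(19.6, 0, 0)),
                       defn, source_id = "E1")
  m2 <- make_ca_bundle(list(`3.50` = c(0, 0, 0), `6.50` = c(20.4, 0, 0)),
                       defn, source_id = "E2")
  stats <- score_set(build_set(list(m1, m2), "eng"), defn)
  expect_equal(stats$mean, 20)
  expect_equal(stats$sd, 0.4)
  expect_equal(stats$score, 50)
})

test_that("identical members give zero spread and a capped score", {
  ens <- generate_ensemble(generator_spec(n_members = 3, seed = 5,
                                          trans_sigma = 0, rot_sigma = 0,
                                          coord_sigma = 0), defn)
  stats <- score_set(ens, defn, score_cap = 1e6)
  expect_true(all(stats$capped))
  expect_true(all(stats$score == 1e6))
  expect_true(all(stats$sd == 0))
})

test_that("scores are scale-invariant; statistics scale linearly", {
  tiny <- random_small_ensemble(defn, n_members = 4, n_positions = 8,
                                seed = 11)
  s1 <- score_set(tiny$ensemble, defn)
  k <- 2.7
  scaled <- build_set(lapply(tiny$ensemble$members, function(m)
    aligned_bundle(m$ca * k, defn, source_id = m$source_id)), "scaled")
  s2 <- score_set(scaled, defn)
  expect_equal(s2$mean, s1$mean * k, tolerance = 1e-9)
  expect_equal(s2$sd, s1$sd * k, tolerance = 1e-9)
  expect_equal(s2$min, s1$min * k, tolerance = 1e-9)
  expect_equal(s2$max, s1$max * k, tolerance = 1e-9)
  expect_equal(s2$score, s1$score, tolerance = 1e-9)
})

test_that("scores are invariant under per-member rigid motions", {
  tiny <- random_small_ensemble(defn, n_members = 4, n_positions = 8,
                                seed = 12)
  s1 <- score_set(tiny$ensemble, defn)
  set.seed(99)
  moved <- build_set(lapply(tiny$ensemble$members, function(m) {
    rg <- random_rigid()
    ca <- apply_rigid(m$ca, rg)
    rownames(ca) <- rownames(m$ca)
    aligned_bundle(ca, defn, source_id = m$source_id)
  }), "moved")
  s2 <- score_set(moved, defn)
  expect_equal(s2$mean, s1$mean, tolerance = 1e-9)
  expect_equal(s2$sd, s1$sd, tolerance = 1e-8)
  expect_equal(s2$score, s1$score, tolerance = 1e-6)
})

test_that("ranking is deterministic, order-independent and adjacency-aware", {
  tiny <- random_small_ensemble(defn, n_members = 5, n_positions = 20,
                                seed = 13)
  stats <- score_set(tiny$ensemble, defn)
  rk <- rank_pairs(stats, exclude_adjacent = TRUE, top_n = 10)
  expect_true(all(diff(rk$ranked$score) <= 0))
  expect_false(any(rk$ranked$adjacent))
  expect_equal(nrow(rk$top), 10L)
  # shuffled input gives the identical table
  set.seed(1)
  shuffled <- stats[sample(nrow(stats)), ]
  rk2 <- rank_pairs(shuffled, exclude_adjacent = TRUE, top_n = 10)
  rownames(rk2$ranked) <- NULL
  expect_identical(rk$ranked, rk2$ranked)
  # top_n beyond the table
  expect_warning(rk3 <- rank_pairs(stats, top_n = 1e6), "exceeds")
  expect_equal(nrow(rk3$top), nrow(rk3$ranked))
})

test_that("ties at the top_n boundary break by canonical pair order", {
  m1 <- make_ca_bundle(list(`1.40` = c(0, 0, 0), `2.50` = c(10, 0, 0),
                            `3.40` = c(0, 10, 0), `4.50` = c(10, 10, 0)),
                       defn, source_id = "T1")
  m2 <- make_ca_bundle(list(`1.40` = c(0, 0, 0), `2.50` = c(11, 0, 0),
                            `3.40` = c(0, 11, 0), `4.50` = c(11, 11, 0)),
                       defn, source_id = "T2")
  stats <- score_set(build_set(list(m1, m2), "ties"), defn)
  rk <- rank_pairs(stats, top_n = 3)
  # equal scores resolve by (a, b) canonical order
  tied <- rk$ranked[rk$ranked$score == max(rk$ranked$score), ]
  expect_identical(order(tied$a, tied$b), seq_len(nrow(tied)))
})

test_that("profile histograms conserve counts", {
  tiny <- random_small_ensemble(defn, n_members = 4, n_positions = 15,
                                seed = 14)
  fit <- dcons(tiny$ensemble, defn, top_n = 20)
  pf <- score_distance_profile(fit)
  expect_equal(sum(pf$score_hist$count_all), fit$universe)
  expect_equal(utils::tail(pf$score_hist$cum_all, 1), fit$universe)
  expect_equal(sum(pf$score_hist$count_nonadjacent),
               sum(!fit$stats$adjacent))
  expect_equal(sum(pf$distance_hist$count_all), fit$universe)
  expect_equal(sum(pf$distance_hist$count_top), nrow(fit$top))
  expect_equal(nrow(pf$scatter), fit$universe)
})

test_that("adjacent pairs form the high-score cluster near 3.8 A", {
  ens <- generate_ensemble(generator_spec(n_members = 8, seed = 21,
                                          coord_sigma = 0.05), defn)
  stats <- score_set(ens, defn)
  adj <- stats[stats$adjacent, ]
  expect_equal(mean(adj$mean), 3.8, tolerance = 0.05)
  # the cluster outranks the typical non-adjacent pair and disappears
  # when adjacency is excluded
  expect_gt(stats::median(adj$score),
            stats::median(stats$score[!stats$adjacent]))
  rk <- rank_pairs(stats, exclude_adjacent = TRUE, top_n = 100)
  expect_false(any(abs(rk$top$mean - 3.8) < 0.1 & rk$top$adjacent))
})

test_that("quiet helix III outscores noisy helices IV and VII", {
  for (seed in c(31, 32)) {
    ens <- generate_ensemble(preset("rhodopsin_like", seed = seed), defn)
    stats <- score_set(ens, defn)
    nonadj <- stats[!stats$adjacent, ]
    med <- function(hp) stats::median(nonadj$score[nonadj$helix_pair == hp])
    expect_gt(med("III-III"), med("IV-IV"))
    expect_gt(med("III-III"), med("VII-VII"))
  }
})
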