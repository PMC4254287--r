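test_that("geometric parameter estimation is the inverse mean", {
  expect_equal(estimate_geometric_p(c(1, 3)), 0.5)
  expect_equal(estimate_geometric_p(rep(1, 10)), 1)
  # observed mean cluster size 1.223 corresponds to p of about 0.818
  sizes <- c(rep(1, 777), rep(2, 223))  # mean 1.223
  expect_equal(estimate_geometric_p(sizes), 1 / 1.223, tolerance = 1e-12)
  expect_equal(estimate_geometric_p(sizes), 0.8177, tolerance = 1e-3)
  expect_error(estimate_geometric_p(numeric(0)), "empty")
})

test_that("truncated geometric sampling respects its support", {
  model <- geometric_size_model(0.8, max_size = 4)
  set.seed(3)
  sizes <- sample_cluster_sizes(5000, model)
  expect_true(all(sizes >= 1 & sizes <= 4))
  one <- sample_cluster_sizes(100, geometric_size_model(1, 10))
  expect_equal(one, rep(1L, 100))
})

test_that("abundance-only generation assigns every occurrence exactly once", {
  freqs <- setNames(c(0.4, 0.3, 0.2, 0.1), c("A", "B", "C", "D"))
  cfg <- simulation_config(freqs, n_occurrences = 500, p = 0.75, seed = 5)
  clusters <- generate_null_clusters(cfg)
  expect_equal(sum(lengths(clusters)), 500)
  expect_true(all(vapply(clusters, anyDuplicated, 1L) == 0))

  # p = 1 means every cluster is a singleton and cluster count equals N
  cfg1 <- simulation_config(freqs, n_occurrences = 200, p = 1, seed = 6)
  singles <- generate_null_clusters(cfg1)
  expect_equal(length(singles), 200)
  expect_true(all(lengths(singles) == 1))
})

test_that("generated species frequencies follow the inputs", {
  freqs <- setNames(c(0.5, 0.25, 0.15, 0.1), c("A", "B", "C", "D"))
  cfg <- simulation_config(freqs, n_occurrences = 2e4, p = 0.8, seed = 9)
  clusters <- generate_null_clusters(cfg)
  counts <- table(factor(unlist(clusters), levels = names(freqs)))
  se <- sqrt(2e4 * freqs * (1 - freqs))
  expect_true(all(abs(counts - 2e4 * freqs) <= 3 * se))
  # mean cluster size near 1/p
  expect_equal(mean(lengths(clusters)), 1 / 0.8, tolerance = 0.05)
})

test_that("association difference is a normalized squared distance", {
  mk <- function(m) {
    dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
    storage.mode(m) <- "integer"
    class(m) <- c("co_occurrence_counts", class(m))
    m
  }
  ab <- mk(matrix(c(0, 4, 0, 4, 0, 0, 0, 0, 0), 3))
  ac <- mk(matrix(c(0, 0, 2, 0, 0, 0, 2, 0, 0), 3))
  expect_equal(association_difference(ab, ab), 0)
  # all mass on (A,B) versus all mass on (A,C): two unit differences
  expect_equal(association_difference(ab, ac), 2)
  # scaling either side leaves the score unchanged
  ab3 <- mk(unclass(ab) * 3L)
  expect_equal(association_difference(ab3, ac),
               association_difference(ab, ac))
  bad <- mk(matrix(0L, 3, 3))
  dimnames(bad) <- list(c("X", "Y", "Z"), c("X", "Y", "Z"))
  expect_error(association_difference(ab, bad), "do not match")
})

test_that("preference swaps conserve structure and never increase the score", {
  set.seed(14)
  freqs <- setNames(0.75^(0:7), LETTERS[1:8])
  cfg <- simulation_config(freqs, n_occurrences = 1500, p = 0.8, seed = 14)
  clusters <- generate_null_clusters(cfg)
  # an arbitrary fixed target: a second, independent draw
  cfg2 <- simulation_config(freqs, n_occurrences = 1500, p = 0.8, seed = 99)
  target <- cluster_counts(generate_null_clusters(cfg2))

  expect_identical(apply_preference_swaps(clusters, target, 0), clusters)

  swapped <- apply_preference_swaps(clusters, target, 1e4)
  # per-species occurrence counts and the cluster-size multiset survive
  expect_equal(table(factor(unlist(swapped), levels = names(freqs))),
               table(factor(unlist(clusters), levels = names(freqs))))
  expect_equal(sort(lengths(swapped)), sort(lengths(clusters)))
  trace <- attr(swapped, "d_trace")
  expect_true(all(diff(trace) <= 1e-9))
  # and the swaps moved the simulated counts toward the target
  d0 <- association_difference(cluster_counts(clusters,
                                              names(freqs)), target)
  d1 <- association_difference(cluster_counts(swapped, names(freqs)), target)
  expect_lt(d1, d0)
  expect_equal(d1, trace[length(trace)], tolerance = 1e-8)
})

test_that("rank percentiles behave at the degenerate replicate count", {
  freqs <- setNames(rep(0.25, 4), c("A", "B", "C", "D"))
  cfg <- simulation_config(freqs, n_occurrences = 300, p = 0.8,
                           n_reps = 2, seed = 4)
  rp <- simulate_betweenness_ranks(cfg)
  expect_s3_class(rp, "rank_percentiles")
  expect_equal(attr(rp, "mode"), "abundance_only")
  # with two replicates the 5%/95% percentiles are the min and max
  expect_true(all(rp$p5 <= rp$mean_rank + 1e-12))
  expect_true(all(rp$mean_rank <= rp$p95 + 1e-12))
  expect_true(all(rp$p5 + rp$p95 == 2 * rp$mean_rank))
})

test_that("uniform frequencies give exchangeable mean ranks", {
  freqs <- setNames(rep(1 / 6, 6), LETTERS[1:6])
  cfg <- simulation_config(freqs, n_occurrences = 400, p = 0.8,
                           n_reps = 60, seed = 21)
  rp <- simulate_betweenness_ranks(cfg)
  # every species' mean rank is near the exchangeable value (S+1)/2 = 3.5
  expect_true(all(abs(rp$mean_rank - 3.5) < 0.8))
  expect_true(all(rp$p5 <= rp$mean_rank & rp$mean_rank <= rp$p95))
})

test_that("simulation output is reproducible from the config seed", {
  freqs <- setNames(c(0.4, 0.3, 0.2, 0.1), LETTERS[1:4])
  cfg <- simulation_config(freqs, n_occurrences = 300, p = 0.8,
                           n_reps = 5, seed = 31)
  expect_identical(simulate_betweenness_ranks(cfg),
                   simulate_betweenness_ranks(cfg))
})
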