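test_that("co-occurrence counts, ASSS and node strength agree with direct counting", {
  rec <- records_from_sets(list(c("A", "B"), c("A", "B"), c("A", "C"), "B"))
  w <- co_occurrence_counts(build_occurrence_matrix(rec))
  expect_equal(w["A", "B"], 2L)
  expect_equal(w["A", "C"], 1L)
  expect_equal(w["B", "C"], 0L)
  expect_equal(unclass(w), t(unclass(w)), ignore_attr = TRUE)

  expect_equal(asss(w), 5)  # 4 + 1 + 0
  expect_equal(node_strength(w, "A"), 3)
  expect_equal(node_strength(w, "B"), 2)
  expect_equal(node_strength(w, "C"), 1)
  expect_error(node_strength(w, "Z"), "unknown species")

  # handshake identity and homogeneity under doubled data
  expect_equal(sum(node_strength(w)), 2 * sum(unclass(w)[upper.tri(w)]))
  rec2 <- records_from_sets(rep(list(c("A", "B"), c("A", "B"), c("A", "C"),
                                     "B"), 2))
  w2 <- co_occurrence_counts(build_occurrence_matrix(rec2))
  expect_equal(asss(w2), 4 * asss(w))

  # all-singleton and one-big-cluster extremes
  singles <- co_occurrence_counts(
    build_occurrence_matrix(records_from_sets(list("A", "B", "C"))))
  expect_true(all(unclass(singles) == 0))
  big <- co_occurrence_counts(
    build_occurrence_matrix(records_from_sets(list(c("A", "B", "C", "D")))))
  expect_true(all(unclass(big)[upper.tri(big)] == 1))
})

test_that("association statistics are invariant under row and column permutations", {
  set.seed(8)
  truth <- ground_truth(seed = 8)
  mat <- build_occurrence_matrix(generate_community(truth, 120))
  m <- unclass(mat); attr(m, "habitat") <- NULL
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  to_counts <- function(x) {
    w <- crossprod(x); diag(w) <- 0L; storage.mode(w) <- "integer"
    class(w) <- c("co_occurrence_counts", class(w)); w
  }
  expect_equal(asss(to_counts(perm)), asss(to_counts(m)))
  s1 <- sort(node_strength(to_counts(m)))
  s2 <- sort(node_strength(to_counts(perm)))
  expect_equal(unname(s1), unname(s2))
})

test_that("dyad null distribution respects its combinatorial support", {
  mat <- fixture_5x4()
  k <- colSums(unclass(mat))
  n <- nrow(mat)
  lo <- max(0, k["A"] + k["B"] - n)
  hi <- min(k["A"], k["B"])
  set.seed(31)
  for (i in 1:200) {
    s <- randomize_occurrences(mat, 60)
    w <- sum(s[, "A"] * s[, "B"])
    expect_gte(w, lo)
    expect_lte(w, hi)
  }
})

test_that("forced co-occurrence is detected by the global and dyad tests", {
  # two species always together, against a backdrop of singletons
  sets <- c(rep(list(c("A", "B")), 12),
            rep(list("C"), 10), rep(list("D"), 10),
            rep(list(c("C", "D")), 2))
  mat <- build_occurrence_matrix(records_from_sets(sets))
  g <- test_global_association(mat, m = 400, seed = 17)
  expect_lte(g$p_upper, 0.01)
  d <- test_dyad(mat, c("A", "B"), m = 400, seed = 18)
  expect_lte(d$p_upper, 0.01)
  expect_error(test_dyad(mat, c("A", "Z"), m = 10, seed = 1), "not in matrix")
})

test_that("degenerate margins give p = 1 on both tails", {
  # all-singleton clusters: ASSS and all strengths are 0 on every state
  mat <- build_occurrence_matrix(records_from_sets(list("A", "B", "A", "B")))
  g <- test_global_association(mat, m = 60, seed = 3)
  expect_equal(g$observed_stat, 0)
  expect_equal(g$p_upper, 1)
  expect_equal(g$p_lower, 1)
  s <- test_node_strength(mat, "A", m = 60, seed = 4)
  expect_equal(s$observed_stat, 0)
  expect_equal(s$p_upper, 1)
  expect_equal(s$p_lower, 1)
})

test_that("a planted solitary species shows small lower-tail node strength", {
  set.seed(55)
  truth <- ground_truth(planted_solitaries = "Bu", solitary_strength = 8,
                        seed = 55)
  mat <- build_occurrence_matrix(generate_community(truth, 1500))
  s <- test_node_strength(mat, "Bu", m = 400, seed = 56)
  expect_lte(s$p_lower, 0.05)
  expect_error(test_node_strength(mat, "Zz", m = 10), "unknown species")
})

test_that("stratification is vacuous when all clusters share one habitat", {
  sets <- c(rep(list(c("A", "B")), 6), rep(list("C"), 6), list(c("A", "C")))
  mat <- build_occurrence_matrix(records_from_sets(sets, habitat = "woodland"))
  r1 <- test_global_association(mat, m = 150, seed = 77)
  r2 <- test_global_association(mat, m = 150, seed = 77,
                                stratify_by_habitat = TRUE)
  expect_equal(r1$p_upper, r2$p_upper)
  expect_equal(r1$p_lower, r2$p_lower)
})

test_that("association_table tidies reports and can BH-adjust", {
  mat <- fixture_5x4()
  reports <- list(test_dyad(mat, c("A", "B"), m = 50, seed = 1),
                  test_dyad(mat, c("A", "C"), m = 50, seed = 2),
                  test_node_strength(mat, "A", m = 50, seed = 3))
  tab <- association_table(reports)
  expect_equal(nrow(tab), 3)
  expect_false("p_upper_adj" %in% names(tab))
  tab2 <- association_table(reports, adjust = "BH")
  expect_true(all(tab2$p_upper_adj >= tab2$p_upper - 1e-12))
})
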