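test_that("read_clusters merges rows by cluster id and validates input", {
  catalog <- make_catalog(c("A", "B", "C"), c(300, 250, 100))
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "cluster_id,ecosystem,season,habitat,species,group_size",
    "c1,TME,wet,grassland,A,5",
    "c1,TME,wet,grassland,B,2",
    "c2,TME,wet,woodland,A,3",
    "c3,SNE,dry,riverine,C,1",
    "c4,SNE,dry,shrubland,B,4",
    "c4,SNE,dry,shrubland,C,2"), csv)
  rec <- read_clusters(csv, catalog)
  expect_s3_class(rec, "cluster_records")
  expect_equal(nrow(rec), 6)
  expect_equal(length(unique(rec$cluster_id)), 4)

  # header-only file gives an empty record set
  empty <- tempfile(fileext = ".csv")
  writeLines("cluster_id,ecosystem,season,habitat,species,group_size", empty)
  expect_equal(nrow(read_clusters(empty, catalog)), 0)

  # unknown species is a named validation error
  bad <- tempfile(fileext = ".csv")
  writeLines(c("cluster_id,ecosystem,season,habitat,species,group_size",
               "c1,TME,wet,grassland,Xx,1"), bad)
  expect_error(read_clusters(bad, catalog), "Xx")

  # duplicate (cluster, species) pair cites the offending row
  dup <- tempfile(fileext = ".csv")
  writeLines(c("cluster_id,ecosystem,season,habitat,species,group_size",
               "c1,TME,wet,grassland,A,1",
               "c1,TME,wet,grassland,A,2"), dup)
  expect_error(read_clusters(dup, catalog), "duplicate")

  # bad enum values and non-integer group sizes rejected
  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("cluster_id,ecosystem,season,habitat,species,group_size",
               "c1,TME,wet,swamp,A,1"), bad2)
  expect_error(read_clusters(bad2, catalog), "habitat")
})

test_that("cluster records round-trip through CSV field-for-field", {
  rec <- records_from_sets(list(c("A", "B"), "A", c("B", "C")),
                           sizes = list(c(A = 5L, B = 2L), c(A = 3L),
                                        c(B = 1L, C = 7L)),
                           habitat = c("grassland", "woodland", "riverine"))
  path <- tempfile(fileext = ".csv")
  write_clusters(rec, path)
  back <- read_clusters(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("occurrence matrix has the documented margins", {
  rec <- records_from_sets(list(c("A", "B"), c("A", "B"), c("A", "C"), "B"))
  mat <- build_occurrence_matrix(rec)
  expect_equal(dim(mat), c(4, 3))
  expect_equal(colSums(unclass(mat))[c("A", "B", "C")],
               c(A = 3, B = 3, C = 1))
  # row sums = species per cluster; total = number of occurrence rows
  expect_equal(unname(rowSums(unclass(mat))), c(2, 2, 2, 1))
  expect_equal(sum(mat), nrow(rec))

  single <- build_occurrence_matrix(records_from_sets(list("A")))
  expect_equal(dim(single), c(1, 1))
  expect_equal(unname(unclass(single)[1, 1]), 1L)

  # subsetting drops clusters left with no retained species
  sub <- build_occurrence_matrix(rec, species_subset = "C")
  expect_equal(dim(sub), c(1, 1))
  expect_true(all(rowSums(unclass(sub)) > 0))

  expect_error(build_occurrence_matrix(rec[0, ]), "zero records")
})

test_that("occurrence matrix carries habitat labels for stratification", {
  rec <- records_from_sets(list(c("A", "B"), "A", "B"),
                           habitat = c("grassland", "woodland", "grassland"))
  mat <- build_occurrence_matrix(rec)
  expect_equal(unname(attr(mat, "habitat")),
               c("grassland", "woodland", "grassland"))
})

test_that("detectability filter reproduces the high-detectability set and is monotone", {
  catalog <- species_catalog()
  expect_equal(filter_by_detectability(catalog, 230),
               c("Hi", "Gi", "Bu", "El", "Wb", "Ha", "To", "GG", "TG", "Ze"))
  expect_length(filter_by_detectability(catalog, 500), 0)
  expect_length(filter_by_detectability(catalog, 1e-6), 26)
  # monotone: raising the threshold never adds a species
  thresholds <- sort(c(catalog$esw_m, 1, 100, 230, 231, 500))
  sets <- lapply(thresholds, filter_by_detectability, catalog = catalog)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("sighting series reads group sizes, contexts and partners", {
  rec <- records_from_sets(list(c("A", "B"), "A"),
                           sizes = list(c(A = 5L, B = 2L), c(A = 3L)))
  s <- sighting_series(rec, "A")
  expect_equal(s$k, 2)
  expect_equal(s$occurrences$group_size, c(5L, 3L))
  expect_equal(s$occurrences$is_mixed, c(TRUE, FALSE))
  expect_equal(s$partners[[1]], "B")
  expect_equal(s$partners[[2]], character(0))

  b <- sighting_series(rec, "B")
  expect_true(all(b$occurrences$is_mixed))
  solo <- sighting_series(records_from_sets(list("C", "C")), "C")
  expect_false(any(solo$occurrences$is_mixed))

  expect_error(sighting_series(rec, "Z"), "never observed")
})

test_that("stratum accounting matches the shipped study metadata", {
  counts <- study_cluster_counts()
  expect_equal(sum(counts$n_clusters), 5403)
  rec <- records_from_sets(list("A", c("A", "B"), "B"),
                           ecosystem = "TME", season = "wet")
  tab <- stratum_cluster_counts(rec)
  expect_equal(tab$n_clusters, 3)
  expect_equal(tab$ecosystem, "TME")
})
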