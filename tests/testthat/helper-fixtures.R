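# Shared fixture builders and independent oracles.

# Build cluster records from a list of species sets, e.g.
# records_from_sets(list(c("A","B"), "A")). Group sizes default to 1 and can
# be supplied as a parallel list of named vectors.
records_from_sets <- function(sets, sizes = NULL, habitat = "grassland",
                              ecosystem = "TME", season = "wet",
                              ids = sprintf("c%03d", seq_along(sets))) {
  habitat <- rep_len(habitat, length(sets))
  rows <- do.call(rbind, lapply(seq_along(sets), function(i) {
    sp <- sets[[i]]
    gs <- if (is.null(sizes)) rep(1L, length(sp)) else unname(sizes[[i]][sp])
    data.frame(cluster_id = ids[i], ecosystem = ecosystem, season = season,
               habitat = habitat[i], species = sp, group_size = gs,
               stringsAsFactors = FALSE)
  }))
  as_cluster_records(rows)
}

# Write a temporary catalog CSV and read it back as a species_catalog.
make_catalog <- function(ids, esw, guild = "grazer") {
  df <- data.frame(species_id = ids, common_name = ids, scientific_name = ids,
                   guild = rep_len(guild, length(ids)), esw_m = esw,
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  read_catalog(path)
}

# Exhaustively enumerate all binary matrices with the given row and column
# sums (independent oracle for the fixed-margin null distribution).
enumerate_margin_matrices <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  stopifnot(sum(row_sums) == sum(col_sums))
  out <- list()
  recurse <- function(i, remaining_cols, rows_so_far) {
    if (i > nr) {
      if (all(remaining_cols == 0)) {
        out[[length(out) + 1]] <<- do.call(rbind, rows_so_far)
      }
      return(invisible())
    }
    k <- row_sums[i]
    eligible <- which(remaining_cols > 0)
    if (length(eligible) < k) return(invisible())
    choices <- if (k == 0) list(integer(0)) else
      asplit(combn(eligible, k), 2)
    for (cols in choices) {
      row <- integer(nc); row[cols] <- 1L
      rc <- remaining_cols; rc[cols] <- rc[cols] - 1L
      # prune: remaining rows must be able to absorb remaining columns
      if (sum(rc) == sum(row_sums[-seq_len(i)]) &&
          all(rc <= nr - i)) {
        recurse(i + 1, rc, c(rows_so_far, list(row)))
      }
    }
    invisible()
  }
  recurse(1, col_sums, list())
  out
}

# Independent unweighted betweenness oracle by exhaustive simple-path
# enumeration on a small adjacency matrix (feasible up to ~7 nodes).
betweenness_by_enumeration <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(s, t) {
    paths <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (v in which(adj[last, ] > 0)) {
        if (!v %in% path) grow(c(path, v))
      }
      invisible()
    }
    grow(s)
    paths
  }
  score <- numeric(n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, 1L)
      shortest <- paths[lens == min(lens)]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        score[v] <- score[v] + through / length(shortest)
      }
    }
  }
  score
}

# A 5x4 binary matrix with row sums (2,2,1,1,1) and column sums (3,2,1,1);
# the pair (species 1, species 2) co-occurs in exactly one cluster.
fixture_5x4 <- function() {
  m <- matrix(0L, 5, 4, dimnames = list(paste0("c", 1:5), c("A", "B", "C", "D")))
  m[1, c(1, 2)] <- 1L
  m[2, c(1, 3)] <- 1L
  m[3, 1] <- 1L
  m[4, 2] <- 1L
  m[5, 4] <- 1L
  attr(m, "habitat") <- setNames(rep("grassland", 5), rownames(m))
  class(m) <- c("occurrence_matrix", class(m))
  m
}

# Exact upper-tail probability of a pair's co-occurrence count under the
# uniform fixed-margin null, by enumeration.
exact_dyad_tail <- function(row_sums, col_sums, i, j, observed) {
  mats <- enumerate_margin_matrices(row_sums, col_sums)
  w <- vapply(mats, function(m) sum(m[, i] * m[, j]), numeric(1))
  mean(w >= observed)
}
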