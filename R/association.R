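#' Pairwise co-occurrence counts
#'
#' `w[i, j]` is the number of clusters (matrix rows) containing both species
#' i and j. The matrix is symmetric with an unused zero diagonal; it is the
#' basis of the association statistics and the edge weights of the species
#' network.
#'
#' @param matrix An `occurrence_matrix`.
#' @return An integer matrix of class `co_occurrence_counts`.
#' @export
co_occurrence_counts <- function(matrix) {
  mat <- as_binary_matrix(matrix)
  w <- crossprod(mat)
  diag(w) <- 0L
  storage.mode(w) <- "integer"
  class(w) <- c("co_occurrence_counts", class(w))
  w
}

#' Global association score (sum of squared co-occurrences)
#'
#' The sum over unordered species pairs of the squared co-occurrence counts,
#' `sum_{i<j} w_ij^2`. Large values indicate a general tendency of species to
#' co-occur with specific other species; under the fixed-margin null its
#' distribution is obtained by randomization.
#'
#' @param counts A `co_occurrence_counts` matrix.
#' @return A single non-negative number.
#' @export
asss <- function(counts) {
  stopifnot(inherits(counts, "co_occurrence_counts"))
  w <- unclass(counts)
  sum(as.numeric(w[upper.tri(w)])^2)
}

#' Node strength
#'
#' The total co-occurrence weight incident to a species,
#' `s_i = sum_{j != i} w_ij`: a measure of heterospecific gregariousness. A
#' species that avoids mixed groups has small strength relative to the
#' fixed-margin null; a gregarious one has large strength.
#'
#' @param counts A `co_occurrence_counts` matrix.
#' @param species Optional single species id; if omitted, strengths for all
#'   species are returned as a named vector.
#' @return A named numeric vector (or a single number when `species` is
#'   given).
#' @export
node_strength <- function(counts, species = NULL) {
  stopifnot(inherits(counts, "co_occurrence_counts"))
  w <- unclass(counts)
  s <- rowSums(w)
  if (is.null(species)) return(s)
  if (!species %in% rownames(w)) {
    stop("unknown species: ", species, call. = FALSE)
  }
  unname(s[species])
}

assoc_report <- function(test, label, bc) {
  structure(list(test = test, label = label,
                 observed_stat = bc$observed_stat,
                 p_upper = bc$p_upper, p_lower = bc$p_lower,
                 m = bc$m, thin = bc$thin, seed = bc$seed, bc = bc),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("%s test (%s): stat = %g, p_upper = %.4g, p_lower = %.4g (m = %d)\n",
              x$test, x$label, x$observed_stat, x$p_upper, x$p_lower, x$m))
  invisible(x)
}

#' Randomization test for global species association
#'
#' Besag-Clifford test with the sum of squared pairwise co-occurrence counts
#' as test statistic, against the null that all occurrence matrices with the
#' observed margins (per-species sighting counts; cluster count and sizes)
#' are equally likely. The upper tail is the reported direction: large values
#' mean non-random association somewhere in the community.
#'
#' @param matrix An `occurrence_matrix`.
#' @param m,thin,seed,stratify_by_habitat Passed to [bc_pvalue()].
#' @return An `association_report`.
#' @export
test_global_association <- function(matrix, m = 1000, thin = NULL,
                                    seed = NULL, stratify_by_habitat = FALSE) {
  bc <- bc_pvalue(matrix, function(x) asss(co_occurrence_counts(x)),
                  m = m, thin = thin, seed = seed,
                  stratify_by_habitat = stratify_by_habitat)
  assoc_report("global_association", "ASSS", bc)
}

#' Randomization test for a specific species dyad
#'
#' Besag-Clifford test with the co-occurrence count of one named species pair
#' as test statistic. A small upper-tail p-value means the pair co-occurs
#' more often than expected given every species' sighting frequency and the
#' cluster size distribution; raw counts are a valid statistic precisely
#' because the randomization conditions on those margins.
#'
#' @param matrix An `occurrence_matrix`.
#' @param pair Character vector of two species ids present in the matrix.
#' @param m,thin,seed,stratify_by_habitat Passed to [bc_pvalue()].
#' @return An `association_report`.
#' @export
test_dyad <- function(matrix, pair, m = 1000, thin = NULL, seed = NULL,
                      stratify_by_habitat = FALSE) {
  stopifnot(length(pair) == 2)
  missing <- setdiff(pair, colnames(matrix))
  if (length(missing) > 0) {
    stop("pair not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  i <- pair[1]; j <- pair[2]
  bc <- bc_pvalue(matrix, function(x) sum(x[, i] * x[, j]),
                  m = m, thin = thin, seed = seed,
                  stratify_by_habitat = stratify_by_habitat)
  assoc_report("dyad", paste(pair, collapse = "-"), bc)
}

#' Randomization test for a species' node strength
#'
#' Besag-Clifford test with the node strength of one species as test
#' statistic. Both tails are reported: the lower tail detects species that
#' occur in mixed groups less than expected (avoidance), the upper tail
#' species that are more heterospecifically gregarious than expected.
#'
#' @param matrix An `occurrence_matrix`.
#' @param species A single species id present in the matrix.
#' @param m,thin,seed,stratify_by_habitat Passed to [bc_pvalue()].
#' @return An `association_report`.
#' @export
test_node_strength <- function(matrix, species, m = 1000, thin = NULL,
                               seed = NULL, stratify_by_habitat = FALSE) {
  if (!species %in% colnames(matrix)) {
    stop("unknown species: ", species, call. = FALSE)
  }
  bc <- bc_pvalue(matrix,
                  function(x) sum(x[, species] * (rowSums(x) - x[, species])),
                  m = m, thin = thin, seed = seed,
                  stratify_by_habitat = stratify_by_habitat)
  assoc_report("node_strength", species, bc)
}

#' Tidy a set of association reports
#'
#' Collects association reports into one data frame, optionally adding
#' Benjamini-Hochberg adjusted p-values (off by default; the analyses this
#' package mirrors report raw per-test p-values).
#'
#' @param reports A list of `association_report`s (a single report is
#'   accepted).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `data.frame` with one row per test: `test`, `label`,
#'   `observed_stat`, `p_lower`, `p_upper`, `m`, `seed`, and (with
#'   `adjust = "BH"`) `p_upper_adj` and `p_lower_adj`.
#' @export
association_table <- function(reports, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(reports, "association_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(test = r$test, label = r$label,
               observed_stat = r$observed_stat,
               p_lower = r$p_lower, p_upper = r$p_upper,
               m = r$m, seed = if (is.null(r$seed)) NA_integer_ else r$seed,
               stringsAsFactors = FALSE)
  }))
  if (adjust == "BH") {
    df$p_upper_adj <- stats::p.adjust(df$p_upper, method = "BH")
    df$p_lower_adj <- stats::p.adjust(df$p_lower, method = "BH")
  }
  rownames(df) <- NULL
  df
}
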