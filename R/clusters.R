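#' Cluster records: the long-format sighting table
#'
#' A cluster is an independent sighting of one or more species whose
#' individuals were within 50 m of one another (a data-collection convention;
#' the package never re-derives membership from coordinates). Records are kept
#' in long format: one row per species occurrence within a cluster, with the
#' cluster-level fields (ecosystem, season, habitat) repeated on every row.
#'
#' @param df A `data.frame` with columns
#'   `cluster_id, ecosystem, season, habitat, species, group_size`.
#' @param catalog Optional `species_catalog`; if supplied, every species must
#'   be a catalog entry.
#' @return The validated `data.frame` with class `cluster_records`.
#' @export
as_cluster_records <- function(df, catalog = NULL) {
  required <- c("cluster_id", "ecosystem", "season", "habitat",
                "species", "group_size")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cluster table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$cluster_id <- as.character(df$cluster_id)
  df$species <- as.character(df$species)

  check_enum <- function(values, allowed, what) {
    bad <- setdiff(unique(values), allowed)
    if (length(bad) > 0) {
      stop("unknown ", what, ": ", paste(bad, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
    }
  }
  check_enum(df$ecosystem, MIXNET_ECOSYSTEMS, "ecosystem")
  check_enum(df$season, MIXNET_SEASONS, "season")
  check_enum(df$habitat, MIXNET_HABITATS, "habitat")

  if (nrow(df) > 0 &&
      (!is.numeric(df$group_size) || any(!is.finite(df$group_size)) ||
       any(df$group_size < 1) || any(df$group_size != round(df$group_size)))) {
    stop("group_size must be a positive integer on every row", call. = FALSE)
  }
  df$group_size <- as.integer(df$group_size)

  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "species_catalog"))
    unknown <- setdiff(unique(df$species), catalog$species_id)
    if (length(unknown) > 0) {
      stop("species not in catalog: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }

  dup <- duplicated(df[c("cluster_id", "species")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate (cluster_id, species) pair at row ", i, ": cluster ",
         df$cluster_id[i], ", species ", df$species[i], call. = FALSE)
  }

  # cluster-level fields must be constant within a cluster
  for (field in c("ecosystem", "season", "habitat")) {
    n_levels <- tapply(df[[field]], df$cluster_id,
                       function(x) length(unique(x)))
    if (any(n_levels > 1)) {
      stop("cluster(s) with inconsistent ", field, ": ",
           paste(names(n_levels)[n_levels > 1], collapse = ", "),
           call. = FALSE)
    }
  }

  class(df) <- c("cluster_records", "data.frame")
  df
}

#' Read cluster records from CSV
#'
#' Reads a long-format sighting table (one row per species occurrence within a
#' cluster) and validates it: enum fields must take known values, group sizes
#' must be positive integers, a species may occur at most once per cluster,
#' and (if a catalog is supplied) every species must be catalogued. Rows
#' sharing a `cluster_id` describe one cluster.
#'
#' @param path Path to a CSV file with header
#'   `cluster_id,ecosystem,season,habitat,species,group_size`.
#' @param catalog Optional `species_catalog` used to validate species ids.
#' @return A `cluster_records` data frame.
#' @export
read_clusters <- function(path, catalog = NULL) {
  if (!file.exists(path)) {
    stop("clusters file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(cluster_id = "character", species = "character"))
  as_cluster_records(df, catalog = catalog)
}

#' Write cluster records to CSV
#'
#' Inverse of [read_clusters()]: writes the long-format table so that reading
#' it back reproduces the records field-for-field.
#'
#' @param records A `cluster_records` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(records, path) {
  stopifnot(inherits(records, "cluster_records"))
  write.csv(as.data.frame(records), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Number of clusters per ecosystem-by-season stratum
#'
#' Counts distinct clusters in each ecosystem/season stratum of a record set;
#' the basis of the stratum-accounting consistency check against the study's
#' printed per-stratum totals.
#'
#' @param records A `cluster_records` data frame.
#' @return A `data.frame` with columns `ecosystem`, `season`, `n_clusters`.
#' @export
stratum_cluster_counts <- function(records) {
  stopifnot(inherits(records, "cluster_records"))
  one <- records[!duplicated(records$cluster_id), ]
  agg <- aggregate(list(n_clusters = one$cluster_id),
                   by = list(ecosystem = one$ecosystem, season = one$season),
                   FUN = length)
  agg[order(match(agg$ecosystem, MIXNET_ECOSYSTEMS),
            match(agg$season, MIXNET_SEASONS)), , drop = FALSE]
}

#' Build a binary occurrence matrix from cluster records
#'
#' Rows are clusters, columns are species; a 1 in row i, column j means
#' species j was present in cluster i. Row sums are cluster sizes (numbers of
#' distinct species); column sums are per-species sighting counts. The
#' habitat of each cluster travels with the matrix so randomizations can be
#' stratified by habitat.
#'
#' @param records A `cluster_records` data frame.
#' @param species_subset Optional character vector of species to retain
#'   (e.g. the high-detectability set); clusters containing none of the
#'   retained species are dropped, so the matrix has no all-zero rows.
#' @return An integer matrix of class `occurrence_matrix` with cluster ids as
#'   row names, species ids as column names, and a `habitat` attribute (named
#'   character vector, one entry per row).
#' @export
build_occurrence_matrix <- function(records, species_subset = NULL) {
  stopifnot(inherits(records, "cluster_records"))
  if (nrow(records) == 0) {
    stop("cannot build an occurrence matrix from zero records", call. = FALSE)
  }
  df <- as.data.frame(records)
  if (!is.null(species_subset)) {
    unknown <- setdiff(species_subset, unique(df$species))
    # a subset id absent from the data is allowed: its column would be empty,
    # which build semantics below handle by simply not creating it
    df <- df[df$species %in% species_subset, , drop = FALSE]
    if (nrow(df) == 0) {
      stop("no records remain after applying species_subset", call. = FALSE)
    }
    species <- species_subset[species_subset %in% unique(df$species)]
  } else {
    species <- unique(df$species)
  }
  clusters <- unique(df$cluster_id)
  mat <- matrix(0L, nrow = length(clusters), ncol = length(species),
                dimnames = list(clusters, species))
  mat[cbind(match(df$cluster_id, clusters), match(df$species, species))] <- 1L
  habitat <- df$habitat[!duplicated(df$cluster_id)]
  names(habitat) <- df$cluster_id[!duplicated(df$cluster_id)]
  attr(mat, "habitat") <- habitat[clusters]
  class(mat) <- c("occurrence_matrix", class(mat))
  mat
}

#' Export an occurrence matrix as CSV
#'
#' @param matrix An `occurrence_matrix`.
#' @param path Output CSV path; cluster ids are written as a `cluster_id`
#'   column.
#' @return `path`, invisibly.
#' @export
write_occurrence_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "occurrence_matrix"))
  df <- data.frame(cluster_id = rownames(matrix),
                   as.data.frame(unclass(matrix)[, , drop = FALSE]),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Per-species sighting series
#'
#' Extracts, for one species, the ordered list of its occurrences: the
#' cluster, the conspecific group size, whether the cluster was mixed
#' (two or more species), and the set of partner species.
#'
#' @param records A `cluster_records` data frame.
#' @param species_id A single species id occurring in the records.
#' @return A list of class `sighting_series` with elements `species_id`,
#'   `occurrences` (a `data.frame` with columns `cluster_id`, `group_size`,
#'   `is_mixed`), `partners` (a list of character vectors parallel to the
#'   occurrence rows), and `k` (the number of occurrences).
#' @export
sighting_series <- function(records, species_id) {
  stopifnot(inherits(records, "cluster_records"))
  stopifnot(is.character(species_id), length(species_id) == 1)
  df <- as.data.frame(records)
  rows <- df[df$species == species_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("species never observed: ", species_id, call. = FALSE)
  }
  members <- split(df$species, df$cluster_id)
  partners <- lapply(rows$cluster_id,
                     function(cid) setdiff(members[[cid]], species_id))
  occ <- data.frame(cluster_id = rows$cluster_id,
                    group_size = rows$group_size,
                    is_mixed = vapply(partners, length, 1L) > 0,
                    stringsAsFactors = FALSE)
  structure(list(species_id = species_id, occurrences = occ,
                 partners = partners, k = nrow(occ)),
            class = "sighting_series")
}

#' @export
print.sighting_series <- function(x, ...) {
  cat("Sighting series for", x$species_id, "-", x$k, "occurrence(s),",
      sum(x$occurrences$is_mixed), "in mixed clusters\n")
  invisible(x)
}

#' @importFrom stats aggregate
NULL
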