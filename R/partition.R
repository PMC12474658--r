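#' Entity partition of record identifiers
#'
#' A partition assigns every record identifier to exactly one cluster (entity).
#' Cluster labels are arbitrary: two partitions are compared by their set
#' structure, never by label values. Internally a partition is a data frame
#' with character columns \code{record_id} and \code{cluster_id}, sorted by
#' \code{record_id}.
#'
#' @param record_id character vector of unique record identifiers.
#' @param cluster_id vector (coerced to character) of cluster labels, one per
#'   record.
#' @return An object of class \code{partition}.
#' @examples
#' p <- partition(c("a", "b", "c"), c(1, 1, 2))
#' cluster_sizes(p)
#' linked_records(p)
#' @export
partition <- function(record_id, cluster_id) {
  record_id <- as.character(record_id)
  cluster_id <- as.character(cluster_id)
  if (length(record_id) != length(cluster_id)) {
    stop("record_id and cluster_id must have equal length")
  }
  if (anyDuplicated(record_id)) {
    dup <- unique(record_id[duplicated(record_id)])
    stop("duplicate record_id in partition: ", paste(head(dup, 5), collapse = ", "))
  }
  ord <- order(record_id)
  out <- data.frame(
    record_id = record_id[ord],
    cluster_id = cluster_id[ord],
    stringsAsFactors = FALSE
  )
  class(out) <- c("partition", "data.frame")
  out
}

#' @export
print.partition <- function(x, ...) {
  sz <- cluster_sizes(x)
  cat(sprintf(
    "<partition> %d records, %d clusters (%d multi-record)\n",
    nrow(x), length(sz), sum(sz >= 2)
  ))
  invisible(x)
}

#' Cluster sizes of a partition
#'
#' @param p a \code{\link{partition}}.
#' @return Named integer vector: size of each cluster, named by cluster label.
#' @export
cluster_sizes <- function(p) {
  stopifnot(inherits(p, "partition"))
  tab <- table(p$cluster_id)
  setNames(as.integer(tab), names(tab))
}

#' Records belonging to multi-record clusters
#'
#' The "linked" records of a partition: members of clusters of size >= 2.
#' These are the positives of the record-level evaluation.
#'
#' @param p a \code{\link{partition}}.
#' @return Character vector of record identifiers, sorted.
#' @export
linked_records <- function(p) {
  stopifnot(inherits(p, "partition"))
  sz <- table(p$cluster_id)
  multi <- names(sz)[sz >= 2]
  sort(p$record_id[p$cluster_id %in% multi])
}

#' Build a partition from undirected links
#'
#' Closes a set of pairwise links transitively (connected components) over a
#' record universe; records incident to no link become singletons. Cluster
#' labels are the lexicographically smallest member id, so the result is
#' invariant to input order.
#'
#' @param record_ids character vector: the full record universe.
#' @param pairs data frame with character columns \code{id1}, \code{id2}
#'   (may have zero rows).
#' @return A \code{\link{partition}}.
#' @export
partition_from_links <- function(record_ids, pairs) {
  record_ids <- as.character(record_ids)
  if (anyDuplicated(record_ids)) stop("record_ids must be unique")
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(partition(record_ids, record_ids))
  }
  stopifnot(all(c("id1", "id2") %in% names(pairs)))
  edges <- cbind(as.character(pairs$id1), as.character(pairs$id2))
  if (!all(edges %in% record_ids)) {
    stop("pairs refer to record ids outside the record universe")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = record_ids, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(g)$membership
  # relabel components by their smallest member id for determinism
  ids <- names(comp)
  lab <- tapply(ids, comp, min)
  partition(ids, unname(lab[as.character(comp)]))
}

#' Test whether two partitions have the same set structure
#'
#' Labels are ignored; only co-membership matters.
#'
#' @param a,b partitions over the same record universe.
#' @return Logical scalar.
#' @export
same_partition <- function(a, b) {
  stopifnot(inherits(a, "partition"), inherits(b, "partition"))
  if (nrow(a) != nrow(b) || !identical(a$record_id, b$record_id)) {
    return(FALSE)
  }
  # canonical form: cluster label = smallest member id
  canon <- function(p) {
    lab <- tapply(p$record_id, p$cluster_id, min)
    unname(lab[p$cluster_id])
  }
  identical(canon(a), canon(b))
}

#' All unordered within-cluster pairs of a partition
#'
#' @param p a \code{\link{partition}}.
#' @return Data frame with columns \code{id1}, \code{id2}, \code{id1 < id2},
#'   sorted.
#' @export
partition_pairs <- function(p) {
  stopifnot(inherits(p, "partition"))
  sz <- table(p$cluster_id)
  multi <- names(sz)[sz >= 2]
  out <- list()
  for (cl in multi) {
    m <- sort(p$record_id[p$cluster_id == cl])
    cmb <- utils::combn(m, 2)
    out[[cl]] <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ], stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(id1 = character(), id2 = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$id1, res$id2), , drop = FALSE]
}
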