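#' Group records into exact-key blocks
#'
#' Restricts pairwise comparison to records sharing the exact values of the
#' blocking key (default: date of birth, sex, village). Records missing any
#' key field join no block; their count is reported in
#' \code{attr(x, "unblocked")}.
#'
#' @param records normalized records.
#' @param keys character vector of blocking field names.
#' @return List of blocks (character vectors of record ids, each of size >= 1),
#'   named by the composite key, with attribute \code{unblocked}.
#' @export
block_records <- function(records, keys = c("dob", "sex", "village")) {
  df <- as.data.frame(records)
  stopifnot(length(keys) >= 1, all(keys %in% names(df)))
  keyvals <- lapply(keys, function(k) as.character(df[[k]]))
  has_all <- Reduce(`&`, lapply(keyvals, function(v) !is.na(v)))
  key <- do.call(paste, c(keyvals, sep = "\r"))
  ids <- df$record_id[has_all]
  blocks <- split(ids, key[has_all])
  blocks <- lapply(blocks, sort)
  blocks <- blocks[order(names(blocks))]
  attr(blocks, "unblocked") <- sum(!has_all)
  blocks
}

# all unordered within-block pairs, id1 < id2, deduplicated and sorted
block_pairs <- function(blocks) {
  big <- blocks[vapply(blocks, length, 1L) >= 2]
  if (length(big) == 0) {
    return(data.frame(id1 = character(), id2 = character(), stringsAsFactors = FALSE))
  }
  parts <- lapply(big, function(m) {
    cmb <- utils::combn(m, 2)
    data.frame(id1 = cmb[1, ], id2 = cmb[2, ], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- unique(out)
  out[order(out$id1, out$id2), , drop = FALSE]
}

#' Records flagged for manual review
#'
#' The candidate set a human reviewer would see: all records in blocks of
#' size >= 2 under the review blocking key.
#'
#' @inheritParams block_records
#' @return Sorted character vector of record ids, with attribute
#'   \code{proportion}: its share of all records.
#' @export
candidate_review_set <- function(records, keys = c("dob", "sex", "village")) {
  blocks <- block_records(records, keys)
  flagged <- sort(unique(unlist(blocks[vapply(blocks, length, 1L) >= 2],
                                use.names = FALSE)))
  if (is.null(flagged)) flagged <- character()
  attr(flagged, "proportion") <- length(flagged) / nrow(as.data.frame(records))
  flagged
}
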