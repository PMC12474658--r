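#' Record-level confusion counts against a gold partition
#'
#' A record is positive in a partition iff it belongs to a cluster of
#' size >= 2. True positives are records positive in both the predicted and
#' gold partitions; false positives predicted-only; false negatives
#' gold-only; true negatives neither. Counts always sum to the size of the
#' record universe, and tp + fn equals the number of gold linked records.
#'
#' @param predicted,gold \code{\link{partition}}s over the same record ids.
#' @return List of class \code{confusion_counts} with fields \code{tn, fp,
#'   fn, tp}.
#' @export
record_confusion <- function(predicted, gold) {
  stopifnot(inherits(predicted, "partition"), inherits(gold, "partition"))
  if (!identical(predicted$record_id, gold$record_id)) {
    diff <- c(setdiff(predicted$record_id, gold$record_id),
              setdiff(gold$record_id, predicted$record_id))
    stop("partitions cover different record universes; symmetric difference: ",
         paste(head(sort(unique(diff)), 10), collapse = ", "))
  }
  pos_p <- predicted$record_id %in% linked_records(predicted)
  pos_g <- gold$record_id %in% linked_records(gold)
  out <- list(
    tn = sum(!pos_p & !pos_g), fp = sum(pos_p & !pos_g),
    fn = sum(!pos_p & pos_g), tp = sum(pos_p & pos_g)
  )
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> tn=%d fp=%d fn=%d tp=%d (n=%d)\n",
              x$tn, x$fp, x$fn, x$tp, x$tn + x$fp + x$fn + x$tp))
  invisible(x)
}

#' Precision, recall and F1 from confusion counts
#'
#' Zero denominators yield 0 with a warning rather than NaN.
#'
#' @param counts a \code{confusion_counts} list (or any list with tn, fp,
#'   fn, tp).
#' @return List of class \code{metric_set}: precision, recall, f1 in [0, 1].
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metrics> precision=%.4f recall=%.4f f1=%.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Round a proportion to a printed integer percentage
#'
#' Half-away-from-zero rounding, the convention used when quoting
#' percentages.
#'
#' @param x proportion in [0, 1].
#' @return Integer percent.
#' @export
percent_round <- function(x) {
  floor(x * 100 + 0.5)
}

#' Precision-recall curve over a score threshold sweep
#'
#' Given one score per record (e.g. the maximum posterior over its incident
#' links, or the deterministic field-agreement count), classifies a record as
#' positive when its score >= threshold, computes record-level confusion
#' against the gold partition at each threshold, and summarizes the curve by
#' the trapezoidal area under (recall, precision) with points sorted by
#' recall. Records with score \code{NA} are never positive.
#'
#' @param scores data frame (record_id, score).
#' @param gold gold \code{\link{partition}}.
#' @param thresholds numeric vector of thresholds to sweep (non-empty).
#' @return List of class \code{pr_curve}: \code{points} (threshold,
#'   precision, recall) and \code{auc}.
#' @export
pr_curve <- function(scores, gold, thresholds) {
  stopifnot(inherits(gold, "partition"),
            all(c("record_id", "score") %in% names(scores)))
  if (length(thresholds) == 0) stop("empty threshold sweep")
  sc <- setNames(scores$score, scores$record_id)[gold$record_id]
  pos_g <- gold$record_id %in% linked_records(gold)
  pts <- lapply(sort(thresholds), function(t) {
    pos_p <- !is.na(sc) & sc >= t
    tp <- sum(pos_p & pos_g); fp <- sum(pos_p & !pos_g); fn <- sum(!pos_p & pos_g)
    data.frame(
      threshold = t,
      precision = if (tp + fp == 0) 1 else tp / (tp + fp),
      recall = if (tp + fn == 0) 0 else tp / (tp + fn)
    )
  })
  pts <- do.call(rbind, pts)
  ord <- order(pts$recall, pts$precision)
  r <- pts$recall[ord]; p <- pts$precision[ord]
  auc <- if (length(r) < 2 || max(r) == min(r)) {
    # degenerate single-point curve: rectangle under the point
    max(r) * p[which.max(r)]
  } else {
    sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
  }
  structure(list(points = pts, auc = auc), class = "pr_curve")
}

#' Record scores from scored pairs
#'
#' Each record's score is the maximum posterior over the scored pairs it
#' appears in; records in no pair score \code{NA}.
#'
#' @param scored data frame (id1, id2, posterior).
#' @param record_ids full record universe.
#' @return Data frame (record_id, score).
#' @export
record_scores_from_pairs <- function(scored, record_ids) {
  score <- setNames(rep(NA_real_, length(record_ids)), record_ids)
  if (nrow(scored) > 0) {
    long <- data.frame(id = c(scored$id1, scored$id2),
                       post = rep(scored$posterior, 2))
    agg <- tapply(long$post, long$id, max)
    score[names(agg)] <- agg
  }
  data.frame(record_id = record_ids, score = unname(score),
             stringsAsFactors = FALSE)
}

#' Cluster-size distribution of a partition
#'
#' Multi-record clusters only, mirroring the way gold-standard match groups
#' are reported: per size, the number of clusters, its share of all
#' multi-record clusters, and the records covered.
#'
#' @param p a \code{\link{partition}}.
#' @return Data frame (size, clusters, pct, records); zero rows when the
#'   partition has no multi-record cluster.
#' @export
cluster_size_table <- function(p) {
  sz <- cluster_sizes(p)
  sz <- sz[sz >= 2]
  if (length(sz) == 0) {
    return(data.frame(size = integer(), clusters = integer(),
                      pct = numeric(), records = integer()))
  }
  tab <- table(sz)
  out <- data.frame(
    size = as.integer(names(tab)),
    clusters = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out$pct <- round(100 * out$clusters / sum(out$clusters), 1)
  out$records <- out$size * out$clusters
  out
}

#' Field completeness profile
#'
#' Percentage of non-missing values per matching variable.
#'
#' @param records raw or normalized records.
#' @return Data frame (field, pct_complete), 2-decimal percentages.
#' @export
completeness_profile <- function(records) {
  df <- as.data.frame(records)
  fields <- setdiff(RECORD_FIELDS, "record_id")
  data.frame(
    field = fields,
    pct_complete = vapply(fields, function(f) {
      round(100 * mean(!is.na(df[[f]])), 2)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Most and least frequent names
#'
#' Ranked frequency tables of the canonical name column; ties broken
#' lexicographically for determinism. Missing names are excluded and counted
#' separately.
#'
#' @param records normalized records.
#' @param top,bottom number of entries in each table.
#' @return List with \code{top} and \code{bottom} data frames (name, count)
#'   and \code{n_missing}.
#' @export
name_frequency <- function(records, top = 10, bottom = 5) {
  df <- as.data.frame(records)
  nm <- df$name[!is.na(df$name)]
  tab <- table(nm)
  freq <- data.frame(name = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  top_df <- freq[order(-freq$count, freq$name), , drop = FALSE]
  bot_df <- freq[order(freq$count, freq$name), , drop = FALSE]
  list(
    top = head(top_df, top),
    bottom = head(bot_df, bottom),
    n_missing = sum(is.na(df$name))
  )
}
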