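#' @keywords internal
#' Field states of the (name, father, mother) triple for a set of pairs
pair_states <- function(records, pairs, placeholder_as_missing = FALSE,
                        placeholders = DEFAULT_PLACEHOLDERS) {
  df <- as.data.frame(records)
  i <- match(pairs$id1, df$record_id)
  j <- match(pairs$id2, df$record_id)
  val <- function(f) {
    v <- df[[f]]
    if (placeholder_as_missing && f == "name") {
      v[placeholder_flag(v, placeholders)] <- NA_character_
    }
    v
  }
  nm <- val("name")
  data.frame(
    id1 = pairs$id1, id2 = pairs$id2,
    name_state = field_state(nm[i], nm[j]),
    father_state = field_state(df$father_name[i], df$father_name[j]),
    mother_state = field_state(df$mother_name[i], df$mother_name[j]),
    stringsAsFactors = FALSE
  )
}

#' Deterministic (rule-based) matching
#'
#' Blocks records on the exact blocking key, classifies every within-block
#' pair by the decision table over the (name, father's name, mother's name)
#' agreement states, and closes matched pairs transitively into clusters.
#' Unmatched records remain singletons.
#'
#' @param records normalized records (see \code{\link{normalize_records}}).
#' @param rules a \code{\link{rule_table}}.
#' @param keys blocking key fields (all must agree exactly).
#' @param strict_all_fields require exact agreement on name, father's and
#'   mother's name (all three \code{MATCH}) instead of the decision table.
#' @param placeholder_as_missing treat placeholder names as missing when
#'   computing the name state.
#' @return A \code{\link{partition}} with attribute \code{pairs}: the matched
#'   pairs (id1, id2).
#' @export
deterministic_match <- function(records, rules = rule_table(),
                                keys = c("dob", "sex", "village"),
                                strict_all_fields = FALSE,
                                placeholder_as_missing = FALSE) {
  df <- as.data.frame(records)
  blocks <- block_records(df, keys)
  pairs <- block_pairs(blocks)
  if (nrow(pairs) > 0) {
    st <- pair_states(df, pairs, placeholder_as_missing)
    dec <- if (strict_all_fields) {
      st$name_state == "MATCH" & st$father_state == "MATCH" &
        st$mother_state == "MATCH"
    } else {
      classify_triple(st$name_state, st$father_state, st$mother_state, rules)
    }
    pairs <- pairs[dec, , drop = FALSE]
  }
  p <- partition_from_links(df$record_id, pairs)
  attr(p, "pairs") <- pairs
  p
}

#' Deterministic agreement score per record
#'
#' A monotone score for sweeping a precision-recall curve over the
#' deterministic matcher: for each record, the maximum number of agreeing
#' fields among \{name, father's name, mother's name\} (0--3) over its
#' within-block pairs. Records in no block score \code{NA} (never positive).
#'
#' @inheritParams deterministic_match
#' @return Data frame (record_id, score).
#' @export
deterministic_scores <- function(records, keys = c("dob", "sex", "village"),
                                 placeholder_as_missing = FALSE) {
  df <- as.data.frame(records)
  pairs <- block_pairs(block_records(df, keys))
  score <- setNames(rep(NA_real_, nrow(df)), df$record_id)
  if (nrow(pairs) > 0) {
    st <- pair_states(df, pairs, placeholder_as_missing)
    agree <- (st$name_state == "MATCH") + (st$father_state == "MATCH") +
      (st$mother_state == "MATCH")
    for (k in seq_len(nrow(pairs))) {
      for (id in c(pairs$id1[k], pairs$id2[k])) {
        if (is.na(score[id]) || agree[k] > score[id]) score[id] <- agree[k]
      }
    }
  }
  data.frame(record_id = df$record_id, score = unname(score[df$record_id]),
             stringsAsFactors = FALSE)
}
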