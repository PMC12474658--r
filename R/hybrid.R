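#' Hybrid deterministic-then-probabilistic matching
#'
#' Runs the deterministic matcher first; records already matched
#' deterministically (members of a deterministic cluster of size >= 2) are
#' withheld from the probabilistic stage, which is run on the residual
#' records only. The final partition is the transitive closure of the union
#' of both link sets. Every probabilistic link is audited against the
#' deterministic rule table (\code{\link{audit_links}}); in the default mode
#' flagged links are kept but marked, in strict-audit mode they are removed
#' before closure.
#'
#' @param records normalized records.
#' @param config a \code{\link{pipeline_config}} (\code{strict_audit}
#'   selects the filtering audit mode).
#' @return A \code{\link{partition}} with attribute \code{trace}: data frame
#'   (id1, id2, provenance, audit) with one row per retained link, provenance
#'   in \{deterministic, probabilistic\} and audit in \{consistent, flagged\}
#'   (deterministic links are consistent by construction).
#' @export
hybrid_match <- function(records, config = pipeline_config()) {
  df <- as.data.frame(records)
  det <- deterministic_match(
    df, rules = rule_table(), keys = config$det_keys,
    strict_all_fields = config$strict_all_fields,
    placeholder_as_missing = config$placeholder_as_missing
  )
  det_pairs <- attr(det, "pairs")
  matched_ids <- linked_records(det)
  residual <- df[!df$record_id %in% matched_ids, , drop = FALSE]

  if (nrow(residual) >= 2) {
    # the prior match probability is a property of the whole registry; the
    # residual's own deterministic proxy is ~0 by construction, so estimate
    # lambda on the full record set and let EM refine it on residual pairs
    lambda_full <- tryCatch(
      estimate_lambda(df, rule_table(), keys = config$prob_keys,
                      recall = config$recall),
      error = function(e) 0.05
    )
    prob <- tryCatch(
      probabilistic_match(residual, config, lambda = as.numeric(lambda_full),
                          fix_lambda = FALSE),
      error = function(e) {
        # residual too homogeneous or unblockable: no probabilistic links
        NULL
      }
    )
    prob_pairs <- if (is.null(prob)) NULL else attr(prob, "pairs")
  } else {
    prob_pairs <- NULL
  }
  if (is.null(prob_pairs) || nrow(prob_pairs) == 0) {
    prob_pairs <- data.frame(id1 = character(), id2 = character(),
                             stringsAsFactors = FALSE)
  }

  trace <- rbind(
    if (nrow(det_pairs) > 0) {
      data.frame(id1 = det_pairs$id1, id2 = det_pairs$id2,
                 provenance = "deterministic", audit = "consistent",
                 stringsAsFactors = FALSE)
    },
    if (nrow(prob_pairs) > 0) {
      data.frame(id1 = prob_pairs$id1, id2 = prob_pairs$id2,
                 provenance = "probabilistic", audit = NA_character_,
                 stringsAsFactors = FALSE)
    }
  )
  if (is.null(trace)) {
    trace <- data.frame(id1 = character(), id2 = character(),
                        provenance = character(), audit = character(),
                        stringsAsFactors = FALSE)
  }
  trace <- audit_links(trace, df, rule_table())
  kept <- trace
  if (config$strict_audit) {
    kept <- trace[trace$audit == "consistent", , drop = FALSE]
  }
  p <- partition_from_links(df$record_id, kept)
  attr(p, "trace") <- if (config$strict_audit) kept else trace
  attr(p, "deterministic") <- det
  p
}

#' Audit probabilistic links against the deterministic rule table
#'
#' Re-evaluates each probabilistic link's (name, father's name, mother's
#' name) agreement states under the decision table. A link is flagged when
#' the deterministic evidence actively conflicts: the sexes differ outright,
#' or the table decides FALSE with at least one NONMATCH among the three
#' name fields. A FALSE arising purely from unavailable fields is not a
#' conflict. Flagged links are marked, never removed, by this function.
#'
#' @param trace link trace as produced inside \code{\link{hybrid_match}}:
#'   data frame with columns \code{id1, id2, provenance, audit}.
#' @param records normalized records.
#' @param rules a \code{\link{rule_table}}.
#' @return The trace with the \code{audit} column filled for probabilistic
#'   links (\code{"consistent"} or \code{"flagged"}).
#' @export
audit_links <- function(trace, records, rules = rule_table()) {
  stopifnot(all(c("id1", "id2", "provenance", "audit") %in% names(trace)))
  idx <- which(trace$provenance == "probabilistic")
  if (length(idx) == 0) return(trace)
  df <- as.data.frame(records)
  pr <- trace[idx, c("id1", "id2"), drop = FALSE]
  st <- pair_states(df, pr)
  i <- match(pr$id1, df$record_id)
  j <- match(pr$id2, df$record_id)
  sex_conflict <- field_state(df$sex[i], df$sex[j]) == "NONMATCH"
  decision <- classify_triple(st$name_state, st$father_state, st$mother_state,
                              rules)
  any_non <- st$name_state == "NONMATCH" | st$father_state == "NONMATCH" |
    st$mother_state == "NONMATCH"
  flagged <- sex_conflict | (!decision & any_non)
  trace$audit[idx] <- ifelse(flagged, "flagged", "consistent")
  trace
}
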