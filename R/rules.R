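FIELD_STATES <- c("MATCH", "NONMATCH", "NOT_AVAILABLE")

#' Agreement state of one field across a record pair
#'
#' \code{NOT_AVAILABLE} if either side is missing, \code{MATCH} if both are
#' present and equal, otherwise \code{NONMATCH}. Values are assumed already
#' canonical (see \code{\link{normalize_text}}).
#'
#' @param a,b character vectors of canonical values (vectorized).
#' @return Character vector over \code{MATCH, NONMATCH, NOT_AVAILABLE}.
#' @export
field_state <- function(a, b) {
  out <- ifelse(is.na(a) | is.na(b), "NOT_AVAILABLE",
                ifelse(a == b, "MATCH", "NONMATCH"))
  as.character(out)
}

#' The deterministic decision table
#'
#' A total mapping from the agreement-state triple (child's name, father's
#' name, mother's name) to a match decision, evaluated only for pairs already
#' agreeing exactly on date of birth, sex and village (the blocking key). The
#' default table is the majority rule \code{count(MATCH) > count(NONMATCH)},
#' which reproduces all 21 published review criteria (10 match, 11 nonmatch)
#' and resolves the 6 unlisted state combinations - all of which have no
#' matching field - to \code{FALSE}.
#'
#' @param overrides optional data frame with columns \code{name_state},
#'   \code{father_state}, \code{mother_state}, \code{decision} replacing the
#'   default decision for the listed triples.
#' @return A \code{rule_table}: data frame over all 27 state triples with a
#'   logical \code{decision} column.
#' @export
rule_table <- function(overrides = NULL) {
  grid <- expand.grid(
    name_state = FIELD_STATES, father_state = FIELD_STATES,
    mother_state = FIELD_STATES,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n_match <- rowSums(grid == "MATCH")
  n_non <- rowSums(grid == "NONMATCH")
  grid$decision <- n_match > n_non
  if (!is.null(overrides)) {
    need <- c("name_state", "father_state", "mother_state", "decision")
    if (!all(need %in% names(overrides))) {
      stop("rule overrides need columns: ", paste(need, collapse = ", "))
    }
    for (i in seq_len(nrow(overrides))) {
      sel <- grid$name_state == overrides$name_state[i] &
        grid$father_state == overrides$father_state[i] &
        grid$mother_state == overrides$mother_state[i]
      if (!any(sel)) stop("override row ", i, " names an unknown state triple")
      grid$decision[sel] <- as.logical(overrides$decision[i])
    }
  }
  key <- paste(grid$name_state, grid$father_state, grid$mother_state, sep = "|")
  grid <- grid[order(key), , drop = FALSE]
  rownames(grid) <- NULL
  class(grid) <- c("rule_table", "data.frame")
  grid
}

#' Read a rule-table override file
#'
#' @param path CSV with columns \code{name_state, father_state, mother_state,
#'   decision}.
#' @return A \code{\link{rule_table}} with the file's decisions applied over
#'   the default table.
#' @export
read_rule_table <- function(path) {
  if (!file.exists(path)) stop("cannot read rule table: no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  df$decision <- toupper(df$decision) %in% c("TRUE", "T", "1", "YES")
  rule_table(overrides = df)
}

#' Classify a state triple under a rule table
#'
#' @param name_state,father_state,mother_state character vectors of field
#'   states (vectorized; recycled to common length).
#' @param rules a \code{\link{rule_table}}.
#' @return Logical vector of match decisions.
#' @examples
#' classify_triple("MATCH", "MATCH", "NONMATCH")            # TRUE
#' classify_triple("MATCH", "NONMATCH", "NONMATCH")         # FALSE
#' @export
classify_triple <- function(name_state, father_state, mother_state,
                            rules = rule_table()) {
  stopifnot(inherits(rules, "rule_table"))
  n <- max(length(name_state), length(father_state), length(mother_state))
  name_state <- rep_len(name_state, n)
  father_state <- rep_len(father_state, n)
  mother_state <- rep_len(mother_state, n)
  ok <- c(name_state, father_state, mother_state) %in% FIELD_STATES
  if (!all(ok)) stop("unknown field state; expected one of ",
                     paste(FIELD_STATES, collapse = ", "))
  key <- paste(name_state, father_state, mother_state, sep = "|")
  rkey <- paste(rules$name_state, rules$father_state, rules$mother_state, sep = "|")
  unname(rules$decision[match(key, rkey)])
}
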