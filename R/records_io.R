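RECORD_FIELDS <- c(
  "record_id", "name", "family_name", "dob", "sex", "village",
  "father_name", "mother_name", "contact"
)
TEXT_FIELDS <- c("name", "family_name", "village", "father_name", "mother_name")

# tokens read as missing in addition to the empty cell; configurable via
# read_records(na_tokens = ...)
DEFAULT_NA_TOKENS <- c("", "NA", "N/A", "na", "n/a", "-")

#' Read demographic records from CSV
#'
#' Reads a UTF-8 CSV of child demographic records with a header row. Expected
#' columns: \code{record_id, name, family_name, dob, sex, village,
#' father_name, mother_name, contact}; missing optional columns are filled
#' with \code{NA}. Dates are accepted as day-first (\code{dd/mm/yyyy}) or ISO
#' 8601 (\code{yyyy-mm-dd}) and stored as \code{Date}. Rows with an
#' unparseable date are kept but flagged; the flag count is available as
#' \code{attr(x, "invalid_dates")}.
#'
#' @param path path to a CSV file.
#' @param na_tokens character vector of cell values treated as missing
#'   (whitespace-only cells are always missing).
#' @param max_contact maximum permitted length of the contact field.
#' @return Data frame of raw records (class \code{lao_records}), one row per
#'   input row, with attributes \code{invalid_dates} (count) and
#'   \code{invalid_date_ids} (record ids).
#' @export
read_records <- function(path, na_tokens = DEFAULT_NA_TOKENS, max_contact = 50) {
  if (!file.exists(path)) stop("cannot read records: no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                        check.names = FALSE)
  if (!"record_id" %in% names(df)) stop("records CSV must have a record_id column")
  for (f in setdiff(RECORD_FIELDS, names(df))) df[[f]] <- NA_character_
  df <- df[RECORD_FIELDS]
  as_records(df, na_tokens = na_tokens, max_contact = max_contact)
}

#' Validate a data frame of raw records
#'
#' Applies the same validation as \code{\link{read_records}} to an in-memory
#' data frame: missing-token substitution, unique \code{record_id}, date
#' parsing with flagging, and the contact length bound.
#'
#' @inheritParams read_records
#' @param df data frame with the record columns.
#' @return Validated records data frame (class \code{lao_records}).
#' @export
as_records <- function(df, na_tokens = DEFAULT_NA_TOKENS, max_contact = 50) {
  for (f in setdiff(RECORD_FIELDS, names(df))) df[[f]] <- NA_character_
  df <- df[RECORD_FIELDS]
  for (f in setdiff(RECORD_FIELDS, "dob")) {
    v <- as.character(df[[f]])
    v[is.na(v)] <- NA_character_
    blank <- !is.na(v) & (trimws(v) %in% na_tokens | trimws(v) == "")
    v[blank] <- NA_character_
    df[[f]] <- v
  }
  if (anyDuplicated(df$record_id)) {
    dup <- unique(df$record_id[duplicated(df$record_id)])
    stop("duplicate record_id: ", paste(head(dup, 5), collapse = ", "))
  }
  if (any(is.na(df$record_id))) stop("record_id may not be missing")

  too_long <- !is.na(df$contact) & nchar(df$contact) > max_contact
  if (any(too_long)) {
    stop(sprintf(
      "contact exceeds the %d-character bound for record(s): %s",
      max_contact, paste(head(df$record_id[too_long], 5), collapse = ", ")
    ))
  }

  raw_dob <- if (is.character(df$dob)) df$dob else as.character(df$dob)
  raw_dob[!is.na(raw_dob) & trimws(raw_dob) %in% c(na_tokens, "")] <- NA_character_
  dob <- parse_dob(raw_dob)
  invalid <- !is.na(raw_dob) & is.na(dob)
  df$dob <- dob
  attr(df, "invalid_dates") <- sum(invalid)
  attr(df, "invalid_date_ids") <- df$record_id[invalid]
  class(df) <- c("lao_records", "data.frame")
  df
}

# day-first dd/mm/yyyy or ISO yyyy-mm-dd; impossible dates -> NA
parse_dob <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[which(iso)] <- as.Date(x[which(iso)], format = "%Y-%m-%d")
  out[which(dmy)] <- as.Date(x[which(dmy)], format = "%d/%m/%Y")
  out
}

#' Write records to CSV
#'
#' Inverse of \code{\link{read_records}}: UTF-8 CSV with ISO 8601 dates.
#'
#' @param records records data frame.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  df <- as.data.frame(records)
  df$dob <- format(df$dob, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(NULL)
}

#' Write a partition to CSV
#'
#' Two-column CSV (\code{record_id, cluster_id}) sorted by record id.
#'
#' @param p a \code{\link{partition}}.
#' @param path output path.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "partition"))
  df <- as.data.frame(p)[order(p$record_id), c("record_id", "cluster_id")]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

#' Read a partition from CSV
#'
#' @param path CSV with columns \code{record_id} and \code{cluster_id}.
#' @return A \code{\link{partition}}.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("cannot read partition: no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("record_id", "cluster_id") %in% names(df))) {
    stop("partition CSV must have record_id and cluster_id columns")
  }
  partition(df$record_id, df$cluster_id)
}

#' Pipeline configuration
#'
#' Collects every tunable of the matching pipeline in one list so that all
#' stages, and all randomness, are driven from a single object.
#'
#' @param det_keys blocking keys of the deterministic stage.
#' @param prob_keys blocking keys of the probabilistic stage (composite key:
#'   a pair is comparable only if it agrees exactly on all of them).
#' @param jw_thresholds decreasing Jaro-Winkler cut-offs defining the partial
#'   agreement levels of name fields.
#' @param recall assumed recall of the deterministic proxy used to estimate
#'   the prior match probability lambda; in (0, 1].
#' @param threshold posterior match probability above which a pair is linked.
#' @param em_tol convergence tolerance on the observed-data log-likelihood.
#' @param em_max_iter maximum number of EM iterations.
#' @param strict_all_fields deterministic variant requiring exact agreement on
#'   all of name, father's and mother's name (no decision table).
#' @param strict_audit if \code{TRUE}, \code{\link{hybrid_match}} removes
#'   probabilistic links flagged by the deterministic audit instead of merely
#'   flagging them.
#' @param placeholder_as_missing treat placeholder names (e.g. "Eanoi") as
#'   not available rather than as ordinary values.
#' @param seed integer seed driving all randomized behaviour.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(det_keys = c("dob", "sex", "village"),
                            prob_keys = c("dob", "village"),
                            jw_thresholds = c(0.88, 0.70),
                            recall = 0.7,
                            threshold = 0.5,
                            em_tol = 1e-6,
                            em_max_iter = 100,
                            strict_all_fields = FALSE,
                            strict_audit = FALSE,
                            placeholder_as_missing = FALSE,
                            seed = 1L) {
  stopifnot(
    length(recall) == 1, recall > 0, recall <= 1,
    length(threshold) == 1, threshold >= 0, threshold <= 1,
    all(diff(jw_thresholds) < 0), all(jw_thresholds > 0 & jw_thresholds < 1),
    em_max_iter >= 1
  )
  cfg <- list(
    det_keys = det_keys, prob_keys = prob_keys,
    jw_thresholds = jw_thresholds, recall = recall, threshold = threshold,
    em_tol = em_tol, em_max_iter = em_max_iter,
    strict_all_fields = strict_all_fields, strict_audit = strict_audit,
    placeholder_as_missing = placeholder_as_missing,
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}
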