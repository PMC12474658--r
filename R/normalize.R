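DEFAULT_PLACEHOLDERS <- c("EANOI", "ແອນ້ອຍ",
                          "MR", "MR.", "MISS", "MISS.")

#' Canonicalize a free-text field
#'
#' Normalization pipeline for name/village text in Lao script or Latin
#' transliteration: Unicode NFC, Latin accent folding, the \code{charmap}
#' substitutions, removal of all whitespace (Lao is written without spaces and
#' transliterations space names inconsistently), upper-casing, and removal of
#' characters outside the Lao block (U+0E80--U+0EFF) and printable ASCII.
#' The function is total and idempotent; missing input stays missing.
#'
#' @param s character vector (may contain \code{NA}).
#' @param map a \code{\link{read_charmap}} substitution table.
#' @return Character vector of canonical forms with attribute
#'   \code{stripped}: the number of inputs from which unmappable characters
#'   were removed.
#' @examples
#' normalize_text("  souk  san ")  # "SOUKSAN"
#' @export
normalize_text <- function(s, map = default_charmap()) {
  out <- as.character(s)
  miss <- is.na(out)
  x <- out[!miss]
  if (length(x)) {
    x <- stringi::stri_trans_nfc(x)
    x <- stringi::stri_trans_general(x, "Latin-ASCII")
    x <- apply_charmap(x, map)
    x <- gsub("\\s+", "", x, perl = TRUE)
    x <- stringi::stri_trans_toupper(x, locale = "en")
    keep_re <- "[^\\x20-\\x7E\\x{0E80}-\\x{0EFF}]"
    stripped <- stringi::stri_detect_regex(x, keep_re)
    x <- stringi::stri_replace_all_regex(x, keep_re, "")
    x[x == ""] <- NA_character_
    out[!miss] <- x
    attr(out, "stripped") <- sum(stripped)
  } else {
    attr(out, "stripped") <- 0L
  }
  out
}

#' Is a canonical name a placeholder?
#'
#' Placeholder (temporary) names such as "Eanoi" ("baby") are recorded before
#' a Lao child receives a permanent name, together with honorific stand-ins
#' like "Mr."/"Miss". Downstream stages can optionally demote agreement on a
#' placeholder to "not available".
#'
#' @param name character vector of canonical names (from
#'   \code{\link{normalize_text}}).
#' @param placeholders canonical placeholder list.
#' @return Logical vector; missing names give \code{FALSE} (missingness is
#'   handled separately).
#' @export
placeholder_flag <- function(name, placeholders = DEFAULT_PLACEHOLDERS) {
  ph <- normalize_text(placeholders)
  !is.na(name) & name %in% ph
}

SEX_MAP <- c(
  "M" = "male", "MALE" = "male", "ຊາຍ" = "male",
  "F" = "female", "FEMALE" = "female", "ຍິງ" = "female",
  "MALE." = "male", "FEMALE." = "female"
)

normalize_sex <- function(x) {
  v <- toupper(trimws(as.character(x)))
  out <- unname(SEX_MAP[v])
  out[is.na(out) & !is.na(v)] <- "unknown"
  out
}

# Lao phone numbers: 8-11 digits once separators are removed
lao_phone_ok <- function(x) {
  d <- gsub("[^0-9]", "", x)
  !is.na(x) & nchar(d) >= 8 & nchar(d) <= 11
}

#' Normalize a set of records
#'
#' Applies \code{\link{normalize_text}} to every text field, maps sex onto
#' \{male, female, unknown\}, and checks the contact field against the Lao
#' phone format (8--11 digits). Records with a malformed contact are retained
#' with the field flagged (ids in \code{attr(x, "contact_flagged")}).
#'
#' @param records raw records (from \code{\link{read_records}} or
#'   \code{\link{as_records}}).
#' @param map a \code{\link{read_charmap}} substitution table.
#' @return Normalized records data frame (class \code{lao_records_norm}).
#' @export
normalize_records <- function(records, map = default_charmap()) {
  df <- as.data.frame(records)
  stopifnot(all(RECORD_FIELDS %in% names(df)))
  for (f in TEXT_FIELDS) df[[f]] <- as.character(normalize_text(df[[f]], map))
  df$sex <- normalize_sex(df$sex)
  bad_contact <- !is.na(df$contact) & !lao_phone_ok(df$contact)
  attr(df, "contact_flagged") <- df$record_id[bad_contact]
  class(df) <- c("lao_records_norm", "data.frame")
  df
}
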