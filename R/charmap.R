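#' Character substitution maps for Lao text canonicalization
#'
#' A \code{charmap} is an ordered substitution table (source sequence ->
#' canonical sequence) applied after Unicode NFC normalization. The bundled
#' default map canonicalizes Lao digit forms and the \code{HO NO} / \code{HO
#' MO} ligature code points, and strips zero-width characters. An optional
#' phonetic-merge layer additionally collapses confusable vowel length marks
#' (e.g. the short and long "u" vowels that spell Souksan two ways) and tone
#' marks into one class, so spellings differing only in those marks compare
#' equal.
#'
#' The map must be idempotent: applying it to any of its own targets changes
#' nothing. This is validated at load time and rules that would rewrite each
#' other's output (cycles) are rejected.
#'
#' @param path CSV file with columns \code{source}, \code{target} (UTF-8).
#' @return A \code{charmap} object (data frame of rules, longest source
#'   first).
#' @export
read_charmap <- function(path) {
  if (!file.exists(path)) stop("cannot read charmap: no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("source", "target") %in% names(df))) {
    stop("charmap CSV must have source and target columns")
  }
  df$target[is.na(df$target)] <- ""
  as_charmap(df)
}

#' @rdname read_charmap
#' @param rules data frame with columns \code{source}, \code{target}.
#' @export
as_charmap <- function(rules) {
  rules <- data.frame(
    source = stringi::stri_trans_nfc(as.character(rules$source)),
    target = stringi::stri_trans_nfc(as.character(rules$target)),
    stringsAsFactors = FALSE
  )
  rules$target[is.na(rules$target)] <- ""
  if (any(is.na(rules$source) | rules$source == "")) stop("charmap sources may not be empty")
  if (anyDuplicated(rules$source)) stop("charmap sources must be unique")
  # longest source first so multi-character rules win over their prefixes
  rules <- rules[order(-nchar(rules$source), rules$source), , drop = FALSE]
  rownames(rules) <- NULL
  class(rules) <- c("charmap", "data.frame")
  # idempotence (hence acyclicity): every target is a fixed point of the map
  for (i in seq_len(nrow(rules))) {
    tgt <- rules$target[i]
    if (tgt != "" && apply_charmap(tgt, rules) != tgt) {
      stop(sprintf(
        "charmap is not idempotent: target '%s' of rule %d is rewritten by the map",
        tgt, i
      ))
    }
  }
  rules
}

#' @rdname read_charmap
#' @param phonetic include the phonetic-merge layer collapsing confusable
#'   vowel length and tone marks.
#' @export
default_charmap <- function(phonetic = FALSE) {
  base <- system.file("extdata", "charmap_default.csv", package = "laolink")
  rules <- utils::read.csv(base, colClasses = "character", fileEncoding = "UTF-8")
  if (phonetic) {
    ph <- system.file("extdata", "charmap_phonetic.csv", package = "laolink")
    rules <- rbind(rules, utils::read.csv(ph, colClasses = "character",
                                          fileEncoding = "UTF-8"))
  }
  rules$target[is.na(rules$target)] <- ""
  as_charmap(rules)
}

apply_charmap <- function(x, map) {
  for (i in seq_len(nrow(map))) {
    x <- gsub(map$source[i], map$target[i], x, fixed = TRUE)
  }
  x
}
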