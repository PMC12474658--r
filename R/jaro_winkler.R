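#' Jaro-Winkler string similarity
#'
#' Similarity in [0, 1] between canonical strings, operating on Unicode code
#' points so Lao script and Latin transliterations are handled alike. Uses the
#' standard Jaro similarity (common characters within a window of
#' \code{floor(max(len)/2) - 1}, transposition penalty) plus the Winkler
#' common-prefix bonus with scaling factor \code{p = 0.1} and prefix length
#' capped at 4.
#'
#' @param s1,s2 character vectors (recycled to common length). Missing values
#'   are a contract violation: callers must resolve missingness before
#'   computing similarity.
#' @param p prefix scaling factor.
#' @param max_prefix maximum prefix length credited.
#' @return Numeric vector of similarities.
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")  # 0.9611
#' @export
jaro_winkler <- function(s1, s2, p = 0.1, max_prefix = 4L) {
  n <- max(length(s1), length(s2))
  s1 <- rep_len(as.character(s1), n)
  s2 <- rep_len(as.character(s2), n)
  if (anyNA(s1) || anyNA(s2)) {
    stop("jaro_winkler: inputs may not be missing; handle missingness upstream")
  }
  a_cp <- lapply(s1, utf8ToInt)
  b_cp <- lapply(s2, utf8ToInt)
  vapply(seq_len(n), function(k) jw_one(a_cp[[k]], b_cp[[k]], p, max_prefix),
         numeric(1))
}

# single-pair Jaro-Winkler on integer code-point vectors
jw_one <- function(a, b, p = 0.1, max_prefix = 4L) {
  la <- length(a); lb <- length(b)
  if (la == 0L && lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)
  window <- max(floor(max(la, lb) / 2) - 1L, 0L)
  a_match <- logical(la)
  b_match <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1L, i - window)
    hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!b_match[j] && a[i] == b[j]) {
        a_match[i] <- TRUE
        b_match[j] <- TRUE
        break
      }
    }
  }
  m <- sum(a_match)
  if (m == 0L) return(0)
  # transpositions: positions at which the matched subsequences differ
  t <- sum(a[a_match] != b[b_match]) / 2
  jaro <- (m / la + m / lb + (m - t) / m) / 3
  l <- 0L
  for (i in seq_len(min(la, lb, max_prefix))) {
    if (a[i] == b[i]) l <- l + 1L else break
  }
  jaro + l * p * (1 - jaro)
}
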