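#' Comparison specification for the probabilistic matcher
#'
#' Defines, per compared field, the ordered agreement levels assigned to a
#' record pair. String fields use four levels: exact equality of canonical
#' forms; Jaro-Winkler similarity >= the first threshold; >= the second
#' threshold; anything else. Categorical fields use exact/else. A field
#' missing on either side of a pair is assigned no level (not available) and
#' is ignored by the model (missing at random).
#'
#' @param string_fields fields compared with Jaro-Winkler levels.
#' @param exact_fields fields compared exact/else.
#' @param jw_thresholds strictly decreasing Jaro-Winkler cut-offs in (0, 1).
#' @return A \code{comparison_spec} object.
#' @export
comparison_spec <- function(string_fields = c("name", "father_name", "mother_name"),
                            exact_fields = "sex",
                            jw_thresholds = c(0.88, 0.70)) {
  stopifnot(all(diff(jw_thresholds) < 0), all(jw_thresholds > 0 & jw_thresholds < 1))
  fields <- c(
    lapply(string_fields, function(f) {
      list(field = f, type = "jw", thresholds = jw_thresholds,
           n_levels = length(jw_thresholds) + 2L)
    }),
    lapply(exact_fields, function(f) {
      list(field = f, type = "exact", n_levels = 2L)
    })
  )
  names(fields) <- vapply(fields, `[[`, "", "field")
  structure(list(fields = fields), class = "comparison_spec")
}

#' Comparison vectors for a set of record pairs
#'
#' @param records normalized records.
#' @param pairs data frame with columns \code{id1}, \code{id2}.
#' @param spec a \code{\link{comparison_spec}}.
#' @return Integer matrix (pairs x fields) of agreement levels, 1 = most
#'   agreeing; \code{NA} where the field is unavailable on either side.
#' @export
compare_pairs <- function(records, pairs, spec = comparison_spec()) {
  stopifnot(inherits(spec, "comparison_spec"))
  df <- as.data.frame(records)
  i <- match(pairs$id1, df$record_id)
  j <- match(pairs$id2, df$record_id)
  if (anyNA(i) || anyNA(j)) stop("pairs refer to unknown record ids")
  out <- matrix(NA_integer_, nrow = nrow(pairs), ncol = length(spec$fields),
                dimnames = list(NULL, names(spec$fields)))
  for (fs in spec$fields) {
    a <- df[[fs$field]][i]
    b <- df[[fs$field]][j]
    avail <- !is.na(a) & !is.na(b)
    lev <- rep(NA_integer_, nrow(pairs))
    if (fs$type == "exact") {
      lev[avail] <- ifelse(a[avail] == b[avail], 1L, 2L)
    } else {
      eq <- avail & a == b
      lev[eq] <- 1L
      rest <- avail & !eq
      if (any(rest)) {
        sim <- jaro_winkler(a[rest], b[rest])
        lv <- rep(fs$n_levels, sum(rest))
        for (t in rev(seq_along(fs$thresholds))) {
          lv[sim >= fs$thresholds[t]] <- t + 1L
        }
        lev[rest] <- as.integer(lv)
      }
    }
    out[, fs$field] <- lev
  }
  out
}
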