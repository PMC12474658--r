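# shared fixtures and independent oracles

# record builder with sensible defaults; fields overridable per record
make_records <- function(n, ...) {
  over <- list(...)
  df <- data.frame(
    record_id = sprintf("r%03d", seq_len(n)),
    name = paste0("NAME", seq_len(n)),
    family_name = NA_character_,
    dob = rep("2020-01-01", n),
    sex = rep("female", n),
    village = rep("BANA", n),
    father_name = paste0("FATHER", seq_len(n)),
    mother_name = paste0("MOTHER", seq_len(n)),
    contact = NA_character_,
    stringsAsFactors = FALSE
  )
  for (f in names(over)) df[[f]] <- over[[f]]
  normalize_records(as_records(df))
}

# from-definition Jaro-Winkler, written independently of the package version:
# availability-vector scan for common characters, positional comparison of
# the matched subsequences for transpositions
jw_oracle <- function(s1, s2) {
  a <- utf8ToInt(s1); b <- utf8ToInt(s2)
  if (length(a) == 0 && length(b) == 0) return(1)
  if (length(a) == 0 || length(b) == 0) return(0)
  win <- max(floor(max(length(a), length(b)) / 2) - 1, 0)
  b_free <- rep(TRUE, length(b))
  a_hit <- integer(0)
  b_hit <- integer(0)
  for (i in seq_along(a)) {
    cand <- which(b_free & b == a[i])
    cand <- cand[abs(cand - i) <= win]
    if (length(cand) > 0) {
      j <- min(cand)
      b_free[j] <- FALSE
      a_hit <- c(a_hit, i)
      b_hit <- c(b_hit, j)
    }
  }
  m <- length(a_hit)
  if (m == 0) return(0)
  trans <- sum(a[a_hit] != b[sort(b_hit)]) / 2
  jaro <- mean(c(m / length(a), m / length(b), (m - trans) / m))
  l <- 0
  for (i in seq_len(min(4, length(a), length(b)))) {
    if (a[i] == b[i]) l <- l + 1 else break
  }
  jaro + 0.1 * l * (1 - jaro)
}

# brute-force record-level confusion: per-record membership check
confusion_oracle <- function(predicted, gold) {
  pos_in <- function(p, id) {
    cl <- p$cluster_id[p$record_id == id]
    sum(p$cluster_id == cl) >= 2
  }
  ids <- gold$record_id
  pp <- vapply(ids, function(i) pos_in(predicted, i), logical(1))
  pg <- vapply(ids, function(i) pos_in(gold, i), logical(1))
  list(tn = sum(!pp & !pg), fp = sum(pp & !pg),
       fn = sum(!pp & pg), tp = sum(pp & pg))
}

# random partition over given ids
random_partition <- function(ids, n_clusters) {
  partition(ids, sample(seq_len(n_clusters), length(ids), replace = TRUE))
}

# the 21 published review criteria over (name, father, mother) states
published_rules <- function() {
  M <- "MATCH"; N <- "NONMATCH"; A <- "NOT_AVAILABLE"
  rows <- list(
    list(M, M, M, TRUE),  list(M, M, N, TRUE),  list(M, N, M, TRUE),
    list(M, N, N, FALSE), list(N, M, M, TRUE),  list(N, N, M, FALSE),
    list(N, M, N, FALSE), list(N, N, N, FALSE), list(M, M, A, TRUE),
    list(M, A, M, TRUE),  list(M, A, A, TRUE),  list(A, M, A, TRUE),
    list(A, A, M, TRUE),  list(A, M, M, TRUE),  list(A, A, A, FALSE),
    list(M, N, A, FALSE), list(M, A, N, FALSE), list(N, M, A, FALSE),
    list(A, M, N, FALSE), list(A, N, M, FALSE), list(N, A, M, FALSE)
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(name_state = r[[1]], father_state = r[[2]],
               mother_state = r[[3]], decision = r[[4]],
               stringsAsFactors = FALSE)
  }))
}
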