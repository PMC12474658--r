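LAO_PLACEHOLDER <- "ແອນ້ອຍ"  # "Eanoi", the pre-naming placeholder

# confusable Lao vowel-length pairs and tone marks
LAO_VOWEL_PAIRS <- matrix(c(
  "ຸ", "ູ",   # short/long u
  "ິ", "ີ",   # short/long i
  "ະ", "າ"    # short/long a
), ncol = 2, byrow = TRUE)
LAO_TONE_MARKS <- c("່", "້", "໊", "໋")

# Latin romanization spelling variants (first applicable, first occurrence)
LATIN_VARIANTS <- matrix(c(
  "PH", "P", "X", "S", "OU", "U", "V", "W", "CH", "TJ",
  "Ph", "P", "Ou", "U", "ou", "u", "ph", "p", "x", "s"
), ncol = 2, byrow = TRUE)

#' Configuration of the synthetic registry generator
#'
#' Defaults emulate the statistical structure of a provincial Lao child
#' health registry: about 15.6\% of records belong to duplicate clusters
#' whose sizes follow the observed 2/3/4/5 mix, the child's family name is
#' recorded for only 32\% of records and a parental contact number for 13\%,
#' placeholder names ("Eanoi", "Mr.", "Miss") occur at their observed rates,
#' and duplicate records differ from their base record through Lao spelling
#' corruptions (tone-mark swap, confusable vowel length, romanization
#' variants, character transposition) or a temporary-name replacement. Twins
#' are emitted as distinct entities sharing date of birth, village, family
#' and parent names.
#'
#' @param n_records number of records to generate.
#' @param dup_fraction fraction of records belonging to clusters of size
#'   >= 2.
#' @param cluster_size_probs distribution of multi-record cluster sizes over
#'   2:5 (must sum to 1).
#' @param completeness named vector of per-field non-missing probabilities.
#' @param placeholder_rates rates of the Eanoi / Mr. / Miss placeholder
#'   names among entities.
#' @param twin_rate fraction of entities that are one of a twin pair.
#' @param twin_placeholder_rate probability that both twins are still
#'   recorded under the placeholder name.
#' @param corrupt_name_rate probability that a duplicate record's child name
#'   is corrupted by a spelling operator.
#' @param corrupt_parent_rate same, per parent name.
#' @param temp_name_rate probability that a duplicate record carries the
#'   placeholder instead of the permanent name (the pre-naming record).
#' @param op_weights sampling weights of the spelling operators in
#'   \code{\link{corrupt_name}}.
#' @param n_villages number of distinct villages.
#' @param date_range inclusive birth-date range.
#' @param latin_share share of entities recorded in Latin transliteration
#'   rather than Lao script.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_records = 20433,
                             dup_fraction = 0.1562,
                             cluster_size_probs = c("2" = 0.869, "3" = 0.114,
                                                    "4" = 0.014, "5" = 0.003),
                             completeness = c(name = 1, family_name = 0.32,
                                              village = 1, father_name = 1,
                                              mother_name = 1, contact = 0.13),
                             placeholder_rates = c(eanoi = 0.024,
                                                   mr = 110 / 20433,
                                                   miss = 80 / 20433),
                             twin_rate = 0.01,
                             twin_placeholder_rate = 0.15,
                             corrupt_name_rate = 0.35,
                             corrupt_parent_rate = 0.30,
                             temp_name_rate = 0.05,
                             op_weights = c(tone_swap = 1, vowel_swap = 1,
                                            translit = 1, transpose = 1),
                             n_villages = 35,
                             date_range = as.Date(c("2019-01-01", "2022-12-31")),
                             latin_share = 0.5,
                             seed = 1L) {
  rates <- c(dup_fraction, completeness, placeholder_rates, twin_rate,
             twin_placeholder_rate, corrupt_name_rate, corrupt_parent_rate,
             temp_name_rate, latin_share)
  stopifnot(
    n_records >= 1,
    all(rates >= 0 & rates <= 1),
    abs(sum(cluster_size_probs) - 1) < 1e-8,
    n_villages >= 1, length(date_range) == 2, date_range[1] <= date_range[2]
  )
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

name_pool <- function() {
  path <- system.file("extdata", "lao_names_synthetic.csv", package = "laolink")
  utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
}

#' Corrupt a name with one Lao-aware spelling operator
#'
#' Samples one operator according to \code{ops} and applies it:
#' \describe{
#'   \item{tone_swap}{replace one Lao tone mark with a different one;}
#'   \item{vowel_swap}{swap a confusable short/long Lao vowel (e.g. the two
#'     spellings of Souksan);}
#'   \item{translit}{apply a romanization spelling variant (PH/P, X/S, OU/U,
#'     ...) to a Latin name;}
#'   \item{transpose}{transpose two adjacent characters;}
#'   \item{temp_name}{replace the whole name with the placeholder
#'     \code{"ແອນ້ອຍ"} (Eanoi), modelling the pre-naming record.}
#' }
#' Operators inapplicable to the input (e.g. a tone swap on a Latin name)
#' fall through to the next sampled choice; if nothing applies, the name is
#' returned unchanged. All-zero weights give the identity.
#'
#' @param name a single non-missing string.
#' @param ops named non-negative sampling weights over the operators.
#' @return The corrupted name, with attribute \code{op}: the operator
#'   applied, or \code{"none"}.
#' @export
corrupt_name <- function(name, ops = c(tone_swap = 1, vowel_swap = 1,
                                       translit = 1, transpose = 1,
                                       temp_name = 0)) {
  stopifnot(length(name) == 1, !is.na(name))
  known <- c("tone_swap", "vowel_swap", "translit", "transpose", "temp_name")
  ops <- ops[names(ops) %in% known]
  ops <- ops[ops > 0]
  if (length(ops) == 0) return(structure(name, op = "none"))
  order_try <- sample(names(ops), length(ops), prob = ops)
  for (op in order_try) {
    out <- apply_corruption_op(name, op)
    if (!is.null(out)) return(structure(out, op = op))
  }
  structure(name, op = "none")
}

# one operator; NULL when inapplicable
apply_corruption_op <- function(name, op) {
  chars <- strsplit(name, "")[[1]]
  switch(op,
    temp_name = LAO_PLACEHOLDER,
    tone_swap = {
      pos <- which(chars %in% LAO_TONE_MARKS)
      if (length(pos) == 0) return(NULL)
      k <- if (length(pos) == 1) pos else sample(pos, 1)
      repl <- setdiff(LAO_TONE_MARKS, chars[k])
      chars[k] <- repl[sample.int(length(repl), 1)]
      paste(chars, collapse = "")
    },
    vowel_swap = {
      hits <- which(chars %in% as.vector(LAO_VOWEL_PAIRS))
      if (length(hits) == 0) return(NULL)
      k <- if (length(hits) == 1) hits else sample(hits, 1)
      ij <- which(LAO_VOWEL_PAIRS == chars[k], arr.ind = TRUE)[1, ]
      chars[k] <- LAO_VOWEL_PAIRS[ij["row"], 3 - ij["col"]]
      paste(chars, collapse = "")
    },
    translit = {
      for (r in seq_len(nrow(LATIN_VARIANTS))) {
        if (grepl(LATIN_VARIANTS[r, 1], name, fixed = TRUE)) {
          return(sub(LATIN_VARIANTS[r, 1], LATIN_VARIANTS[r, 2], name,
                     fixed = TRUE))
        }
      }
      NULL
    },
    transpose = {
      if (length(chars) < 2) return(NULL)
      k <- sample.int(length(chars) - 1, 1)
      chars[c(k, k + 1)] <- chars[c(k + 1, k)]
      out <- paste(chars, collapse = "")
      if (out == name) NULL else out
    },
    stop("unknown corruption operator: ", op)
  )
}

# multi-record cluster sizes summing to ~round(n * dup_fraction)
draw_cluster_sizes <- function(n, dup_fraction, probs) {
  target <- round(n * dup_fraction)
  if (target < 2) return(integer(0))
  sizes <- integer(0)
  total <- 0
  vals <- as.integer(names(probs))
  while (total < target) {
    s <- sample(vals, 1, prob = probs)
    if (total + 2 > n) break
    sizes <- c(sizes, s)
    total <- total + s
  }
  excess <- total - target
  if (excess > 0 && length(sizes) > 0) {
    last <- sizes[length(sizes)]
    sizes[length(sizes)] <- max(2L, last - excess)
    total <- sum(sizes)
  }
  if (total > n) stop("infeasible generator config: duplicate records exceed n_records")
  sizes
}

#' Generate a synthetic Lao-like registry with known truth
#'
#' Emits \code{n_records} demographic records plus the truth partition
#' mapping each record to its entity. Deterministic given the seed.
#'
#' @param config a \code{\link{generator_config}}.
#' @return List with \code{records} (raw records data frame, shuffled row
#'   order) and \code{truth} (a \code{\link{partition}} with attribute
#'   \code{annotations}: data frame (cluster_id, type) with type in
#'   ordinary / twin / temp_name).
#' @export
generate_registry <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_registry_impl(config))
}

generate_registry_impl <- function(cfg) {
  pool <- name_pool()
  n <- cfg$n_records
  sizes <- draw_cluster_sizes(n, cfg$dup_fraction, cfg$cluster_size_probs)
  n_dup_records <- sum(sizes)
  n_singles <- n - n_dup_records
  ent_sizes <- c(sizes, rep(1L, n_singles))
  n_ent <- length(ent_sizes)

  villages <- paste0("BAN", toupper(pool$latin[seq_len(min(cfg$n_villages,
                                                           nrow(pool)))]))
  latin <- runif(n_ent) < cfg$latin_share
  pick_name <- function(k, is_latin) {
    idx <- sample.int(nrow(pool), k, replace = TRUE)
    ifelse(is_latin, pool$latin[idx], pool$lao[idx])
  }
  ent <- data.frame(
    entity = sprintf("E%05d", seq_len(n_ent)),
    size = ent_sizes,
    name = pick_name(n_ent, latin),
    family_name = pick_name(n_ent, latin),
    father_name = pick_name(n_ent, latin),
    mother_name = pick_name(n_ent, latin),
    dob = cfg$date_range[1] +
      sample.int(as.integer(cfg$date_range[2] - cfg$date_range[1]) + 1L,
                 n_ent, replace = TRUE) - 1L,
    sex = sample(c("male", "female"), n_ent, replace = TRUE),
    village = sample(villages, n_ent, replace = TRUE),
    contact = paste0("20", vapply(seq_len(n_ent), function(i)
      paste(sample(0:9, 8, replace = TRUE), collapse = ""), "")),
    type = "ordinary",
    stringsAsFactors = FALSE
  )

  # placeholder names at the configured entity rates
  ph <- runif(n_ent)
  r <- cumsum(cfg$placeholder_rates)
  ent$name[ph < r[1]] <- ifelse(latin[ph < r[1]], "EANOI", LAO_PLACEHOLDER)
  ent$name[ph >= r[1] & ph < r[2]] <- "Mr."
  ent$name[ph >= r[2] & ph < r[3]] <- "Miss"

  # twins: pair up singleton entities; the second of each pair inherits the
  # first's household identifiers but stays a distinct entity
  single_idx <- which(ent$size == 1L)
  n_twin_pairs <- floor(cfg$twin_rate * n_ent / 2)
  if (n_twin_pairs > 0 && length(single_idx) >= 2 * n_twin_pairs) {
    chosen <- sample(single_idx, 2 * n_twin_pairs)
    a <- chosen[seq_len(n_twin_pairs)]
    b <- chosen[n_twin_pairs + seq_len(n_twin_pairs)]
    for (f in c("dob", "village", "family_name", "father_name", "mother_name")) {
      ent[[f]][b] <- ent[[f]][a]
    }
    same_sex <- runif(n_twin_pairs) < 0.5
    ent$sex[b][same_sex] <- ent$sex[a][same_sex]
    ent$sex[b][!same_sex] <- ifelse(ent$sex[a][!same_sex] == "male",
                                    "female", "male")
    both_ph <- runif(n_twin_pairs) < cfg$twin_placeholder_rate
    ph_name <- ifelse(latin[a], "EANOI", LAO_PLACEHOLDER)
    ent$name[a][both_ph] <- ph_name[both_ph]
    ent$name[b][both_ph] <- ph_name[both_ph]
    ent$type[c(a, b)] <- "twin"
  }

  # expand entities into records; duplicates derive from the base record
  rows <- ent[rep(seq_len(n_ent), ent$size), , drop = FALSE]
  is_dup <- unlist(lapply(ent$size, function(s) c(FALSE, rep(TRUE, s - 1L))))
  dup_idx <- which(is_dup)
  ops_name <- cfg$op_weights
  for (k in dup_idx) {
    if (runif(1) < cfg$temp_name_rate) {
      rows$name[k] <- LAO_PLACEHOLDER
      rows$type[k] <- "temp_name"
    } else if (runif(1) < cfg$corrupt_name_rate) {
      rows$name[k] <- as.character(corrupt_name(rows$name[k], ops_name))
    }
    for (f in c("father_name", "mother_name")) {
      if (runif(1) < cfg$corrupt_parent_rate) {
        rows[[f]][k] <- as.character(corrupt_name(rows[[f]][k], ops_name))
      }
    }
  }

  # completeness masking (dob, sex always present)
  nr <- nrow(rows)
  for (f in names(cfg$completeness)) {
    drop <- runif(nr) >= cfg$completeness[[f]]
    rows[[f]][drop] <- NA_character_
  }

  ord <- sample.int(nr)
  rows <- rows[ord, , drop = FALSE]
  rows$record_id <- sprintf("R%06d", seq_len(nr))
  records <- as_records(rows[c("record_id", "name", "family_name", "dob",
                               "sex", "village", "father_name", "mother_name",
                               "contact")])
  truth <- partition(rows$record_id, rows$entity)

  cl_type <- tapply(rows$type, rows$entity, function(t) {
    if (any(t == "twin")) "twin"
    else if (any(t == "temp_name")) "temp_name"
    else "ordinary"
  })
  attr(truth, "annotations") <- data.frame(
    cluster_id = names(cl_type), type = unname(cl_type),
    stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}

#' Simulate the three-reviewer gold-standard process
#'
#' Each simulated reviewer applies the deterministic decision table to every
#' within-block candidate pair, with each decision independently flipped at
#' the given error rate; the consensus links are the pairs all three
#' reviewers call a match (so the consensus match count never exceeds any
#' single reviewer's).
#'
#' @param records normalized records.
#' @param reviewer_error_rate per-decision flip probability.
#' @param keys review blocking keys.
#' @param seed integer seed.
#' @return List with \code{reviewers} (list of three partitions),
#'   \code{consensus} (partition), and \code{match_counts} (linked-record
#'   count per reviewer and for the consensus).
#' @export
emit_gold_review <- function(records, reviewer_error_rate = 0.02,
                             keys = c("dob", "sex", "village"), seed = 1L) {
  df <- as.data.frame(records)
  pairs <- block_pairs(block_records(df, keys))
  st <- if (nrow(pairs)) pair_states(df, pairs) else NULL
  base <- if (nrow(pairs)) {
    classify_triple(st$name_state, st$father_state, st$mother_state)
  } else logical(0)
  withr::with_seed(seed, {
    revs <- lapply(1:3, function(r) {
      flip <- runif(length(base)) < reviewer_error_rate
      xor(base, flip)
    })
    parts <- lapply(revs, function(d) {
      partition_from_links(df$record_id, pairs[d, , drop = FALSE])
    })
    cons <- Reduce(`&`, revs)
    consensus <- partition_from_links(df$record_id, pairs[cons, , drop = FALSE])
    list(
      reviewers = parts,
      consensus = consensus,
      match_counts = c(vapply(parts, function(p) length(linked_records(p)), 1L),
                       consensus = length(linked_records(consensus)))
    )
  })
}
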