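test_that("the generator is deterministic given the seed", {
  a <- generate_registry(generator_config(n_records = 500, seed = 99))
  b <- generate_registry(generator_config(n_records = 500, seed = 99))
  expect_identical(as.data.frame(a$records), as.data.frame(b$records))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c <- generate_registry(generator_config(n_records = 500, seed = 100))
  expect_false(identical(as.data.frame(a$records), as.data.frame(c$records)))
})

test_that("a duplicate-free, corruption-free registry is all singletons", {
  cfg <- generator_config(
    n_records = 100, dup_fraction = 0, twin_rate = 0,
    corrupt_name_rate = 0, corrupt_parent_rate = 0, temp_name_rate = 0,
    completeness = c(name = 1, family_name = 1, village = 1,
                     father_name = 1, mother_name = 1, contact = 1),
    seed = 12
  )
  gen <- generate_registry(cfg)
  expect_equal(nrow(gen$records), 100)
  expect_equal(max(cluster_sizes(gen$truth)), 1)
  rows <- as.data.frame(gen$records)[-1]  # drop record_id
  expect_equal(anyDuplicated(rows), 0)
})

test_that("truth clusters are consistent with emitted records", {
  gen <- generate_registry(generator_config(n_records = 1000, seed = 44))
  expect_setequal(gen$truth$record_id, gen$records$record_id)
  ann <- attr(gen$truth, "annotations")
  expect_setequal(ann$cluster_id, unique(gen$truth$cluster_id))
  expect_true(all(ann$type %in% c("ordinary", "twin", "temp_name")))
  # every duplicate record shares dob and village with its cluster mates
  tp <- partition_pairs(gen$truth)
  df <- as.data.frame(gen$records)
  i <- match(tp$id1, df$record_id); j <- match(tp$id2, df$record_id)
  expect_true(all(df$dob[i] == df$dob[j]))
})

test_that("rates calibrate to the configuration at moderate n", {
  cfg <- generator_config(n_records = 5000, seed = 7)
  gen <- generate_registry(cfg)
  rec <- normalize_records(gen$records)
  comp <- completeness_profile(rec)
  expect_equal(comp$pct_complete[comp$field == "family_name"], 32,
               tolerance = 0.0625)  # +/- 2 points
  ph_rate <- mean(placeholder_flag(rec$name), na.rm = TRUE)
  # Eanoi + Mr. + Miss entity rates, plus pre-naming duplicates
  expect_gt(ph_rate, 0.02)
  expect_lt(ph_rate, 0.06)
  sz <- cluster_sizes(gen$truth)
  expect_equal(sum(sz[sz >= 2]) / 5000, 0.1562, tolerance = 0.065)
})

test_that("review-flagged share matches the configured collision structure", {
  cfg <- generator_config(n_records = 10000, seed = 23)
  gen <- generate_registry(cfg)
  rec <- normalize_records(gen$records)
  got <- attr(candidate_review_set(rec), "proportion")
  # analytic expectation: true duplicates are flagged by construction, and a
  # singleton entity is flagged when another entity draws the same
  # (dob, sex, village) key (Poisson approximation over the key space)
  sz <- cluster_sizes(gen$truth)
  n_dup <- sum(sz[sz >= 2])
  n_ent <- length(sz)
  key_space <- cfg$n_villages * 2 *
    (as.integer(diff(cfg$date_range)) + 1)
  collide <- 1 - exp(-(n_ent - 1) / key_space)
  expected <- n_dup / cfg$n_records +
    (1 - n_dup / cfg$n_records) * collide
  expect_lt(abs(got - expected), 0.02)  # within 2 points
})

test_that("twins share identifiers but remain distinct entities", {
  gen <- generate_registry(generator_config(n_records = 4000, seed = 3,
                                            twin_rate = 0.05))
  ann <- attr(gen$truth, "annotations")
  twins <- ann$cluster_id[ann$type == "twin"]
  expect_gt(length(twins), 0)
  # twins are singleton truth clusters here (each twin is one record)
  sz <- cluster_sizes(gen$truth)
  expect_true(all(sz[twins] >= 1))
})

test_that("spelling operators behave as documented", {
  withr::local_seed(6)
  expect_identical(as.character(corrupt_name("SOUKSAN", ops = c(transpose = 0))),
                   "SOUKSAN")
  v <- corrupt_name("ສຸກສັນ", ops = c(vowel_swap = 1))
  expect_identical(as.character(v), "ສູກສັນ")
  expect_identical(as.character(corrupt_name("DAO", ops = c(temp_name = 1))),
                   "ແອນ້ອຍ")
  tr <- corrupt_name("SOUKSAN", ops = c(transpose = 1))
  expect_false(identical(as.character(tr), "SOUKSAN"))
  expect_equal(nchar(tr), 7)
  # inapplicable operator falls through to identity
  expect_identical(as.character(corrupt_name("DAO", ops = c(tone_swap = 1))),
                   "DAO")
  lat <- corrupt_name("Phetvong", ops = c(translit = 1))
  expect_false(identical(as.character(lat), "Phetvong"))
})

test_that("placeholder twins can fool the deterministic matcher", {
  fp_seen <- FALSE
  for (seed in c(1, 2, 3)) {
    gen <- generate_registry(generator_config(n_records = 3000, seed = seed))
    rec <- normalize_records(gen$records)
    det <- deterministic_match(rec)
    cc <- record_confusion(det, gen$truth)
    if (cc$fp > 0) fp_seen <- TRUE
  }
  expect_true(fp_seen)
})

test_that("simulated reviewer consensus is the intersection of reviewers", {
  gen <- generate_registry(generator_config(n_records = 2000, seed = 15))
  rec <- normalize_records(gen$records)

  perfect <- emit_gold_review(rec, reviewer_error_rate = 0, seed = 1)
  det_rule <- partition_from_links(
    rec$record_id,
    attr(deterministic_match(rec), "pairs")
  )
  expect_true(same_partition(perfect$consensus, det_rule))
  for (p in perfect$reviewers) {
    expect_true(same_partition(p, det_rule))
  }

  noisy <- emit_gold_review(rec, reviewer_error_rate = 0.02, seed = 2)
  counts <- noisy$match_counts
  expect_true(all(counts["consensus"] <= counts[1:3]))

  # error rate 1 flips every decision: a lone true pair is never unanimous
  pair <- make_records(2, name = c("A", "A"), father_name = c("B", "B"),
                       mother_name = c("C", "C"))
  flipped <- emit_gold_review(pair, reviewer_error_rate = 1, seed = 3)
  expect_equal(length(linked_records(flipped$consensus)), 0)
})
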