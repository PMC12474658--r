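# minimal comparison spec over abstract fields, for EM tests on simulated
# comparison vectors
sim_spec <- function(fields, n_levels = 3L) {
  fs <- lapply(fields, function(f) list(field = f, type = "jw",
                                        n_levels = n_levels))
  names(fs) <- fields
  structure(list(fields = fs), class = "comparison_spec")
}

# draw comparison vectors from known m/u/lambda
sim_vectors <- function(n, m, u, lambda) {
  z <- runif(n) < lambda
  g <- sapply(names(m), function(f) {
    out <- integer(n)
    L <- length(m[[f]])
    out[z] <- sample.int(L, sum(z), TRUE, prob = m[[f]])
    out[!z] <- sample.int(L, sum(!z), TRUE, prob = u[[f]])
    out
  })
  colnames(g) <- names(m)
  list(gamma = g, z = z)
}

test_that("comparison vectors assign the declared agreement levels", {
  rec <- make_records(
    4,
    name = c("SOUKSAN", "SOUKSAN", "SOUKSAM", NA),
    mother_name = c("MANI", "MANI", "MANI", "MANI")
  )
  pairs <- data.frame(id1 = c("r001", "r001", "r001"),
                      id2 = c("r002", "r003", "r004"))
  g <- compare_pairs(rec, pairs, comparison_spec())
  expect_equal(unname(g[1, "name"]), 1L)            # exact
  jw <- jaro_winkler("SOUKSAN", "SOUKSAM")
  expect_true(jw >= 0.88)
  expect_equal(unname(g[2, "name"]), 2L)            # first JW band
  expect_true(is.na(g[3, "name"]))                  # missing side
  expect_equal(unname(g[, "mother_name"]), c(1L, 1L, 1L))
  expect_equal(unname(g[1, "sex"]), 1L)
})

test_that("match weights are log2 Bayes factors, additive, zero when absent", {
  params <- linkage_params(
    m = list(a = c(0.9, 0.1), b = c(0.8, 0.2)),
    u = list(a = c(0.1, 0.9), b = c(0.2, 0.8)),
    lambda = 0.1
  )
  g1 <- matrix(c(1L, NA), nrow = 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(match_weight(g1, params), log2(9), tolerance = 1e-6)
  g0 <- matrix(c(NA_integer_, NA), nrow = 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(match_weight(g0, params), 0)
  g2 <- matrix(c(1L, 1L), nrow = 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(match_weight(g2, params), log2(9) + log2(4), tolerance = 1e-6)
  # posterior identity
  w <- match_weight(g2, params)
  bf <- 2^w
  expect_equal(posterior_from_weight(w, 0.1), 0.1 * bf / (0.1 * bf + 0.9),
               tolerance = 1e-12)
})

test_that("lambda estimation follows the recall-adjusted proxy arithmetic", {
  # 10 blocks of 5 records -> 100 comparable pairs; in 7 blocks exactly one
  # pair agrees on all three names -> 7 proxy match pairs
  blocks <- lapply(1:10, function(b) {
    nm <- paste0("B", b, "N", 1:5)
    fa <- paste0("B", b, "F", 1:5)
    mo <- paste0("B", b, "M", 1:5)
    if (b <= 7) {
      nm[2] <- nm[1]; fa[2] <- fa[1]; mo[2] <- mo[1]
    }
    data.frame(record_id = paste0("b", b, "r", 1:5), name = nm,
               father_name = fa, mother_name = mo,
               dob = sprintf("2020-01-%02d", b), sex = "male",
               village = "BANA", stringsAsFactors = FALSE)
  })
  rec <- normalize_records(as_records(do.call(rbind, blocks)))
  lam <- estimate_lambda(rec, keys = c("dob", "village"), recall = 0.7)
  expect_equal(attr(lam, "comparable_pairs"), 100)
  expect_equal(attr(lam, "proxy_pairs"), 7)
  expect_equal(as.numeric(lam), 0.1, tolerance = 1e-12)
  expect_equal(as.numeric(estimate_lambda(rec, keys = c("dob", "village"),
                                          recall = 1)), 0.07,
               tolerance = 1e-12)
  expect_error(estimate_lambda(rec[c(1, 6, 11), ], keys = c("dob", "village")),
               "no comparable pairs")
})

test_that("lambda lands near the true comparable-pair match rate", {
  gen <- generate_registry(generator_config(n_records = 4000, seed = 21))
  rec <- normalize_records(gen$records)
  pairs <- attr(probabilistic_match(rec, pipeline_config()), "all_pairs")
  truth_keys <- with(partition_pairs(gen$truth), paste(id1, id2))
  true_rate <- mean(paste(pairs$id1, pairs$id2) %in% truth_keys)
  lam <- as.numeric(estimate_lambda(rec, recall = 0.7))
  expect_lt(abs(lam - true_rate) / true_rate, 0.30)
})

test_that("EM: stopping rule, monotone log-likelihood, degenerate input", {
  withr::local_seed(77)
  m <- list(f1 = c(0.9, 0.07, 0.03), f2 = c(0.85, 0.1, 0.05))
  u <- list(f1 = c(0.05, 0.15, 0.8), f2 = c(0.1, 0.2, 0.7))
  sim <- sim_vectors(5000, m, u, lambda = 0.15)
  spec <- sim_spec(c("f1", "f2"))
  init <- init_params(sim$gamma, spec, lambda = 0.1)

  one <- em_estimate(sim$gamma, init, tol = Inf)
  expect_equal(attr(one, "iterations"), 1)

  fit <- em_estimate(sim$gamma, init, tol = 1e-8, max_iter = 300)
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) >= -1e-8))

  same <- matrix(1L, nrow = 10, ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  expect_error(em_estimate(same, init), "unidentifiable")
})

test_that("EM started at the generating parameters barely moves", {
  withr::local_seed(78)
  m <- list(f1 = c(0.92, 0.05, 0.03), f2 = c(0.85, 0.1, 0.05),
            f3 = c(0.9, 0.07, 0.03))
  u <- list(f1 = c(0.05, 0.15, 0.8), f2 = c(0.1, 0.2, 0.7),
            f3 = c(0.08, 0.12, 0.8))
  sim <- sim_vectors(50000, m, u, lambda = 0.1)
  truth <- linkage_params(m, u, lambda = 0.1)
  fit <- em_estimate(sim$gamma, truth, tol = 1e-8, max_iter = 300)
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) >= -1e-8))
  move <- max(vapply(names(m), function(f) {
    max(abs(fit$m[[f]] - m[[f]]), abs(fit$u[[f]] - u[[f]]))
  }, numeric(1)))
  expect_lt(move, 0.01)
  # clamping invariant
  all_probs <- unlist(c(fit$m, fit$u))
  expect_true(all(all_probs >= 1e-6 & all_probs <= 1 - 1e-6))
})

test_that("predict_pairs respects threshold bounds and ordering", {
  rec <- make_records(
    4,
    name = c("SOUKSAN", "SOUKSAN", "DAONOY", "KHAMLA"),
    father_name = c("KHAM", "KHAM", "PHET", "SOM"),
    mother_name = c("MANI", "MANI", "NOY", "SI")
  )
  spec <- comparison_spec()
  params <- linkage_params(
    m = list(name = c(0.8, 0.1, 0.05, 0.05),
             father_name = c(0.8, 0.1, 0.05, 0.05),
             mother_name = c(0.8, 0.1, 0.05, 0.05),
             sex = c(0.95, 0.05)),
    u = list(name = c(0.05, 0.05, 0.1, 0.8),
             father_name = c(0.05, 0.05, 0.1, 0.8),
             mother_name = c(0.05, 0.05, 0.1, 0.8),
             sex = c(0.5, 0.5)),
    lambda = 0.1
  )
  all_p <- predict_pairs(rec, spec, params, threshold = 0)
  expect_equal(nrow(all_p), choose(4, 2))          # every within-block pair
  expect_true(all(diff(all_p$posterior) <= 0))     # sorted descending
  none <- predict_pairs(rec, spec, params, threshold = 1)
  expect_equal(nrow(none), 0)
  some <- predict_pairs(rec, spec, params, threshold = 0.5)
  expect_equal(nrow(some), 1)
  expect_equal(c(some$id1, some$id2), c("r001", "r002"))
})

test_that("blocked scoring equals brute-force all-pairs scoring (n <= 60)", {
  gen <- generate_registry(generator_config(n_records = 60, seed = 13))
  rec <- normalize_records(gen$records)
  df <- as.data.frame(rec)
  spec <- comparison_spec()
  params <- init_params(
    compare_pairs(df, data.frame(id1 = df$record_id[1],
                                 id2 = df$record_id[2]), spec),
    spec, lambda = 0.2
  )
  blocked <- predict_pairs(df, spec, params, threshold = 0,
                           keys = c("dob", "village"))
  # oracle: enumerate all pairs, keep those agreeing on the block key
  cmb <- utils::combn(sort(df$record_id), 2)
  keep <- vapply(seq_len(ncol(cmb)), function(k) {
    a <- df[df$record_id == cmb[1, k], ]
    b <- df[df$record_id == cmb[2, k], ]
    isTRUE(a$dob == b$dob) && isTRUE(a$village == b$village)
  }, logical(1))
  brute <- data.frame(id1 = cmb[1, keep], id2 = cmb[2, keep])
  expect_setequal(paste(blocked$id1, blocked$id2),
                  paste(brute$id1, brute$id2))
  if (nrow(brute) > 0) {
    w_brute <- match_weight(compare_pairs(df, brute, spec), params)
    key <- paste(brute$id1, brute$id2)
    got <- setNames(blocked$weight, paste(blocked$id1, blocked$id2))[key]
    expect_equal(unname(got), w_brute, tolerance = 1e-12)
  }
})

test_that("weight is symmetric in the pair order", {
  rec <- make_records(2, name = c("SOUKSAN", "SOUKSAM"),
                      father_name = c("KHAM", "KHAN"))
  spec <- comparison_spec()
  params <- init_params(compare_pairs(rec, data.frame(id1 = "r001",
                                                      id2 = "r002"), spec),
                        spec, 0.1)
  g_ab <- compare_pairs(rec, data.frame(id1 = "r001", id2 = "r002"), spec)
  g_ba <- compare_pairs(rec, data.frame(id1 = "r002", id2 = "r001"), spec)
  expect_equal(match_weight(g_ab, params), match_weight(g_ba, params))
})

test_that("probabilistic matching closes links transitively", {
  rec <- make_records(
    4,
    name = c("SOUKSAN", "SOUKSAN", "SOUKSAN", "ZZZZZZ"),
    father_name = c("KHAM", "KHAM", "KHAM", "AAA"),
    mother_name = c("MANI", "MANI", "MANI", "BBB")
  )
  cfg <- pipeline_config(threshold = 0.5)
  p <- probabilistic_match(rec, cfg, lambda = 0.3)
  expect_true(same_partition(p, partition(sprintf("r%03d", 1:4),
                                          c("x", "x", "x", "y"))))
  # no comparable pairs at all -> all singletons
  alone <- make_records(4, dob = sprintf("2020-02-%02d", 1:4))
  p1 <- probabilistic_match(alone, cfg)
  expect_equal(length(linked_records(p1)), 0)
})

test_that("Jaro-Winkler levels beat exact-only comparison under typos", {
  cfg_gen <- generator_config(n_records = 1500, seed = 31,
                              corrupt_name_rate = 0.6,
                              corrupt_parent_rate = 0.5)
  gen <- generate_registry(cfg_gen)
  rec <- normalize_records(gen$records)
  truth_keys <- with(partition_pairs(gen$truth), paste(id1, id2))
  pair_recall <- function(spec) {
    p <- probabilistic_match(rec, pipeline_config(), spec = spec)
    linked <- attr(p, "pairs")
    mean(truth_keys %in% paste(linked$id1, linked$id2))
  }
  r_jw <- pair_recall(comparison_spec())
  r_exact <- pair_recall(comparison_spec(
    string_fields = character(0),
    exact_fields = c("name", "father_name", "mother_name", "sex")
  ))
  expect_gt(r_jw, r_exact)
})
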