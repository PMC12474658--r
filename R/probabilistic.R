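#' Score within-block pairs and keep those above a posterior threshold
#'
#' @param records normalized records.
#' @param spec a \code{\link{comparison_spec}}.
#' @param params estimated \code{\link{linkage_params}}.
#' @param threshold posterior match probability cut-off in [0, 1].
#' @param keys probabilistic blocking keys.
#' @return Data frame (id1, id2, weight, posterior), sorted by descending
#'   posterior then ascending id pair; only pairs with posterior >=
#'   threshold. Attribute \code{all_pairs} holds every scored within-block
#'   pair (for threshold sweeps).
#' @export
predict_pairs <- function(records, spec, params, threshold = 0.5,
                          keys = c("dob", "village")) {
  df <- as.data.frame(records)
  pairs <- block_pairs(block_records(df, keys))
  if (nrow(pairs) == 0) {
    out <- data.frame(id1 = character(), id2 = character(),
                      weight = numeric(), posterior = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "all_pairs") <- out
    return(out)
  }
  gamma <- compare_pairs(df, pairs, spec)
  w <- match_weight(gamma, params)
  post <- posterior_from_weight(w, params$lambda)
  scored <- data.frame(id1 = pairs$id1, id2 = pairs$id2,
                       weight = w, posterior = post,
                       stringsAsFactors = FALSE)
  scored <- scored[order(-scored$posterior, scored$id1, scored$id2), , drop = FALSE]
  rownames(scored) <- NULL
  out <- scored[scored$posterior >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_pairs") <- scored
  out
}

#' Probabilistic (Fellegi-Sunter) matching
#'
#' Full probabilistic pipeline: block on the configured keys, build
#' Jaro-Winkler comparison vectors for every within-block pair, estimate the
#' prior match probability from the deterministic proxy at the configured
#' recall, fit m/u probabilities by EM, score pairs, keep those above the
#' posterior threshold and close them transitively into clusters.
#'
#' @param records normalized records.
#' @param config a \code{\link{pipeline_config}}.
#' @param spec optional \code{\link{comparison_spec}}; by default built from
#'   the config's Jaro-Winkler thresholds, adding exact date-of-birth
#'   comparison when \code{dob} is not a blocking key.
#' @param lambda optional prior match probability; when \code{NULL} it is
#'   estimated by \code{\link{estimate_lambda}} on \code{records}.
#' @param fix_lambda keep the prior fixed at its recall-adjusted estimate
#'   (the default) instead of letting EM re-estimate it.
#' @return A \code{\link{partition}} with attributes \code{pairs} (the linked
#'   scored pairs), \code{all_pairs} (every scored pair), \code{params} and
#'   \code{lambda}.
#' @export
probabilistic_match <- function(records, config = pipeline_config(),
                                spec = NULL, lambda = NULL,
                                fix_lambda = TRUE) {
  df <- as.data.frame(records)
  if (is.null(spec)) {
    exact_fields <- "sex"
    if (!"dob" %in% config$prob_keys) exact_fields <- c("sex", "dob")
    spec <- comparison_spec(jw_thresholds = config$jw_thresholds,
                            exact_fields = exact_fields)
  }
  pairs <- block_pairs(block_records(df, config$prob_keys))
  if (nrow(pairs) == 0) {
    p <- partition_from_links(df$record_id, pairs)
    attr(p, "pairs") <- pairs
    attr(p, "all_pairs") <- pairs
    return(p)
  }
  if (is.null(lambda)) {
    lambda <- estimate_lambda(df, rule_table(), keys = config$prob_keys,
                              recall = config$recall)
  }
  gamma <- compare_pairs(df, pairs, spec)
  init <- init_params(gamma, spec, lambda = as.numeric(lambda))
  params <- em_estimate(gamma, init, tol = config$em_tol,
                        max_iter = config$em_max_iter,
                        fix_lambda = fix_lambda)
  linked <- predict_pairs(df, spec, params, threshold = config$threshold,
                          keys = config$prob_keys)
  p <- partition_from_links(df$record_id, linked)
  attr(p, "pairs") <- linked
  attr(p, "all_pairs") <- attr(linked, "all_pairs")
  attr(p, "params") <- params
  attr(p, "lambda") <- lambda
  p
}

#' Sensitivity sweep over the proxy recall parameter
#'
#' Re-runs the probabilistic matcher for each value of the assumed proxy
#' recall (which rescales the prior match probability) and evaluates each run
#' against a gold partition, showing how sensitive the results are to the
#' prior.
#'
#' @param records normalized records.
#' @param gold gold-standard \code{\link{partition}}.
#' @param recalls recall values to sweep.
#' @param config base \code{\link{pipeline_config}}.
#' @return Data frame (recall, precision, recall_metric, f1).
#' @export
recall_sweep <- function(records, gold, recalls = seq(0.65, 0.95, by = 0.05),
                         config = pipeline_config()) {
  rows <- lapply(recalls, function(r) {
    cfg <- config
    cfg$recall <- r
    p <- probabilistic_match(records, cfg)
    ms <- metrics(record_confusion(p, gold))
    data.frame(recall = r, precision = ms$precision,
               recall_metric = ms$recall, f1 = ms$f1)
  })
  do.call(rbind, rows)
}
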