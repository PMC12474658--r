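PROB_EPS <- 1e-6

#' Fellegi-Sunter linkage parameters
#'
#' Container for the per-field, per-level match probabilities \code{m}
#' (probability of observing an agreement level given a true match) and
#' non-match probabilities \code{u} (given a true non-match), plus the prior
#' match probability \code{lambda} of a comparable pair. All probabilities
#' are clamped to [1e-6, 1 - 1e-6] and each field's levels sum to 1.
#'
#' @param m,u named lists (one numeric vector per field, one entry per level).
#' @param lambda prior match probability in (0, 1).
#' @return A \code{linkage_params} object.
#' @export
linkage_params <- function(m, u, lambda) {
  stopifnot(identical(names(m), names(u)), length(lambda) == 1,
            lambda > 0, lambda < 1)
  norm <- function(v) {
    v <- pmin(pmax(v, PROB_EPS), 1 - PROB_EPS)
    v / sum(v)
  }
  m <- lapply(m, norm)
  u <- lapply(u, norm)
  for (f in names(m)) {
    if (length(m[[f]]) != length(u[[f]])) {
      stop("m and u disagree on level count for field ", f)
    }
  }
  structure(list(m = m, u = u, lambda = as.numeric(lambda)),
            class = "linkage_params")
}

#' @export
print.linkage_params <- function(x, ...) {
  cat(sprintf("<linkage_params> lambda = %.4g\n", x$lambda))
  for (f in names(x$m)) {
    cat(sprintf("  %s: m = (%s), u = (%s)\n", f,
                paste(sprintf("%.3f", x$m[[f]]), collapse = ", "),
                paste(sprintf("%.3f", x$u[[f]]), collapse = ", ")))
  }
  invisible(x)
}

#' Default EM initialization
#'
#' \code{m} puts 0.9 on the most-agreeing level and spreads the rest
#' uniformly; \code{u} is the empirical level frequency over all comparison
#' vectors (a good approximation because true matches are rare among
#' comparable pairs).
#'
#' @param gamma integer level matrix from \code{\link{compare_pairs}}.
#' @param spec the \code{\link{comparison_spec}} that produced it.
#' @param lambda initial prior match probability.
#' @return A \code{\link{linkage_params}}.
#' @export
init_params <- function(gamma, spec, lambda = 0.1) {
  m <- list(); u <- list()
  for (fs in spec$fields) {
    L <- fs$n_levels
    mv <- rep(0.1 / max(L - 1, 1), L)
    mv[1] <- if (L > 1) 0.9 else 1
    g <- gamma[, fs$field]
    g <- g[!is.na(g)]
    freq <- tabulate(g, nbins = L) + 0.5  # smoothed
    m[[fs$field]] <- mv
    u[[fs$field]] <- freq / sum(freq)
  }
  linkage_params(m, u, lambda)
}

# log P(gamma_i | class) for every pair; NA levels contribute 0
class_loglik <- function(gamma, probs) {
  ll <- numeric(nrow(gamma))
  for (f in names(probs)) {
    g <- gamma[, f]
    ok <- !is.na(g)
    ll[ok] <- ll[ok] + log(probs[[f]][g[ok]])
  }
  ll
}

#' Estimate m/u probabilities by expectation-maximization
#'
#' Standard two-class latent-variable EM over conditionally independent
#' fields: the E step computes each pair's posterior match probability under
#' the current parameters, the M step re-estimates \code{m}, \code{u} and
#' \code{lambda} from the posteriors. Levels recorded as \code{NA} (field
#' unavailable) are excluded from the field likelihood (missing at random).
#' The observed-data log-likelihood is non-decreasing across iterations;
#' iteration stops when its increase falls below \code{tol} or after
#' \code{max_iter} iterations.
#'
#' @param gamma integer level matrix from \code{\link{compare_pairs}}.
#' @param init initial \code{\link{linkage_params}}.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param fix_lambda keep \code{lambda} at its initial value instead of
#'   re-estimating it.
#' @return A \code{\link{linkage_params}} with attributes \code{loglik}
#'   (trace of the observed-data log-likelihood, one value per E step) and
#'   \code{iterations} (number of parameter updates performed; \code{tol =
#'   Inf} gives exactly one).
#' @export
em_estimate <- function(gamma, init, tol = 1e-6, max_iter = 100,
                        fix_lambda = FALSE) {
  stopifnot(inherits(init, "linkage_params"), nrow(gamma) >= 2)
  if (nrow(unique(gamma)) < 2) {
    stop("EM unidentifiable: all comparison vectors are identical")
  }
  m <- init$m; u <- init$u; lambda <- init$lambda
  fields <- names(m)
  trace <- numeric(0)
  ll_old <- -Inf
  updates <- 0
  clamp_norm <- function(v) {
    v <- pmin(pmax(v, PROB_EPS), 1 - PROB_EPS)
    v / sum(v)
  }
  repeat {
    # E step
    la <- log(lambda) + class_loglik(gamma, m)
    lb <- log1p(-lambda) + class_loglik(gamma, u)
    mx <- pmax(la, lb)
    ll <- sum(mx + log(exp(la - mx) + exp(lb - mx)))
    trace <- c(trace, ll)
    p <- 1 / (1 + exp(lb - la))
    if (abs(ll - ll_old) < tol || updates >= max_iter) break
    ll_old <- ll
    # M step
    for (f in fields) {
      g <- gamma[, f]
      ok <- !is.na(g)
      L <- length(m[[f]])
      wm <- vapply(seq_len(L), function(l) sum(p[ok][g[ok] == l]), numeric(1))
      wu <- vapply(seq_len(L), function(l) sum((1 - p[ok])[g[ok] == l]), numeric(1))
      m[[f]] <- clamp_norm(wm / max(sum(wm), .Machine$double.eps))
      u[[f]] <- clamp_norm(wu / max(sum(wu), .Machine$double.eps))
    }
    if (!fix_lambda) {
      lambda <- min(max(mean(p), PROB_EPS), 1 - PROB_EPS)
    }
    updates <- updates + 1
  }
  out <- linkage_params(m, u, lambda)
  attr(out, "loglik") <- trace
  attr(out, "iterations") <- updates
  out
}

#' Estimate the prior match probability lambda
#'
#' Uses the deterministic rule table as a proxy labeller: within the
#' probabilistic blocking, the number of rule-matched pairs divided by an
#' assumed recall \code{r} of that proxy estimates the number of true match
#' pairs, and dividing by the total number of comparable pairs gives
#' \code{lambda}. Sweeping \code{r} supports sensitivity analysis of the
#' prior.
#'
#' @param records normalized records.
#' @param proxy_rules \code{\link{rule_table}} used as the proxy labeller.
#' @param keys probabilistic blocking keys.
#' @param recall assumed recall of the proxy, in (0, 1].
#' @return \code{lambda} in (1e-6, 1 - 1e-6), with attributes
#'   \code{proxy_pairs} and \code{comparable_pairs}.
#' @export
estimate_lambda <- function(records, proxy_rules = rule_table(),
                            keys = c("dob", "village"), recall = 0.7) {
  stopifnot(recall > 0, recall <= 1)
  df <- as.data.frame(records)
  pairs <- block_pairs(block_records(df, keys))
  n_pairs <- nrow(pairs)
  if (n_pairs == 0) stop("no comparable pairs under blocking")
  st <- pair_states(df, pairs)
  i <- match(pairs$id1, df$record_id)
  j <- match(pairs$id2, df$record_id)
  sex_ok <- field_state(df$sex[i], df$sex[j]) != "NONMATCH"
  proxy <- sex_ok & classify_triple(st$name_state, st$father_state,
                                    st$mother_state, proxy_rules)
  lambda <- min(max((sum(proxy) / recall) / n_pairs, PROB_EPS), 1 - PROB_EPS)
  attr(lambda, "proxy_pairs") <- sum(proxy)
  attr(lambda, "comparable_pairs") <- n_pairs
  lambda
}

#' Fellegi-Sunter match weight
#'
#' The log2 Bayes factor of a comparison vector: the sum over fields of
#' \code{log2(m[level] / u[level])}, with unavailable fields contributing 0.
#'
#' @param gamma integer level matrix (pairs x fields).
#' @param params \code{\link{linkage_params}}.
#' @return Numeric vector of weights in bits.
#' @export
match_weight <- function(gamma, params) {
  stopifnot(inherits(params, "linkage_params"))
  w <- numeric(nrow(gamma))
  for (f in names(params$m)) {
    g <- gamma[, f]
    ok <- !is.na(g)
    w[ok] <- w[ok] + log2(params$m[[f]][g[ok]] / params$u[[f]][g[ok]])
  }
  w
}

#' Posterior match probability from a match weight
#'
#' \code{posterior = lambda * 2^w / (lambda * 2^w + 1 - lambda)}.
#'
#' @param w match weight in bits.
#' @param lambda prior match probability.
#' @return Posterior probability in [0, 1].
#' @export
posterior_from_weight <- function(w, lambda) {
  # on the log-odds scale for numerical stability
  lo <- log(lambda) - log1p(-lambda) + w * log(2)
  stats::plogis(lo)
}
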