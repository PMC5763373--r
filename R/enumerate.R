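#' Exact posterior over state vectors by brute-force enumeration
#'
#' Sums the collapsed allocation mass over every admissible allocation of
#' every read in both samples, for every valid state vector, yielding the
#' exact posterior `P(c | x, y)` on tiny instances. Used as the independent
#' oracle against which both MCMC samplers are validated.
#'
#' Allocations factorise per sample given the counts, so allocations are
#' aggregated into unique count vectors with alignment-density weights before
#' the state-dependent mass is applied.
#'
#' @param x,y matched [alignments()] tables.
#' @param hyper a [hyperparams()].
#' @param pi fixed prior probability of differential expression.
#' @return an object of class `jointde_enum`: list with `states` (tibble with
#'   columns `code`, `c_plus`, `prob` and list-column `c`) and `q` (exact
#'   per-transcript posterior DE probabilities).
#' @export
exact_state_posterior <- function(x, y, hyper = NULL, pi = 0.5) {
  check_matched_pair(x, y)
  cx <- as_align_csr(x)
  cy <- as_align_csr(y)
  K <- cx$K
  if (is.null(hyper)) hyper <- hyperparams(K)
  r <- length(cx$ptr) - 1L
  s <- length(cy$ptr) - 1L
  if (K > 4 || r + s > 8)
    abort("exact enumeration is restricted to K <= 4 and r + s <= 8 reads")

  aggregate_counts <- function(csr, n) {
    cand <- lapply(seq_len(n), function(i)
      (csr$ptr[i] + 1):csr$ptr[i + 1])
    grid <- as.matrix(expand.grid(cand))
    counts <- matrix(0L, nrow(grid), K)
    logf <- numeric(nrow(grid))
    for (i in seq_len(n)) {
      kk <- csr$idx[grid[, i]] + 1L
      logf <- logf + log(csr$f[grid[, i]])
      counts[cbind(seq_len(nrow(grid)), kk)] <-
        counts[cbind(seq_len(nrow(grid)), kk)] + 1L
    }
    key <- apply(counts, 1, paste, collapse = ",")
    agg <- rowsum(exp(logf), key)
    ucounts <- counts[match(rownames(agg), key), , drop = FALSE]
    list(counts = ucounts, weight = as.numeric(agg))
  }
  ax <- aggregate_counts(cx, r)
  ay <- aggregate_counts(cy, s)

  states <- enumerate_states(K)
  logw <- vapply(states, function(st) {
    lm <- matrix(0, nrow(ax$counts), nrow(ay$counts))
    for (i in seq_len(nrow(ax$counts)))
      for (j in seq_len(nrow(ay$counts)))
        lm[i, j] <- collapsed_log_mass(ax$counts[i, ], ay$counts[j, ],
                                       st, hyper) +
          log(ax$weight[i]) + log(ay$weight[j])
    state_prior_logpmf(st, pi) + log_sum_exp(as.numeric(lm))
  }, numeric(1))
  prob <- exp(logw - log_sum_exp(logw))
  cvecs <- lapply(states, `[[`, "c")
  q <- colSums(do.call(rbind, cvecs) * prob)
  structure(list(
    states = tibble(
      code = vapply(cvecs, state_code, numeric(1)),
      c = cvecs,
      c_plus = vapply(states, `[[`, integer(1), "c_plus"),
      prob = prob),
    q = setNames(q, transcript_ids(x)),
    pi = pi, K = K), class = "jointde_enum")
}

#' @export
print.jointde_enum <- function(x, ...) {
  cat("<jointde_enum> exact posterior over", nrow(x$states),
      "valid states, K =", x$K, "\n")
  print(x$states[order(-x$states$prob), c("code", "c_plus", "prob")])
  invisible(x)
}

#' @export
tidy.jointde_enum <- function(x, ...) x$states

#' Total-variation distance between two distributions over state codes
#'
#' @param p,q named numeric vectors of probabilities (names = state codes);
#'   missing codes count as zero mass.
#' @return total variation distance in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  codes <- union(names(p), names(q))
  pv <- ifelse(codes %in% names(p), p[codes], 0)
  qv <- ifelse(codes %in% names(q), q[codes], 0)
  pv[is.na(pv)] <- 0; qv[is.na(qv)] <- 0
  sum(abs(pv - qv)) / 2
}
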