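#' Decision rules on posterior probabilities of differential expression
#'
#' Three ways to turn per-transcript posterior DE probabilities `q_k` into a
#' decision list:
#'
#' * `call_conservative()`: call `q_k > 1 - alpha`. Controls the Bayesian FDR
#'   conservatively; can have low power.
#' * `call_fdr()`: sort `q` descending, form cumulative means
#'   `G_k = (1/k) * sum_{j<=k} (1 - q_j)`, and reject the top
#'   `g = max{k : G_k <= alpha}`. Controls the expected FDR at `alpha`
#'   exactly, since the expected FDR of the rejection set is `G_g`.
#' * `call_loss()`: call `q_k > cost / (cost + 1)`, the optimal cutoff under
#'   the loss `cost * FD + FN` (posterior expected false discoveries and
#'   false negatives).
#'
#' Ties in `q` are broken by original order (stable sort), so decisions are
#' deterministic.
#'
#' @param q numeric vector of posterior DE probabilities in `[0, 1]`.
#' @param alpha target FDR level in (0, 1).
#' @param cost relative cost of a false discovery (`> 0`).
#' @param transcript optional identifiers carried into the output.
#' @return a tibble of class `jointde_calls` with columns `transcript`
#'   (if supplied), `q`, `G` (cumulative mean in the rank order, `call_fdr`
#'   only), `d` (0/1 decision); attributes `rule`, `level`, `D` (number of
#'   calls) and `expected_fdr`.
#' @examples
#' call_fdr(c(0.99, 0.97, 0.90), alpha = 0.05)
#' call_loss(c(0.85, 0.5), cost = 4)
#' @name calling
NULL

new_calls <- function(q, d, rule, level, G = NULL, transcript = NULL) {
  out <- tibble(q = q, d = as.integer(d))
  if (!is.null(G)) out$G <- G
  if (!is.null(transcript)) out <- dplyr::bind_cols(tibble(transcript = transcript), out)
  D <- sum(out$d)
  efdr <- expected_fdr(q, out$d)
  structure(out, rule = rule, level = level, D = D, expected_fdr = efdr,
            class = c("jointde_calls", class(out)))
}

#' @rdname calling
#' @export
call_conservative <- function(q, alpha = 0.05, transcript = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  check_q(q)
  new_calls(q, q > 1 - alpha, "conservative", alpha, transcript = transcript)
}

#' @rdname calling
#' @export
call_fdr <- function(q, alpha = 0.05, transcript = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  check_q(q)
  o <- order_desc_stable(q)
  G_sorted <- cumsum(1 - q[o]) / seq_along(q)
  g <- if (any(G_sorted <= alpha)) max(which(G_sorted <= alpha)) else 0L
  d <- integer(length(q))
  if (g > 0) d[o[seq_len(g)]] <- 1L
  G <- numeric(length(q))
  G[o] <- G_sorted
  new_calls(q, d, "fdr", alpha, G = G, transcript = transcript)
}

#' @rdname calling
#' @export
call_loss <- function(q, cost = 4, transcript = NULL) {
  stopifnot(cost > 0)
  check_q(q)
  new_calls(q, q > cost / (cost + 1), "loss", cost, transcript = transcript)
}

check_q <- function(q) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    abort("`q` must contain probabilities in [0, 1]")
  invisible(q)
}

#' Posterior expected false discovery rate of a decision vector
#'
#' `E(FDR | data) = sum_k (1 - q_k) d_k / D` with `D = sum_k d_k`. With no
#' rejections the FDR is undefined; a zero flagged with attribute
#' `undefined = TRUE` is returned.
#'
#' @param q posterior DE probabilities.
#' @param d 0/1 decision vector.
#' @return the expected FDR (scalar).
#' @export
expected_fdr <- function(q, d) {
  stopifnot(length(q) == length(d))
  D <- sum(d)
  if (D == 0) return(structure(0, undefined = TRUE))
  sum((1 - q) * d) / D
}

#' @export
print.jointde_calls <- function(x, ...) {
  cat("<jointde_calls> rule = ", attr(x, "rule"),
      " (", attr(x, "level"), "), calls = ", attr(x, "D"),
      ", E(FDR|data) = ", signif(attr(x, "expected_fdr"), 4), "\n", sep = "")
  NextMethod()
}
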