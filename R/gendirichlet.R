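#' Generalized Dirichlet (Connor--Mosimann) random deviates
#'
#' Samples via the exact stick-breaking construction: independent
#' `z_k ~ Beta(lam_k, beta_k)` for `k = 1, ..., K-1`, then
#' `u_k = z_k * prod_{j<k} (1 - z_j)` with the remainder as `u_K`.
#'
#' When `beta_k = lam_{k+1} + beta_{k+1}` (with `beta_{K-1} = lam_K`) the
#' distribution reduces to `Dirichlet(lam_1, ..., lam_{K-1}, lam_K)`.
#'
#' @param n number of draws.
#' @param lam,beta positive shape vectors of equal length `K - 1`.
#' @return an `n x K` matrix of simplex rows.
#' @examples
#' set.seed(1)
#' colMeans(rgdirichlet(1000, c(2, 1), c(3, 1)))
#' @export
rgdirichlet <- function(n, lam, beta) {
  stopifnot(length(lam) == length(beta))
  if (any(lam <= 0) || any(beta <= 0))
    abort("`lam` and `beta` must be strictly positive")
  Km1 <- length(lam)
  z <- matrix(stats::rbeta(n * Km1, rep(lam, each = n), rep(beta, each = n)),
              nrow = n)
  out <- matrix(0, n, Km1 + 1)
  remain <- rep(1, n)
  for (k in seq_len(Km1)) {
    out[, k] <- z[, k] * remain
    remain <- remain * (1 - z[, k])
  }
  out[, Km1 + 1] <- remain
  out
}

#' Generalized Dirichlet log-density
#'
#' Connor--Mosimann density on the `K`-simplex,
#' `f(u) = prod_k u_k^{lam_k - 1} T_k^{d_k} / B(lam_k, beta_k)` with
#' `T_k = 1 - u_1 - ... - u_k`, `d_k = beta_k - lam_{k+1} - beta_{k+1}` for
#' `k < K - 1` and `d_{K-1} = beta_{K-1} - 1`. Points on the boundary of the
#' simplex return `-Inf`.
#'
#' @param x simplex vector of length `K`, or a matrix with simplex rows.
#' @param lam,beta shape vectors of length `K - 1`.
#' @param log return log-density (default `TRUE`).
#' @return numeric vector of (log-)densities.
#' @export
dgdirichlet <- function(x, lam, beta, log = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  Km1 <- length(lam)
  stopifnot(length(beta) == Km1, ncol(x) == Km1 + 1)
  d <- c(beta[-Km1] - lam[-1] - beta[-1], beta[Km1] - 1)
  lognorm <- sum(lbeta(lam, beta))
  out <- vapply(seq_len(nrow(x)), function(i) {
    u <- x[i, ]
    if (any(u <= 0) || abs(sum(u) - 1) > 1e-9) return(-Inf)
    Tk <- 1 - cumsum(u[seq_len(Km1)])
    # T_{K-1} equals u_K, strictly positive in the interior
    sum((lam - 1) * log(u[seq_len(Km1)])) + sum(d * log(Tk)) - lognorm
  }, numeric(1))
  if (log) out else exp(out)
}

#' Full-conditional parameters of the free abundance parameters
#'
#' Given allocation counts in both samples and the state vector, the
#' constant-dimension simplex `u` has a generalized Dirichlet full
#' conditional and the variable-dimension simplex `v` a Dirichlet one.
#' Writing counts in the canonical (dead-then-alive) order,
#' `t_k = counts_x[tau_k]` and `m_k = counts_y[tau_k]`, and `kstar = K - c+`:
#'
#' * `lam_k = alpha_k + t_k + m_k` for `k <= kstar`, else `alpha_k + t_k`;
#' * `beta_k = sum_{j>k} (alpha_j + t_j + m_j)` for `k <= kstar`, else
#'   `sum_{j>k} (alpha_j + t_j)`;
#' * `v ~ Dirichlet(gamma_l + m_{kstar+l})`, `l = 1, ..., c+`.
#'
#' When `c+ = 0` the generalized Dirichlet collapses to
#' `Dirichlet(alpha_k + t_k + m_k)` (both samples pooled); when `c+ = K` the
#' posteriors of `u` and `v` are two independent Dirichlets.
#'
#' @param counts_x,counts_y non-negative integer count vectors of length `K`
#'   (per-transcript allocation tallies in each sample).
#' @param state a [state_vector()].
#' @param hyper a [hyperparams()].
#' @return list with `lam`, `beta` (length `K - 1`, parameters of `u`) and
#'   `gamma_v` (length `c_plus`, Dirichlet parameters of `v`).
#' @export
posterior_free_params <- function(counts_x, counts_y, state,
                                  hyper = hyperparams(state$K)) {
  stopifnot(inherits(state, "state_vector"), inherits(hyper, "jointde_hyper"))
  K <- state$K
  if (length(counts_x) != K || length(counts_y) != K)
    abort("count vectors must have length K")
  kstar <- K - state$c_plus
  t_tau <- counts_x[state$tau]
  m_tau <- counts_y[state$tau]
  a <- hyper$alpha
  pooled <- a + t_tau + m_tau      # alpha_k + t_k + m_k in tau order
  xonly <- a + t_tau
  lam <- ifelse(seq_len(K) <= kstar, pooled, xonly)[seq_len(K - 1)]
  # reverse cumulative sums for the two branches
  rc_pooled <- rev(cumsum(rev(pooled)))
  rc_xonly <- rev(cumsum(rev(xonly)))
  beta <- vapply(seq_len(K - 1), function(k) {
    if (k <= kstar) rc_pooled[k + 1] else rc_xonly[k + 1]
  }, numeric(1))
  gamma_v <- if (state$c_plus > 0)
    hyper$gamma[seq_len(state$c_plus)] + m_tau[kstar + seq_len(state$c_plus)]
  else numeric(0)
  list(lam = lam, beta = beta, gamma_v = gamma_v)
}

#' Draw Dirichlet deviates
#'
#' Gamma-ratio construction; used for the variable-dimension simplex `v` and
#' in the synthetic-data generator.
#'
#' @param n number of draws.
#' @param alpha positive shape vector.
#' @return an `n x length(alpha)` matrix of simplex rows.
#' @export
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
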