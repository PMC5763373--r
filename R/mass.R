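#' Collapsed log-mass of the allocations given the state vector
#'
#' Log of the marginal (unnormalised) mass of the allocation count vectors
#' after integrating the free abundance parameters `u` and `v` out against
#' their Dirichlet priors. With `at_k` the prior parameter of transcript `k`
#' (`alpha` indexed through the canonical permutation) and `gl_k` the `v`
#' prior parameter attached to alive transcript `k`:
#'
#' \deqn{\log \Gamma\{\textstyle\sum_{C_1}(at_k + sx_k + sz_k)\}
#'   - \log \Gamma\{\sum_{C_1}(at_k + sx_k)\}
#'   - \log \Gamma\{\sum_{C_1}(gl_k + sz_k)\}
#'   + \sum_{C_1}[\log\Gamma(at_k + sx_k) + \log\Gamma(gl_k + sz_k)]
#'   + \sum_{C_0}\log\Gamma(at_k + sx_k + sz_k)
#'   + \log\Gamma(\textstyle\sum_{l \le c_+}\gamma_l)
#'   - \sum_{l \le c_+}\log\Gamma(\gamma_l).}
#'
#' The last two terms are the normaliser of the prior on `v`; they are
#' constant in the allocations but depend on the state dimension, so they are
#' required when comparing masses across state vectors (block updates of `c`
#' and exact enumeration). Terms constant in both allocations and state
#' (read-level alignment densities, `\Gamma(\sum\alpha + r + s)` and the `u`
#' prior normaliser) are dropped.
#'
#' When `c+ = 0` the expression reduces to the pooled-sample Dirichlet
#' marginal `sum_k logGamma(at_k + sx_k + sz_k)`; when `c+ = K` it reduces to
#' two independent Dirichlet-multinomial marginals (up to constants).
#'
#' @inheritParams posterior_free_params
#' @return a finite log mass.
#' @export
collapsed_log_mass <- function(counts_x, counts_y, state,
                               hyper = hyperparams(state$K)) {
  stopifnot(inherits(state, "state_vector"), inherits(hyper, "jointde_hyper"))
  K <- state$K
  if (length(counts_x) != K || length(counts_y) != K)
    abort("count vectors must have length K")
  at <- hyper$alpha[state$tau_inv]          # prior parameter of transcript k
  cp <- state$c_plus
  dead <- state$C0
  out <- sum(lgamma(at[dead] + counts_x[dead] + counts_y[dead]))
  if (cp > 0) {
    alive <- state$C1
    gl <- hyper$gamma[seq_len(cp)]          # in alive (ascending) order
    ax <- at[alive] + counts_x[alive]
    gz <- gl + counts_y[alive]
    out <- out +
      lgamma(sum(ax) + sum(counts_y[alive])) - lgamma(sum(ax)) -
      lgamma(sum(gz)) + sum(lgamma(ax)) + sum(lgamma(gz)) +
      lgamma(sum(gl)) - sum(lgamma(gl))
  }
  out
}
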