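#' State vector of differential expression indicators
#'
#' A state vector `c` flags each transcript as equally expressed between the
#' two samples (`c_k = 0`, the "dead" set) or differentially expressed
#' (`c_k = 1`, the "alive" set). Because both abundance vectors live on a
#' simplex, a single abundance cannot change alone: the model excludes states
#' with exactly one alive transcript (`sum(c) != 1`).
#'
#' The canonical permutation `tau` lists the dead indices in ascending order
#' followed by the alive indices in ascending order; `tau_inv` is its inverse.
#' For `c = (1,0,0,1,0,1)`: `C0 = {2,3,5}`, `C1 = {1,4,6}`,
#' `tau = (2,3,5,1,4,6)` and `tau_inv = (4,1,2,5,3,6)`.
#'
#' @param c binary vector of length `K >= 2`.
#' @return an object of class `state_vector` with elements `c`, `K`,
#'   `c_plus`, `C0`, `C1`, `tau`, `tau_inv`.
#' @examples
#' s <- state_vector(c(1, 0, 0, 1, 0, 1))
#' s$tau
#' @export
state_vector <- function(c) {
  c <- as.integer(c)
  K <- length(c)
  if (K < 2) abort("state vector must have length K >= 2")
  if (anyNA(c) || any(c != 0L & c != 1L)) abort("state vector must be binary")
  c_plus <- sum(c)
  if (c_plus == 1L)
    abort("invalid state: exactly one differentially expressed transcript (c+ = 1) is not allowed")
  C0 <- which(c == 0L)
  C1 <- which(c == 1L)
  tau <- c(C0, C1)
  tau_inv <- integer(K)
  tau_inv[tau] <- seq_len(K)
  structure(list(c = c, K = K, c_plus = c_plus, C0 = C0, C1 = C1,
                 tau = tau, tau_inv = tau_inv),
            class = "state_vector")
}

#' @export
print.state_vector <- function(x, ...) {
  cat("<state_vector> K =", x$K, " c+ =", x$c_plus, "\n c  =",
      paste(x$c, collapse = ""), "\n")
  invisible(x)
}

#' Map free parameters (u, v) to the abundance pair (theta, w)
#'
#' The pair of abundance simplexes is a deterministic bijection of the free
#' parameters given the state: `theta` is `u` reordered by the inverse of the
#' canonical permutation, the dead coordinates of `w` equal those of `theta`,
#' and the alive coordinates of `w` are `v` scaled by the total alive mass of
#' `theta` (so the alive mass is conserved between samples).
#'
#' @param state a [state_vector()].
#' @param u simplex of length `K`.
#' @param v simplex of length `state$c_plus` (or `numeric(0)` when
#'   `c_plus = 0`).
#' @return list with components `theta` and `w`, both simplexes of length `K`.
#' @examples
#' st <- state_vector(c(1, 0, 0, 1, 0, 1))
#' u <- rep(1 / 6, 6); v <- c(0.5, 0.25, 0.25)
#' free_to_weights(st, u, v)
#' @export
free_to_weights <- function(state, u, v = numeric(0)) {
  stopifnot(inherits(state, "state_vector"))
  if (length(u) != state$K) abort("`u` must have length K")
  if (length(v) != state$c_plus)
    abort("`v` must have length c_plus")
  check_simplex(u, arg = "u")
  if (state$c_plus > 0) check_simplex(v, arg = "v")
  theta <- u[state$tau_inv]
  w <- theta
  if (state$c_plus > 0) {
    S <- sum(theta[state$C1])
    w[state$C1] <- v * S
  }
  list(theta = theta, w = w)
}

#' Recover the free parameters (u, v) from (theta, w)
#'
#' Inverse of [free_to_weights()]; exact up to floating point.
#'
#' @inheritParams free_to_weights
#' @param theta,w abundance simplexes of length `K` consistent with `state`
#'   (equal on the dead set).
#' @return list with components `u` and `v`.
#' @export
weights_to_free <- function(state, theta, w) {
  stopifnot(inherits(state, "state_vector"))
  u <- theta[state$tau]
  if (state$c_plus == 0) return(list(u = u, v = numeric(0)))
  S <- sum(theta[state$C1])
  list(u = u, v = w[state$C1] / S)
}

#' Log prior mass of a state vector given the DE proportion
#'
#' Independent Bernoulli(`pi`) indicators truncated to the valid set
#' `sum(c) != 1`: `P(c | pi) = pi^c+ (1-pi)^(K-c+) / (1 - K pi (1-pi)^(K-1))`.
#'
#' @param state a [state_vector()].
#' @param pi DE proportion in (0, 1).
#' @return log prior probability.
#' @export
state_prior_logpmf <- function(state, pi) {
  stopifnot(inherits(state, "state_vector"))
  if (pi <= 0 || pi >= 1) abort("`pi` must lie strictly in (0, 1)")
  K <- state$K
  cp <- state$c_plus
  cp * log(pi) + (K - cp) * log1p(-pi) -
    log1p(-K * pi * (1 - pi)^(K - 1))
}

#' Beta posterior parameters of the DE proportion
#'
#' Under the Jeffreys `Beta(1/2, 1/2)` prior the DE proportion is updated as
#' `pi | c ~ Beta(c+ + 1/2, K - c+ + 1/2)`.
#'
#' @param state a [state_vector()].
#' @param hyper a [hyperparams()]; must have `pi_mode = "jeffreys"`.
#' @return numeric vector `c(shape1, shape2)`.
#' @export
pi_posterior_params <- function(state, hyper = hyperparams(state$K)) {
  stopifnot(inherits(state, "state_vector"))
  if (hyper$pi_mode != "jeffreys")
    abort("pi posterior is only defined in jeffreys mode (pi is fixed otherwise)")
  c(state$c_plus + 0.5, state$K - state$c_plus + 0.5)
}

#' Enumerate all valid state vectors
#'
#' All binary vectors of length `K` with `sum != 1`; intended for tiny `K`
#' (exact enumeration and tests).
#'
#' @param K number of transcripts (`K <= 20`).
#' @return a list of [state_vector()] objects.
#' @export
enumerate_states <- function(K) {
  if (K > 20) abort("state enumeration is limited to K <= 20")
  grid <- as.matrix(expand.grid(rep(list(0:1), K)))[, K:1, drop = FALSE]
  keep <- rowSums(grid) != 1
  lapply(seq_len(nrow(grid))[keep], function(i) state_vector(grid[i, ]))
}

# compact label for a state: bitmask with transcript k on bit k-1
state_code <- function(c) sum(as.integer(c) * 2^(seq_along(c) - 1))
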