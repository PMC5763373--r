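#' Hyperparameters of the joint expression/DE model
#'
#' Bundles the Dirichlet parameters of the two free abundance vectors and the
#' prior on the probability of differential expression. `alpha` parametrises
#' the constant-dimension simplex `u` (length `K`); `gamma` parametrises the
#' variable-dimension simplex `v`, of which only the first `c+` entries are
#' used for a state with `c+` differentially expressed transcripts. The
#' default `alpha = gamma = 1` is the uniform prior on both simplexes.
#'
#' The DE proportion `pi` either carries a Jeffreys `Beta(1/2, 1/2)` prior and
#' is updated by Gibbs sampling (`pi_mode = "jeffreys"`), or is held at a
#' fixed value (`pi_mode = "fixed"`), e.g. `pi = 0.5` for a prior-insensitive
#' analysis.
#'
#' @param K number of transcripts (mixture components), `K >= 2`.
#' @param alpha Dirichlet parameters for `u`; scalar recycled to length `K`.
#' @param gamma Dirichlet parameters for `v`; scalar recycled to length `K`.
#' @param pi_mode `"jeffreys"` or `"fixed"`.
#' @param pi_fixed fixed DE prior probability, used only when
#'   `pi_mode = "fixed"`.
#' @return an object of class `jointde_hyper`.
#' @examples
#' hyperparams(4)
#' hyperparams(3, alpha = c(1, 2, 1), pi_mode = "fixed", pi_fixed = 0.5)
#' @export
hyperparams <- function(K, alpha = 1, gamma = 1,
                        pi_mode = c("jeffreys", "fixed"), pi_fixed = 0.5) {
  pi_mode <- match.arg(pi_mode)
  K <- as.integer(K)
  if (is.na(K) || K < 2) abort("`K` must be an integer >= 2")
  if (length(alpha) == 1) alpha <- rep(alpha, K)
  if (length(gamma) == 1) gamma <- rep(gamma, K)
  if (length(alpha) != K || length(gamma) != K)
    abort("`alpha` and `gamma` must have length 1 or K")
  if (any(alpha <= 0) || any(gamma <= 0))
    abort("`alpha` and `gamma` must be strictly positive")
  if (pi_fixed <= 0 || pi_fixed >= 1)
    abort("`pi_fixed` must lie strictly in (0, 1)")
  structure(
    list(K = K, alpha = as.double(alpha), gamma = as.double(gamma),
         pi_mode = pi_mode, pi_fixed = as.double(pi_fixed)),
    class = "jointde_hyper"
  )
}

#' @export
print.jointde_hyper <- function(x, ...) {
  cat("<jointde_hyper> K =", x$K,
      "| alpha:", if (length(unique(x$alpha)) == 1) x$alpha[1] else "vector",
      "| gamma:", if (length(unique(x$gamma)) == 1) x$gamma[1] else "vector",
      "| pi:", if (x$pi_mode == "jeffreys") "Beta(1/2,1/2)"
               else sprintf("fixed at %g", x$pi_fixed), "\n")
  invisible(x)
}
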