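# internal numeric helpers

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a per-cluster chain seed from a master seed
#'
#' Deterministic integer mixing so that per-cluster chains are reproducible
#' independently of how clusters are scheduled across workers. Kept below
#' 2^31 - 1.
#'
#' @param master integer master seed.
#' @param id integer stream id (e.g. cluster id).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(master, id) {
  as.integer((as.double(master) * 48271 + as.double(id) * 16807 + 12345) %%
               2147483647)
}

check_simplex <- function(x, tol = 1e-8, arg = "x") {
  if (any(!is.finite(x)) || any(x < -tol))
    abort(sprintf("`%s` must be a non-negative finite vector", arg))
  if (abs(sum(x) - 1) > tol)
    abort(sprintf("`%s` must sum to 1 (got %.10g)", arg, sum(x)))
  invisible(x)
}

# stable positions of the g largest values of q (ties by original order)
order_desc_stable <- function(q) order(-q, seq_along(q))
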