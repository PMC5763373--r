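#' MCMC chain configuration
#'
#' @param n_iter total sweeps.
#' @param burn_in sweeps discarded before recording (`burn_in < n_iter`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param sampler `"collapsed"` (expression parameters integrated out;
#'   default and recommended) or `"rjmcmc"` (birth/death moves on the
#'   variable-dimension free parameters).
#' @param sample_expression also draw the expression parameters at kept
#'   iterations to report posterior mean abundances (always on for the
#'   RJMCMC sampler).
#' @param record_states record the visited state vectors as bitmask codes
#'   (requires `K <= 30`; used for exact-posterior comparisons).
#' @param random_scan resample allocations in random order instead of the
#'   default systematic sweep (collapsed sampler only).
#' @return an object of class `jointde_config`.
#' @export
chain_config <- function(n_iter = 10000, burn_in = 2000, thin = 1,
                         sampler = c("collapsed", "rjmcmc"),
                         sample_expression = TRUE,
                         record_states = FALSE,
                         random_scan = FALSE) {
  sampler <- match.arg(sampler)
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) abort("`burn_in` must be smaller than `n_iter`")
  if (thin < 1) abort("`thin` must be >= 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 sampler = sampler, sample_expression = sample_expression,
                 record_states = record_states, random_scan = random_scan),
            class = "jointde_config")
}

#' Run one MCMC chain on a matched pair of alignment tables
#'
#' Runs the configured sampler on the full (unclustered) problem and returns
#' per-transcript posterior summaries: the posterior probability of
#' differential expression `q_k` (post-burn-in frequency of `c_k = 1`),
#' posterior mean abundances in both samples and the log2 fold change of the
#' posterior means. Deterministic given `seed`.
#'
#' Both samplers are initialised at the all-null state vector with
#' allocations drawn proportionally to the alignment densities and, in
#' Jeffreys mode, the DE proportion drawn from its prior.
#'
#' @param x,y matched [alignments()] tables (sample x and sample y).
#' @param hyper a [hyperparams()]; defaults to the uniform prior.
#' @param config a [chain_config()].
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return an object of class `jointde_chain` with elements `summary`
#'   (tibble), `pi_mean`, `trace`, `diagnostics`, `state_codes`,
#'   `counts_x`, `counts_y`.
#' @examples
#' sim <- simulate_dataset(K = 4, r = 60, s = 60, c_true = c(1, 1, 0, 0),
#'                         effect_size = 2, seed = 1)
#' ch <- run_chain(sim$x, sim$y, config = chain_config(2000, 500), seed = 1)
#' tidy(ch)
#' @export
run_chain <- function(x, y, hyper = NULL, config = chain_config(),
                      seed = NULL) {
  check_matched_pair(x, y)
  stopifnot(inherits(config, "jointde_config"))
  cx <- as_align_csr(x)
  cy <- as_align_csr(y)
  K <- cx$K
  if (K < 2) abort("the model requires at least K = 2 transcripts")
  if (is.null(hyper)) hyper <- hyperparams(K)
  stopifnot(inherits(hyper, "jointde_hyper"))
  if (hyper$K != K) abort("hyperparameters were built for a different K")
  if (!is.null(seed)) set.seed(seed)
  res <- chain_impl(cx, cy, hyper, config)
  ids <- transcript_ids(x)
  summary <- tibble(
    transcript = ids,
    q = as.numeric(res$q),
    theta_mean = as.numeric(res$theta_mean),
    w_mean = as.numeric(res$w_mean),
    log2fc = log2(as.numeric(res$theta_mean) / as.numeric(res$w_mean)),
    counts_x = as.integer(res$counts_x),
    counts_y = as.integer(res$counts_y))
  trace <- as_tibble(as.data.frame(res$trace_q))
  names(trace) <- ids
  trace$iteration <- as.integer(res$trace_iter)
  structure(list(
    summary = summary, pi_mean = res$pi_mean, n_kept = res$n_kept,
    trace = trace, diagnostics = as.list(res$diagnostics),
    state_codes = as.integer(res$state_codes),
    c_final = as.integer(res$c_final),
    allocations = list(xi = as.integer(res$xi) + 1L,
                       z = as.integer(res$z) + 1L),
    config = config, hyper = hyper, K = K,
    n_reads = c(x = length(cx$ptr) - 1L, y = length(cy$ptr) - 1L)),
    class = "jointde_chain")
}

#' @export
print.jointde_chain <- function(x, ...) {
  cat("<jointde_chain> ", x$config$sampler, " sampler, K = ", x$K,
      ", reads = ", x$n_reads[["x"]], "/", x$n_reads[["y"]],
      ", kept ", x$n_kept, " draws\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @describeIn run_chain per-transcript posterior summary as a tibble.
#' @param x a `jointde_chain`.
#' @param ... unused.
#' @export
tidy.jointde_chain <- function(x, ...) x$summary

#' @export
glance.jointde_chain <- function(x, ...) {
  tibble(K = x$K, n_reads_x = x$n_reads[["x"]], n_reads_y = x$n_reads[["y"]],
         sampler = x$config$sampler, n_iter = x$config$n_iter,
         n_kept = x$n_kept, pi_mean = x$pi_mean)
}

# run the compiled sampler on csr slices; assumes the RNG state is already set
chain_impl <- function(cx, cy, hyper, config) {
  pi_init <- if (hyper$pi_mode == "jeffreys") stats::rbeta(1, 0.5, 0.5)
             else hyper$pi_fixed
  run_chain_cpp(cx$ptr, cx$idx, cx$f, cy$ptr, cy$idx, cy$f,
                cx$K, hyper$alpha, hyper$gamma,
                hyper$pi_mode == "jeffreys", pi_init,
                config$n_iter, config$burn_in, config$thin,
                config$sampler == "collapsed",
                config$sample_expression,
                config$record_states, config$random_scan)
}

# empirical distribution over recorded state codes, as named probabilities
state_code_freq <- function(chain) {
  codes <- chain$state_codes
  if (length(codes) == 0)
    abort("chain was run without record_states = TRUE")
  tab <- table(codes)
  setNames(as.numeric(tab) / length(codes), names(tab))
}
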