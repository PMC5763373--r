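#' Joint Bayesian estimation of expression and differential expression
#'
#' The top-level driver. Partitions transcripts into read-sharing clusters
#' ([build_clusters()]), runs an independent MCMC chain per cluster (largest
#' clusters dispatched first, optionally across workers), and merges
#' per-cluster posteriors into a genome-wide result table. With
#' `cluster = FALSE` a single chain is run on the whole problem instead.
#'
#' Within a cluster, the state-vector constraint (`c+ != 1`) applies to the
#' cluster's own transcripts and the DE proportion carries its own Jeffreys
#' prior (or the global fixed value in fixed mode). Global abundances are
#' recovered as within-cluster posterior means scaled by the posterior mean
#' cluster mass under a Dirichlet-multinomial over per-cluster read totals
#' (prior mass = the summed `alpha` of the cluster).
#'
#' Transcripts in singleton clusters carry no within-cluster DE information
#' (a one-transcript state vector admits only `c = 0`), so their `q` is 0 and
#' they are flagged in the `note` column; differences in their read totals
#' still show up in the abundance estimates and fold change.
#'
#' @param x,y matched [alignments()] tables for the two samples.
#' @param hyper a [hyperparams()] for the full transcript universe; defaults
#'   to the uniform prior with a Jeffreys prior on the DE proportion.
#' @param config a [chain_config()] applied to every cluster chain.
#' @param cluster decompose into read-sharing clusters (default) or run one
#'   chain on the full problem.
#' @param n_workers number of parallel workers for per-cluster chains
#'   (forked processes; results are identical for any worker count because
#'   each cluster derives its own seed).
#' @param seed master seed; per-cluster seeds are derived deterministically.
#' @param fdr_level FDR level for the default decision columns.
#' @param loss_cost cost for the loss-rule decision column.
#' @return an object of class `jointde_fit`; see [tidy.jointde_fit()].
#' @examples
#' sim <- simulate_dataset(K = 6, r = 150, s = 150, c_true = c(1, 1, 0, 0, 0, 0),
#'                         effect_size = 2, group_size = 3, seed = 7)
#' fit <- fit_de(sim$x, sim$y, config = chain_config(1500, 500), seed = 7)
#' tidy(fit)
#' @export
fit_de <- function(x, y, hyper = NULL, config = chain_config(),
                   cluster = TRUE, n_workers = 1, seed = NULL,
                   fdr_level = 0.05, loss_cost = 4) {
  check_matched_pair(x, y)
  ids <- transcript_ids(x)
  K <- length(ids)
  if (is.null(hyper)) hyper <- hyperparams(K)
  if (hyper$K != K) abort("hyperparameters were built for a different K")
  master <- if (is.null(seed)) sample.int(2147483646L, 1) else as.integer(seed)

  cx <- as_align_csr(x)
  cy <- as_align_csr(y)
  r <- length(cx$ptr) - 1L
  s <- length(cy$ptr) - 1L

  if (!cluster) {
    ch <- run_chain(x, y, hyper, config, seed = master)
    res <- ch$summary |>
      mutate(cluster = 1L, note = "")
    fit <- new_fit(res, NULL, hyper, config, master,
                   pi_mean = ch$pi_mean, r = r, s = s,
                   fdr_level = fdr_level, loss_cost = loss_cost)
    return(fit)
  }

  part <- build_clusters(x, y)
  members_of <- split(seq_len(K), part$assignment$cluster)
  n_cl <- nrow(part$info)

  run_one <- function(cid) {
    members <- members_of[[as.character(cid)]]
    Kc <- length(members)
    sx <- subset_csr(cx, members)
    sy <- subset_csr(cy, members)
    if (Kc == 1) {
      return(list(cid = cid,
                  transcript = ids[members],
                  q = 0, theta_within = 1, w_within = 1,
                  counts_x = length(sx$ptr) - 1L,
                  counts_y = length(sy$ptr) - 1L,
                  note = if (length(sx$f) + length(sy$f) == 0) "no_data"
                         else "singleton",
                  pi_mean = NA_real_))
    }
    hc <- hyperparams(Kc, alpha = hyper$alpha[members],
                      gamma = hyper$gamma[seq_len(Kc)],
                      pi_mode = hyper$pi_mode, pi_fixed = hyper$pi_fixed)
    set.seed(derive_seed(master, cid))
    res <- chain_impl(sx, sy, hc, config)
    list(cid = cid, transcript = ids[members],
         q = as.numeric(res$q),
         theta_within = as.numeric(res$theta_mean),
         w_within = as.numeric(res$w_mean),
         counts_x = as.integer(res$counts_x),
         counts_y = as.integer(res$counts_y),
         note = "", pi_mean = res$pi_mean)
  }

  order_big_first <- part$info$cluster  # already ordered by read count
  out <- if (n_workers > 1) {
    parallel::mclapply(order_big_first, run_one, mc.cores = n_workers)
  } else {
    lapply(order_big_first, run_one)
  }
  bad <- vapply(out, function(o) inherits(o, "try-error") || is.null(o$cid),
                logical(1))
  if (any(bad))
    abort(paste0("cluster chain failed for cluster(s): ",
                 paste(order_big_first[bad], collapse = ", ")))

  # posterior mean cluster masses: Dirichlet-multinomial over read totals
  A_c <- vapply(out, function(o) sum(hyper$alpha[match(o$transcript, ids)]),
                numeric(1))
  r_c <- vapply(out, function(o) sum(o$counts_x), numeric(1))
  s_c <- vapply(out, function(o) sum(o$counts_y), numeric(1))
  mass_x <- (A_c + r_c) / (sum(A_c) + r)
  mass_y <- (A_c + s_c) / (sum(A_c) + s)

  res <- purrr::map2_dfr(out, seq_along(out), function(o, i) {
    tibble(transcript = o$transcript,
           cluster = o$cid,
           q = o$q,
           theta_mean = o$theta_within * mass_x[i],
           w_mean = o$w_within * mass_y[i],
           counts_x = o$counts_x,
           counts_y = o$counts_y,
           note = o$note)
  })
  res$log2fc <- log2(res$theta_mean / res$w_mean)
  res <- res[match(ids, res$transcript), ]
  pi_by_cluster <- vapply(out, function(o) o$pi_mean, numeric(1))
  new_fit(res, part, hyper, config, master,
          pi_mean = mean(pi_by_cluster, na.rm = TRUE), r = r, s = s,
          fdr_level = fdr_level, loss_cost = loss_cost)
}

new_fit <- function(res, part, hyper, config, seed, pi_mean, r, s,
                    fdr_level, loss_cost) {
  res$d_fdr <- call_fdr(res$q, fdr_level)$d
  res$d_conservative <- call_conservative(res$q, fdr_level)$d
  res$d_loss <- call_loss(res$q, loss_cost)$d
  cols <- c("transcript", "cluster", "q", "theta_mean", "w_mean", "log2fc",
            "counts_x", "counts_y", "d_fdr", "d_conservative", "d_loss",
            "note")
  res <- res[intersect(cols, names(res))]
  structure(list(results = as_tibble(res), clusters = part, hyper = hyper,
                 config = config, seed = seed, pi_mean = pi_mean,
                 n_reads = c(x = r, y = s),
                 fdr_level = fdr_level, loss_cost = loss_cost),
            class = "jointde_fit")
}

#' @export
print.jointde_fit <- function(x, ...) {
  cat("<jointde_fit> K = ", nrow(x$results),
      ", reads = ", x$n_reads[["x"]], "/", x$n_reads[["y"]],
      ", clusters = ", if (is.null(x$clusters)) 1 else nrow(x$clusters$info),
      ", DE calls (FDR ", x$fdr_level, ") = ", sum(x$results$d_fdr),
      "\n", sep = "")
  print(x$results)
  invisible(x)
}

#' Tidiers and plots for fitted objects
#'
#' `tidy()` returns the per-transcript result table (posterior DE
#' probability `q`, posterior mean abundances, log2 fold change, decision
#' columns for the three calling rules). `glance()` returns a one-row model
#' summary. `autoplot()` draws posterior DE probability against log2 fold
#' change, coloured by the FDR-rule decision.
#'
#' @param x a `jointde_fit`.
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per transcript; `glance()`: a
#'   one-row tibble; `autoplot()`: a ggplot.
#' @export
tidy.jointde_fit <- function(x, ...) x$results

#' @rdname tidy.jointde_fit
#' @export
glance.jointde_fit <- function(x, ...) {
  tibble(K = nrow(x$results),
         n_reads_x = x$n_reads[["x"]], n_reads_y = x$n_reads[["y"]],
         n_clusters = if (is.null(x$clusters)) 1L else nrow(x$clusters$info),
         sampler = x$config$sampler,
         n_iter = x$config$n_iter,
         pi_mean = x$pi_mean,
         n_de_fdr = sum(x$results$d_fdr),
         expected_fdr = as.numeric(expected_fdr(x$results$q, x$results$d_fdr)))
}

#' @rdname tidy.jointde_fit
#' @param object a `jointde_fit`.
#' @export
autoplot.jointde_fit <- function(object, ...) {
  df <- object$results |>
    mutate(called = factor(ifelse(.data$d_fdr == 1, "DE", "not DE"),
                           levels = c("not DE", "DE")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$q,
                                   colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c("not DE" = "grey40",
                                            "DE" = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (posterior means)",
                  y = "posterior probability of DE",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.jointde_fit
#' @export
autoplot.jointde_chain <- function(object, ...) {
  tr <- object$trace |>
    tidyr::pivot_longer(-"iteration", names_to = "transcript",
                        values_to = "ergodic_q")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$ergodic_q,
                                   group = .data$transcript)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "iteration", y = "ergodic mean of P(c_k = 1 | data)") +
    ggplot2::theme_minimal()
}
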