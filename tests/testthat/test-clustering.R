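test_that("read-sharing components form the expected clusters", {
  ids <- paste0("t", 1:3)
  a <- mk_align(data.frame(read = c("r1", "r1", "r2"),
                           transcript = c("t1", "t2", "t3"), dens = 1), ids)
  cl <- build_clusters(a, a)
  asg <- cl$assignment
  expect_equal(asg$cluster[1], asg$cluster[2])
  expect_false(asg$cluster[1] == asg$cluster[3])
  # chained sharing is transitive
  b <- mk_align(data.frame(read = c("r1", "r1", "r2", "r2"),
                           transcript = c("t1", "t2", "t2", "t3"), dens = 1),
                ids)
  cl2 <- build_clusters(b, b)
  expect_equal(length(unique(cl2$assignment$cluster)), 1)
})

test_that("transcripts without reads form singleton clusters", {
  ids <- paste0("t", 1:4)
  a <- mk_align(data.frame(read = "r1", transcript = "t1", dens = 1), ids)
  cl <- build_clusters(a, a)
  expect_equal(nrow(cl$info), 4)
  expect_equal(cl$info$n_reads_x, c(1L, 0L, 0L, 0L))
})

test_that("clustering is invariant to read order and sample order", {
  inst <- random_tiny_instance(K = 5, r = 8, s = 8, seed = 13)
  cl <- build_clusters(inst$x, inst$y)
  shuffled <- alignments(as.data.frame(inst$x[sample(nrow(inst$x)), ]),
                         transcript_ids = transcript_ids(inst$x))
  cl2 <- build_clusters(shuffled, inst$y)
  cl3 <- build_clusters(inst$y, inst$x)
  expect_equal(cl$assignment, cl2$assignment)
  expect_equal(cl$assignment, cl3$assignment)
})

test_that("clusterwise fit merges to a global simplex and is worker-deterministic", {
  sim <- simulate_dataset(K = 12, r = 400, s = 400, c_true = rep(c(1, 0), c(2, 10)),
                          effect_size = 2, group_size = 3, multimap_prob = 0.5,
                          seed = 21)
  f1 <- fit_de(sim$x, sim$y, config = chain_config(1200, 300), seed = 21)
  expect_equal(sum(f1$results$theta_mean), 1, tolerance = 1e-9)
  expect_equal(sum(f1$results$w_mean), 1, tolerance = 1e-9)
  f2 <- fit_de(sim$x, sim$y, config = chain_config(1200, 300), seed = 21,
               n_workers = 3)
  expect_identical(tidy(f1), tidy(f2))
})

test_that("zero-read singletons are flagged and carry q = 0", {
  ids <- paste0("t", 1:3)
  x <- mk_align(data.frame(read = c("x1", "x1", "x2"),
                           transcript = c("t1", "t2", "t1"), dens = 1), ids)
  y <- mk_align(data.frame(read = c("y1", "y1"),
                           transcript = c("t1", "t2"), dens = 1), ids)
  fit <- fit_de(x, y, config = chain_config(500, 100), seed = 2)
  row <- fit$results[fit$results$transcript == "t3", ]
  expect_equal(row$q, 0)
  expect_equal(row$note, "no_data")
})

test_that("fixed-pi clusterwise marginals match the raw sampler on informative data", {
  ids <- paste0("t", 1:4)
  mk_reads <- function(prefix, spec) {
    rows <- list(); cnt <- 0
    for (sp in spec) for (i in seq_len(sp$n)) {
      cnt <- cnt + 1
      rows[[length(rows) + 1]] <- data.frame(
        read = paste0(prefix, cnt), transcript = sp$t, dens = 1 / length(sp$t))
    }
    mk_align(do.call(rbind, rows), ids)
  }
  x <- mk_reads("x", list(list(t = "t1", n = 16), list(t = "t2", n = 2),
                          list(t = c("t1", "t2"), n = 4),
                          list(t = "t3", n = 9), list(t = "t4", n = 9),
                          list(t = c("t3", "t4"), n = 2)))
  y <- mk_reads("y", list(list(t = "t1", n = 2), list(t = "t2", n = 16),
                          list(t = c("t1", "t2"), n = 4),
                          list(t = "t3", n = 9), list(t = "t4", n = 9),
                          list(t = c("t3", "t4"), n = 2)))
  hy <- hyperparams(4, pi_mode = "fixed", pi_fixed = 0.5)
  raw <- run_chain(x, y, hy, chain_config(40000, 5000,
                                          sample_expression = FALSE), seed = 1)
  fit <- fit_de(x, y, hy, chain_config(40000, 5000,
                                       sample_expression = FALSE), seed = 2)
  q_cl <- fit$results$q[match(raw$summary$transcript, fit$results$transcript)]
  expect_lt(max(abs(raw$summary$q - q_cl)), 0.03)
})
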