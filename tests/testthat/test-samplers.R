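test_that("chains are reproducible under a fixed seed", {
  inst <- random_tiny_instance(K = 3, r = 4, s = 4, seed = 2)
  for (sam in c("collapsed", "rjmcmc")) {
    cfg <- chain_config(800, 200, sampler = sam, record_states = TRUE)
    a <- run_chain(inst$x, inst$y, config = cfg, seed = 7)
    b <- run_chain(inst$x, inst$y, config = cfg, seed = 7)
    expect_identical(a$summary, b$summary)
    expect_identical(a$state_codes, b$state_codes)
  }
})

test_that("visited states never violate the c+ != 1 constraint", {
  inst <- random_tiny_instance(K = 4, r = 5, s = 5, seed = 3)
  for (sam in c("collapsed", "rjmcmc")) {
    ch <- run_chain(inst$x, inst$y,
                    config = chain_config(2000, 0, sampler = sam,
                                          record_states = TRUE),
                    seed = 1)
    expect_false(any(popcount(ch$state_codes) == 1))
  }
})

test_that("allocation tallies match the final labels exactly", {
  inst <- random_tiny_instance(K = 4, r = 12, s = 9, seed = 5)
  for (sam in c("collapsed", "rjmcmc")) {
    ch <- run_chain(inst$x, inst$y,
                    config = chain_config(500, 100, sampler = sam), seed = 2)
    expect_equal(ch$summary$counts_x,
                 tabulate(ch$allocations$xi, nbins = 4))
    expect_equal(ch$summary$counts_y,
                 tabulate(ch$allocations$z, nbins = 4))
    expect_equal(sum(ch$summary$counts_x), 12)
    expect_equal(sum(ch$summary$counts_y), 9)
  }
})

test_that("both samplers recover the exact posterior on tiny instances", {
  hy3 <- hyperparams(3, pi_mode = "fixed", pi_fixed = 0.5)
  for (seed in 1:2) {
    inst <- random_tiny_instance(K = 3, r = 2, s = 2, seed = seed)
    oracle <- exact_state_posterior(inst$x, inst$y, hy3, pi = 0.5)
    pref <- setNames(oracle$states$prob, oracle$states$code)
    for (sam in c("collapsed", "rjmcmc")) {
      ch <- run_chain(inst$x, inst$y, hy3,
                      chain_config(60000, 6000, sampler = sam,
                                   record_states = TRUE,
                                   sample_expression = FALSE),
                      seed = 10 + seed)
      expect_lt(tv_distance(jointde:::state_code_freq(ch), pref), 0.05)
    }
  }
})

test_that("a chain with non-exchangeable hyperparameters matches the oracle", {
  hy <- hyperparams(3, alpha = c(0.7, 1.3, 2), gamma = c(1.5, 0.8, 1.2),
                    pi_mode = "fixed", pi_fixed = 0.4)
  inst <- random_tiny_instance(K = 3, r = 2, s = 2, seed = 9)
  oracle <- exact_state_posterior(inst$x, inst$y, hy, pi = 0.4)
  pref <- setNames(oracle$states$prob, oracle$states$code)
  for (sam in c("collapsed", "rjmcmc")) {
    ch <- run_chain(inst$x, inst$y, hy,
                    chain_config(80000, 8000, sampler = sam,
                                 record_states = TRUE,
                                 sample_expression = FALSE),
                    seed = 4)
    expect_lt(tv_distance(jointde:::state_code_freq(ch), pref), 0.05)
  }
})

test_that("unique balanced data give near-null DE calls; strong contrast is caught", {
  # balanced: every read unique, equal counts -> q stays moderate, lfc ~ 0
  ids <- c("a", "b")
  bal <- function(prefix, n) data.frame(
    read = paste0(prefix, seq_len(2 * n)),
    transcript = rep(c("a", "b"), each = n), dens = 1)
  x <- mk_align(bal("x", 40), ids)
  y <- mk_align(bal("y", 40), ids)
  ch <- run_chain(x, y, config = chain_config(4000, 1000), seed = 1)
  expect_lt(max(abs(ch$summary$log2fc)), 0.35)
  # strong contrast on one transcript
  y2 <- mk_align(data.frame(read = paste0("y", 1:80),
                            transcript = rep(c("a", "b"), c(5, 75)), dens = 1),
                 ids)
  ch2 <- run_chain(x, y2, config = chain_config(4000, 1000), seed = 1)
  expect_gt(min(ch2$summary$q), 0.95)
  expect_gt(ch2$summary$log2fc[1], 1.5)
})

test_that("posterior mean abundances track the conjugate closed form without ambiguity", {
  # unique reads, all-null truth: theta posterior ~ Dirichlet(alpha + pooled)
  ids <- c("a", "b", "c")
  nx <- c(30, 15, 5); ny <- c(28, 17, 5)
  x <- mk_align(data.frame(read = paste0("x", 1:50),
                           transcript = rep(ids, nx), dens = 1), ids)
  y <- mk_align(data.frame(read = paste0("y", 1:50),
                           transcript = rep(ids, ny), dens = 1), ids)
  ch <- run_chain(x, y, config = chain_config(6000, 1000), seed = 3)
  pooled <- (1 + nx + ny) / (3 + 100)
  # q is small here so the pooled conjugate mean dominates
  expect_equal(ch$summary$theta_mean, pooled, tolerance = 0.08)
  expect_equal(sum(ch$summary$theta_mean), 1, tolerance = 1e-6)
  expect_equal(sum(ch$summary$w_mean), 1, tolerance = 1e-6)
})
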