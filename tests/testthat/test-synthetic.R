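test_that("all-null truth makes the two abundance vectors identical", {
  sim <- simulate_dataset(K = 5, r = 50, s = 50, c_true = rep(0, 5), seed = 1)
  expect_equal(sim$truth$theta_true, sim$truth$w_true)
  expect_equal(sum(sim$truth$c_true), 0)
})

test_that("zero ambiguity yields uniquely mapped reads", {
  sim <- simulate_dataset(K = 6, r = 200, s = 200, c_plus = 2,
                          group_size = 3, multimap_prob = 0, seed = 2)
  expect_equal(nrow(sim$x), 200)   # one entry per read
  expect_equal(nrow(sim$y), 200)
  sim2 <- simulate_dataset(K = 6, r = 200, s = 200, c_plus = 2,
                           group_size = 3, multimap_prob = 1, seed = 2)
  expect_equal(nrow(sim2$x), 600)  # every group mate reported
})

test_that("read counts follow the multinomial law of the true abundances", {
  sim <- simulate_dataset(K = 5, r = 20000, s = 100, c_true = rep(0, 5),
                          seed = 3)
  counts <- tabulate(sim$origins$xi, nbins = 5)
  th <- sim$truth$theta_true
  se <- sqrt(20000 * th * (1 - th))
  expect_true(all(abs(counts - 20000 * th) < 4 * se + 4))
})

test_that("the effect-size construction respects the model constraints", {
  sim <- simulate_dataset(K = 20, r = 10, s = 10, c_plus = 6,
                          effect_size = 2.5, de_expressed = TRUE, seed = 4)
  tr <- sim$truth
  al <- tr$c_true == 1
  expect_equal(tr$theta_true[!al], tr$w_true[!al])
  expect_equal(sum(tr$w_true[al]), sum(tr$theta_true[al]), tolerance = 1e-12)
  lfc <- abs(log2(tr$theta_true[al] / tr$w_true[al]))
  expect_true(all(lfc > 1))   # realised folds stay close to the 2.5 target
  expect_equal(sum(tr$theta_true), 1, tolerance = 1e-12)
})

test_that("generated weights follow the marginal Dirichlet prior law", {
  # mapping (c, u, v) -> (theta, w) preserves Dirichlet(1,..,1) marginally,
  # so each coordinate is Beta(1, K-1)
  set.seed(5)
  d <- prior_weight_draws(20000, K = 3)
  for (k in 1:3) {
    expect_gt(suppressWarnings(
      stats::ks.test(d$theta[, k], stats::pbeta, 1, 2))$p.value, 0.005)
    expect_gt(suppressWarnings(
      stats::ks.test(d$w[, k], stats::pbeta, 1, 2))$p.value, 0.005)
  }
})

test_that("identical seeds reproduce the dataset; different seeds differ", {
  a <- simulate_dataset(K = 4, r = 30, s = 30, c_plus = 2, seed = 9)
  b <- simulate_dataset(K = 4, r = 30, s = 30, c_plus = 2, seed = 9)
  d <- simulate_dataset(K = 4, r = 30, s = 30, c_plus = 2, seed = 10)
  expect_identical(as.data.frame(a$x), as.data.frame(b$x))
  expect_identical(a$truth, b$truth)
  expect_false(identical(as.data.frame(a$x), as.data.frame(d$x)))
  expect_error(simulate_dataset(K = 1, r = 5, s = 5), "K")
  expect_error(simulate_dataset(K = 4, r = 5, s = 5, c_plus = 1), "c_plus")
})

test_that("recovery metrics behave on trivial inputs", {
  truth <- tibble::tibble(transcript = paste0("t", 1:6),
                          c_true = c(1, 1, 0, 0, 0, 0),
                          theta_true = rep(1 / 6, 6), w_true = rep(1 / 6, 6))
  perfect <- tibble::tibble(transcript = truth$transcript,
                            q = c(1, 1, 0, 0, 0, 0))
  expect_equal(recovery_report(perfect, truth)$auroc, 1)
  deg <- truth; deg$c_true <- rep(0, 6)
  rep0 <- recovery_report(perfect, deg)
  expect_true(is.na(rep0$auroc))
  expect_match(rep0$note, "degenerate")
  # random scores hover around chance level
  set.seed(6)
  aucs <- replicate(40, {
    rnd <- tibble::tibble(transcript = truth$transcript, q = stats::runif(6))
    recovery_report(rnd, truth)$auroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})
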