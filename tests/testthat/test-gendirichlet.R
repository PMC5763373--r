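test_that("generalized Dirichlet samples live on the simplex", {
  set.seed(1)
  x <- rgdirichlet(2000, lam = c(2, 0.5, 3), beta = c(1, 4, 0.7))
  expect_true(all(x >= 0))
  expect_true(all(abs(rowSums(x) - 1) < 1e-12))
})

test_that("K = 2 generalized Dirichlet is a Beta stick", {
  set.seed(2)
  x <- rgdirichlet(20000, lam = 3, beta = 2)
  ks <- suppressWarnings(stats::ks.test(x[, 1], stats::pbeta, 3, 2))
  expect_gt(ks$p.value, 0.01)
  # uniform case: log-density identically zero
  expect_equal(dgdirichlet(c(0.3, 0.7), lam = 1, beta = 1), 0)
})

test_that("nested-beta parameters reduce to the Dirichlet distribution", {
  a <- c(2, 3, 1.5, 4)
  lam <- a[1:3]
  beta <- rev(cumsum(rev(a)))[-1]          # beta_k = sum_{j>k} a_j
  expect_equal(beta[3], a[4])              # beta_{K-1} = lam_K
  set.seed(3)
  x <- rgdirichlet(1e5, lam, beta)
  m <- colMeans(x)
  se <- apply(x, 2, stats::sd) / sqrt(nrow(x))
  expect_true(all(abs(m - a / sum(a)) < 3 * se + 1e-12))
  # and the density matches the Dirichlet density pointwise
  set.seed(4)
  pts <- rdirichlet(20, a)
  ld_dir <- apply(pts, 1, function(u)
    sum((a - 1) * log(u)) + lgamma(sum(a)) - sum(lgamma(a)))
  expect_equal(dgdirichlet(pts, lam, beta), ld_dir, tolerance = 1e-10)
})

test_that("density is -Inf on the boundary and sampling is reproducible", {
  expect_equal(dgdirichlet(c(0, 1, 0), lam = c(1, 1), beta = c(1, 1)), -Inf)
  set.seed(9); a <- rgdirichlet(3, c(1, 2), c(2, 1))
  set.seed(9); b <- rgdirichlet(3, c(1, 2), c(2, 1))
  expect_identical(a, b)
})

test_that("sampler and density agree (Monte Carlo self-consistency)", {
  # P(u1 < 0.5) from draws vs from quadrature of the density, K = 3
  lam <- c(1.5, 2.5); beta <- c(3, 1.2)
  set.seed(5)
  x <- rgdirichlet(4e4, lam, beta)
  p_mc <- mean(x[, 1] < 0.5)
  g <- simplex_grid(250)
  dens <- dgdirichlet(g, lam, beta, log = FALSE)
  h2 <- (1 / 250)^2
  p_quad <- sum(dens[g[, 1] < 0.5]) * h2 / (sum(dens) * h2)
  expect_lt(abs(p_mc - p_quad), 0.01)
})

test_that("full-conditional parameters reduce as the conjugacy predicts", {
  hy <- hyperparams(3, alpha = c(0.8, 1.4, 2.1), gamma = c(1.3, 0.9, 1))
  sx <- c(3, 1, 2); sz <- c(2, 2, 1)
  # c+ = 0: plain pooled Dirichlet
  p0 <- posterior_free_params(sx, sz, state_vector(c(0, 0, 0)), hy)
  pooled <- hy$alpha + sx + sz
  expect_equal(p0$lam, pooled[1:2])
  expect_equal(p0$beta, rev(cumsum(rev(pooled)))[-1])
  expect_length(p0$gamma_v, 0)
  # c+ = K: u ignores sample-y counts, v is its own Dirichlet
  p1 <- posterior_free_params(sx, sz, state_vector(c(1, 1, 1)), hy)
  xonly <- hy$alpha + sx
  expect_equal(p1$lam, xonly[1:2])
  expect_equal(p1$beta, rev(cumsum(rev(xonly)))[-1])
  expect_equal(p1$gamma_v, hy$gamma + sz)
})

test_that("full conditional of u matches the brute-force posterior (quadrature)", {
  # K = 3, c = (0, 1, 1): one shared coordinate, two differential
  hy <- hyperparams(3, alpha = c(0.9, 1.3, 1.6), gamma = c(1.2, 0.8, 1))
  st <- state_vector(c(0, 1, 1))
  sx <- c(2, 1, 3); sz <- c(1, 2, 2)
  pp <- posterior_free_params(sx, sz, st, hy)
  g <- simplex_grid(300)
  # unnormalised posterior of u in tau coordinates:
  # prior Dir(alpha) x u-likelihood x (alive mass)^(alive z-count)
  t_tau <- sx[st$tau]; m_tau <- sz[st$tau]
  kstar <- 3 - st$c_plus
  ex <- hy$alpha - 1 + t_tau + ifelse(seq_len(3) <= kstar, m_tau, 0)
  M1 <- sum(m_tau[(kstar + 1):3])
  logh <- log(g) %*% cbind(ex) + M1 * log(g[, 2] + g[, 3])
  ld <- dgdirichlet(g, pp$lam, pp$beta)
  # shape: log-density differs from log h by a constant everywhere
  off <- ld - logh
  expect_lt(max(off) - min(off), 1e-9)
  # normalisation: quadrature of h equals the implied constant
  h2 <- (1 / 300)^2
  expect_equal(sum(exp(logh)) * h2, exp(-mean(off)), tolerance = 2e-3)
})
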