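# shared fixtures and independent oracles used across test files

mk_align <- function(df, ids) alignments(df, transcript_ids = ids)

# a random tiny two-sample instance: each read aligns to a random non-empty
# candidate subset with random positive densities
random_tiny_instance <- function(K = 3, r = 2, s = 2, seed = 1) {
  set.seed(seed)
  ids <- paste0("t", seq_len(K))
  one_sample <- function(n, prefix) {
    rows <- lapply(seq_len(n), function(i) {
      m <- sample.int(K, 1)
      cand <- sample.int(K, m)
      data.frame(read = paste0(prefix, i), transcript = ids[cand],
                 dens = round(stats::runif(m, 0.2, 1), 3))
    })
    mk_align(do.call(rbind, rows), ids)
  }
  list(x = one_sample(r, "x"), y = one_sample(s, "y"))
}

# restrict an alignment table to a transcript subset (read-sharing cluster)
cluster_subset <- function(a, tr) {
  alignments(as.data.frame(a[a$transcript %in% tr, ]), transcript_ids = tr)
}

# draws of (theta, w) from the hierarchical prior: pi ~ Beta(1/2,1/2),
# c | pi truncated Bernoulli, u ~ Dir(alpha), v ~ Dir(gamma), mapped through
# the free-parameter bijection; vectorised by grouping draws on the state
prior_weight_draws <- function(n, K, alpha = 1, gamma = 1) {
  pi <- stats::rbeta(n, 0.5, 0.5)
  cmat <- matrix(stats::rbinom(n * K, 1, rep(pi, K)), nrow = n)
  bad <- rowSums(cmat) == 1
  while (any(bad)) {
    pi_b <- pi[bad]
    cmat[bad, ] <- stats::rbinom(sum(bad) * K, 1, rep(pi_b, K))
    bad <- rowSums(cmat) == 1
  }
  theta <- matrix(NA_real_, n, K)
  w <- matrix(NA_real_, n, K)
  key <- apply(cmat, 1, paste, collapse = "")
  for (pat in unique(key)) {
    rows <- which(key == pat)
    st <- state_vector(as.integer(strsplit(pat, "")[[1]]))
    u <- rdirichlet(length(rows), rep(alpha, K))
    th <- u[, st$tau_inv, drop = FALSE]
    ww <- th
    if (st$c_plus > 0) {
      S <- rowSums(th[, st$C1, drop = FALSE])
      v <- rdirichlet(length(rows), rep(gamma, st$c_plus))
      ww[, st$C1] <- v * S
    }
    theta[rows, ] <- th
    w[rows, ] <- ww
  }
  list(theta = theta, w = w, c = cmat)
}

# midpoint quadrature nodes over the interior of the 2-simplex (K = 3)
simplex_grid <- function(n = 200) {
  h <- 1 / n
  g <- expand.grid(u1 = (seq_len(n) - 0.5) * h, u2 = (seq_len(n) - 0.5) * h)
  g <- g[g$u1 + g$u2 < 1, ]
  cbind(u1 = g$u1, u2 = g$u2, u3 = 1 - g$u1 - g$u2)
}

# Monte-Carlo estimate of E[prod theta^sx * prod w^sz] under the conditional
# prior given state c -- brute-force integration oracle for the collapsed mass
mc_collapsed_integral <- function(sx, sz, cvec, alpha, gamma, n = 3e5) {
  st <- state_vector(cvec)
  K <- st$K
  u <- rdirichlet(n, alpha)
  theta <- u[, st$tau_inv, drop = FALSE]
  w <- theta
  if (st$c_plus > 0) {
    S <- rowSums(theta[, st$C1, drop = FALSE])
    v <- rdirichlet(n, gamma[seq_len(st$c_plus)])
    w[, st$C1] <- v * S
  }
  lw <- rowSums(log(theta) * rep(sx, each = n)) +
    rowSums(log(w) * rep(sz, each = n))
  mean(exp(lw))
}

# popcount of the bitmask codes recorded by a chain
popcount <- function(code) {
  vapply(code, function(x) sum(bitwAnd(x, 2^(0:29)) > 0), numeric(1))
}
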