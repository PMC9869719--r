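# Independent brute-force oracles used to check the vectorized
# implementations.  Everything here is literal loops over definitions and
# deliberately shares no code with R/.

# random tiny co-completion instance: problem, factors, Laplacian, hyper
random_instance <- function(seed, n_max = 8, t_max = 3) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  cc <- sample(1:n_max, 1)
  d <- sample(1:n_max, 1)
  t <- sample(1:t_max, 1)
  Y <- matrix(rbinom(n * cc, 1, 0.4), n, cc)
  X <- matrix(rbinom(n * d, 1, 0.4), n, d)
  test_rows <- if (n > 2 && runif(1) < 0.5) sample(n, 1) else integer(0)
  problem <- build_problem(Y, X, test_rows = test_rows)
  W <- matrix(rnorm(t * n), t, n)
  H <- matrix(rnorm(t * (cc + d)), t, cc + d)
  # random sparse graph -> normalized Laplacian
  A <- matrix(runif(n * n) < 0.4, n, n) * matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  hyper <- gtmcc_hyper(t = t, beta = runif(1, 0.1, 0.9),
                       gamma = runif(1, 0, 3), lambda1 = runif(1, 0, 2),
                       lambda2 = runif(1, 0, 2))
  list(problem = problem, W = W, H = H, L = normalized_laplacian(A),
       hyper = hyper)
}

# Eq.-by-eq objective with explicit loops
naive_objective <- function(problem, W, H, L, hyper) {
  Z <- problem$Z; Om <- problem$Omega
  n <- problem$n; m <- problem$c + problem$d
  t <- nrow(W)
  loss <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (Om[i, j] == 1) {
        pred <- 0
        for (k in seq_len(t)) pred <- pred + W[k, i] * H[k, j]
        w <- if (Z[i, j] == 1) hyper$beta else 1 - hyper$beta
        loss <- loss + w * (Z[i, j] - pred)^2
      }
    }
  }
  tr <- 0
  WL <- W %*% L
  for (k in seq_len(t)) for (i in seq_len(n)) tr <- tr + WL[k, i] * W[k, i]
  loss + hyper$gamma * tr + hyper$lambda1 * sum(W * W) +
    hyper$lambda2 * sum(H * H)
}

# entrywise gradients of the smooth weighted loss
naive_gradients <- function(problem, W, H, beta) {
  Z <- problem$Z; Om <- problem$Omega
  n <- problem$n; m <- problem$c + problem$d
  t <- nrow(W)
  gW <- matrix(0, t, n)
  gH <- matrix(0, t, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (Om[i, j] == 1) {
        resid <- Z[i, j] - sum(W[, i] * H[, j])
        w <- if (Z[i, j] == 1) beta else 1 - beta
        gW[, i] <- gW[, i] - 2 * w * resid * H[, j]
        gH[, j] <- gH[, j] - 2 * w * resid * W[, i]
      }
    }
  }
  list(W = gW, H = gH)
}

# pairwise-enumeration AUC with half credit for ties
naive_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) s <- s + 1 else if (p == q) s <- s + 0.5
    }
  }
  s / (length(pos) * length(neg))
}

# AP over distinct decreasing thresholds, by explicit threshold loop
naive_ap <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels)
  ap <- 0
  r_prev <- 0
  for (th in thr) {
    sel <- scores >= th
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / np
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

# row-wise multi-label metrics straight from their definitions
naive_ranking <- function(Y, S) {
  lrap <- cov <- rl <- numeric(0)
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]; s <- S[i, ]
    pos <- which(y == 1)
    if (length(pos) == 0) next
    per_label <- numeric(0)
    ranks <- numeric(0)
    for (j in pos) {
      rank_j <- sum(s >= s[j])
      above_true <- 0
      for (k in pos) if (s[k] >= s[j]) above_true <- above_true + 1
      per_label <- c(per_label, above_true / rank_j)
      ranks <- c(ranks, rank_j)
    }
    lrap <- c(lrap, mean(per_label))
    cov <- c(cov, max(ranks))
    neg <- which(y == 0)
    if (length(neg) > 0) {
      bad <- 0
      for (j in pos) {
        for (k in neg) {
          if (s[k] > s[j]) bad <- bad + 1
          else if (s[k] == s[j]) bad <- bad + 0.5
        }
      }
      rl <- c(rl, bad / (length(pos) * length(neg)))
    }
  }
  list(lrap = mean(lrap), co_error = mean(cov), rloss = mean(rl))
}

# plain unweighted alternating proximal-gradient factorization with
# Lipschitz steps: reference for the beta = 0.5, no-regularizer case
reference_unweighted_palm <- function(problem, t, iters, seed) {
  Z <- problem$Z; Om <- problem$Omega
  n <- problem$n; m <- problem$c + problem$d
  set.seed(as.integer(seed))
  W <- matrix(rnorm(t * n, sd = 1 / sqrt(t)), t, n)
  H <- matrix(rnorm(t * m, sd = 1 / sqrt(t)), t, m)
  for (k in seq_len(iters)) {
    tw <- max(2 * norm(H, "2")^2, 1e-8)
    W <- W - 2 * (H %*% t(Om * (crossprod(W, H) - Z))) / tw
    th <- max(2 * norm(W, "2")^2, 1e-8)
    H <- H - 2 * (W %*% (Om * (crossprod(W, H) - Z))) / th
  }
  list(W = W, H = H)
}

# small dense synthetic scenario used across test files
tiny_scenario <- function(seed, observe_frac = 0.6) {
  synthetic_scenario(n = 40, c = 60, d = 30, t_true = 5,
                     positive_density = 0.1, observe_frac = observe_frac,
                     similarity_noise = 0, seed = seed)
}
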