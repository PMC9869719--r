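# Problem construction, weighted loss, objective, gradients, proximal maps,
# step sizes, and the PALM fit.

test_that("build_problem concatenates Y before X and masks test rows", {
  Y <- matrix(c(1, 0), 2, 1, dimnames = list(c("d1", "d2"), "s1"))
  X <- matrix(c(0, 1), 2, 1, dimnames = list(c("d1", "d2"), "p1"))
  p <- build_problem(Y, X)
  expect_equal(dim(p$Z), c(2, 2))
  expect_equal(p$Omega, matrix(1, 2, 2))
  expect_equal(p$Z[1, 1], 1)

  p2 <- build_problem(Y, X, test_rows = 2)
  expect_equal(p2$Omega[2, 1], 0)   # Y column excluded for the test drug
  expect_equal(p2$Omega[2, 2], 1)   # X column stays observed
  expect_equal(p2$Z[2, 1], 0)       # held-out labels zeroed

  rownames(X) <- c("d2", "d1")
  expect_error(build_problem(Y, X), "do not match")
})

test_that("weighted_loss follows the positive-unlabelled weighting", {
  set.seed(1)
  Y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  X <- matrix(rbinom(8, 1, 0.5), 4, 2)
  p <- build_problem(Y, X)
  t <- 2
  W0 <- matrix(0, t, 4); H0 <- matrix(0, t, 5)
  n_pos <- sum(p$Z[p$Omega == 1] == 1)
  # zero factors: residual 1 on positives, 0 on zeroes
  expect_equal(weighted_loss(p, W0, H0, 0.8), 0.8 * n_pos)
  # beta = 0.5 halves the unweighted squared error
  W <- matrix(rnorm(2 * 4), 2, 4); H <- matrix(rnorm(2 * 5), 2, 5)
  sse <- sum(p$Omega * (p$Z - crossprod(W, H))^2)
  expect_equal(weighted_loss(p, W, H, 0.5), 0.5 * sse)
  expect_error(weighted_loss(p, W, H, 1.2), "beta")
})

test_that("loss vanishes at an exact reconstruction", {
  set.seed(2)
  W <- matrix(rnorm(2 * 3), 2, 3)
  H <- matrix(rnorm(2 * 4), 2, 4)
  Z <- crossprod(W, H)
  # hand-built problem with real-valued Z, everything observed
  p <- structure(list(Z = Z, Omega = matrix(1, 3, 4), n = 3, c = 2, d = 2,
                      test_rows = integer(0), drug_ids = NULL,
                      se_ids = NULL, target_ids = NULL),
                 class = "cocompletion_problem")
  expect_equal(weighted_loss(p, W, H, 0.7), 0)
  g <- partial_gradients(p, W, H, 0.7)
  expect_equal(g$W, matrix(0, 2, 3))
  expect_equal(g$H, matrix(0, 2, 4))
})

test_that("objective and gradients agree with brute-force loops", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    obj <- gtmcc_objective(inst$problem, inst$W, inst$H, inst$L, inst$hyper)
    expect_equal(obj,
                 naive_objective(inst$problem, inst$W, inst$H, inst$L,
                                 inst$hyper),
                 tolerance = 1e-10)
    g <- partial_gradients(inst$problem, inst$W, inst$H, inst$hyper$beta)
    ng <- naive_gradients(inst$problem, inst$W, inst$H, inst$hyper$beta)
    expect_equal(g$W, ng$W, tolerance = 1e-10)
    expect_equal(g$H, ng$H, tolerance = 1e-10)
  }
})

test_that("gradients match the scalar hand calculation and finite differences", {
  # one drug, one observed positive, w = 0, h = 1, beta = 0.8
  p <- structure(list(Z = matrix(1, 1, 1), Omega = matrix(1, 1, 1),
                      n = 1, c = 1, d = 0, test_rows = integer(0),
                      drug_ids = NULL, se_ids = NULL, target_ids = NULL),
                 class = "cocompletion_problem")
  g <- partial_gradients(p, matrix(0, 1, 1), matrix(1, 1, 1), 0.8)
  expect_equal(g$W[1, 1], -1.6)

  inst <- random_instance(99)
  beta <- inst$hyper$beta
  g <- partial_gradients(inst$problem, inst$W, inst$H, beta)
  eps <- 1e-6
  for (k in 1:5) {
    i <- sample(length(inst$W), 1)
    Wp <- inst$W; Wm <- inst$W
    Wp[i] <- Wp[i] + eps; Wm[i] <- Wm[i] - eps
    fd <- (weighted_loss(inst$problem, Wp, inst$H, beta) -
             weighted_loss(inst$problem, Wm, inst$H, beta)) / (2 * eps)
    expect_equal(g$W[i], fd, tolerance = 1e-5)
  }
})

test_that("proximal maps satisfy their closed forms and stationarity", {
  # prox of the zero function is the identity
  G <- matrix(rnorm(6), 2, 3)
  L0 <- matrix(0, 3, 3)
  expect_equal(prox_w(G, L0, gamma = 0, lambda1 = 0, t_w = 1.7), G)
  # scalar stationarity: w = t_w g / (2 lambda1 + t_w) = 2*4/(2+2)
  expect_equal(prox_w(matrix(4), matrix(0), 0, 1, 2), matrix(2))
  expect_equal(prox_h(matrix(2), lambda2 = 1, t_h = 2), matrix(1))
  expect_equal(prox_h(G, 0, 3.1), G)

  set.seed(8)
  for (rep in 1:20) {
    n <- 5
    A <- matrix(runif(n * n) * (runif(n * n) < 0.5), n, n)
    A <- (A + t(A)) / 2; diag(A) <- 0
    L <- normalized_laplacian(A)
    G <- matrix(rnorm(3 * n), 3, n)
    gamma <- runif(1, 0, 4); lambda1 <- runif(1, 0, 3)
    t_w <- runif(1, 0.5, 5)
    W <- prox_w(G, L, gamma, lambda1, t_w)
    stat <- 2 * gamma * W %*% L + 2 * lambda1 * W + t_w * (W - G)
    expect_lt(norm(stat, "F"), 1e-8)
    # the prox objective at W beats random perturbations
    fobj <- function(M) gamma * sum((M %*% L) * M) + lambda1 * sum(M^2) +
      t_w / 2 * sum((M - G)^2)
    for (j in 1:50) {
      P <- W + matrix(rnorm(length(W), sd = 0.1), nrow(W), ncol(W))
      expect_lte(fobj(W), fobj(P))
    }
  }
})

test_that("step sizes are Lipschitz bounds with a degeneracy floor", {
  s <- step_sizes(matrix(1), matrix(2), beta = 0.8)
  expect_equal(s$t_w, 2 * 0.8 * 4)
  expect_equal(step_sizes(matrix(1), matrix(0), 0.8)$t_w, 1e-8)
  expect_error(step_sizes(matrix(NaN), matrix(1), 0.5), "finite")

  # a prox-gradient step on W with this step never increases the objective
  for (seed in 1:20) {
    inst <- random_instance(seed + 400)
    hy <- inst$hyper
    obj0 <- gtmcc_objective(inst$problem, inst$W, inst$H, inst$L, hy)
    t_w <- step_sizes(inst$W, inst$H, hy$beta)$t_w
    g <- partial_gradients(inst$problem, inst$W, inst$H, hy$beta)
    W1 <- prox_w(inst$W - g$W / t_w, inst$L, hy$gamma, hy$lambda1, t_w)
    obj1 <- gtmcc_objective(inst$problem, W1, inst$H, inst$L, hy)
    expect_lte(obj1, obj0 + 1e-8)
  }
})

test_that("fit is monotone, deterministic, and ignores held-out labels", {
  sim <- simulate_dataset(tiny_scenario(1))
  hy <- gtmcc_hyper(t = 10, max_iters = 120)
  f1 <- gtmcc(sim$Y, sim$X, sim$S, hyper = hy, seed = 3)
  expect_true(all(diff(f1$trace$objective) <= 1e-8))
  f2 <- gtmcc(sim$Y, sim$X, sim$S, hyper = hy, seed = 3)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)

  # transductivity: the Y values of test drugs never enter the fit
  test_rows <- c(2, 9, 17)
  fa <- gtmcc(sim$Y, sim$X, sim$S, hyper = hy, test_rows = test_rows, seed = 5)
  Y_mut <- sim$Y
  Y_mut[test_rows, ] <- 1 - Y_mut[test_rows, ]
  fb <- gtmcc(Y_mut, sim$X, sim$S, hyper = hy, test_rows = test_rows, seed = 5)
  expect_identical(fa$W, fb$W)
  expect_identical(fa$H, fb$H)
})

test_that("with beta = 0.5 and no regularizers PALM reduces to unweighted
          alternating gradient factorization", {
  sim <- simulate_dataset(tiny_scenario(4))
  prob <- build_problem(sim$Y, sim$X)
  hy <- gtmcc_hyper(t = 6, beta = 0.5, gamma = 0, lambda1 = 0, lambda2 = 0,
                    max_iters = 15, rel_tol = 0)
  fit <- gtmcc_fit(prob, matrix(0, prob$n, prob$n), hy, seed = 12)
  ref <- reference_unweighted_palm(prob, t = 6, iters = 15, seed = 12)
  expect_equal(unname(fit$W), unname(ref$W), tolerance = 1e-10)
  expect_equal(unname(fit$H), unname(ref$H), tolerance = 1e-10)
})

test_that("predict returns the requested block of W'H", {
  # two drugs, one side-effect column, one target column, t = 1
  Y <- matrix(0, 2, 1, dimnames = list(c("d1", "d2"), "s1"))
  X <- matrix(0, 2, 1, dimnames = list(c("d1", "d2"), "p1"))
  p <- build_problem(Y, X)
  fit <- structure(list(W = matrix(c(1, 2), 1, 2),
                        H = matrix(c(3, -1), 1, 2),
                        problem = p, hyper = gtmcc_hyper(t = 1),
                        seed = 1L, trace = list()), class = "gtmcc")
  expect_equal(unname(predict_side_effects(fit)), matrix(c(3, 6), 2, 1))
  expect_equal(unname(predict_targets(fit)), matrix(c(-1, -2), 2, 1))
  expect_equal(dim(predict(fit, "side_effects")), c(2, 1))
})

test_that("training positives outscore unobserved zeroes after a fit", {
  sim <- simulate_dataset(tiny_scenario(7))
  hy <- gtmcc_hyper(t = 10, max_iters = 150)
  fit <- gtmcc(sim$Y, sim$X, sim$S, hyper = hy, seed = 7)
  sc <- predict_side_effects(fit)
  expect_gt(mean(sc[sim$Y == 1]), mean(sc[sim$Y == 0]))
  # hidden target positives rank above true zeroes
  expect_gt(heldout_positive_auc(fit, sim, "targets"), 0.5)
})

test_that("fit reports convergence state and objective trace consistently", {
  sim <- simulate_dataset(tiny_scenario(2))
  hy <- gtmcc_hyper(t = 8, max_iters = 400, rel_tol = 1e-7)
  fit <- gtmcc(sim$Y, sim$X, sim$S, hyper = hy, seed = 2)
  expect_length(fit$trace$objective, fit$trace$iterations + 1)
  expect_length(fit$trace$t_w, fit$trace$iterations)
  expect_equal(
    utils::tail(fit$trace$objective, 1),
    gtmcc_objective(fit$problem, fit$W, fit$H, fit$graph$L, hy),
    tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.gtmcc")
  expect_output(print(s), "GTMCC fit summary")
  expect_output(print(fit), "co-completion")
})
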