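# Model fitting by proximal alternating linearized minimization (PALM)
# and the S3 methods of the fitted-model object.

#' Fit a graph-regularized transductive matrix co-completion model
#'
#' Jointly factorizes the concatenated drug association matrix Z = \[Y, X\]
#' as W'H, minimizing the positive-unlabelled weighted squared loss over the
#' observed entries plus a chemical-similarity graph penalty on the drug
#' factors and ridge penalties on both factor blocks:
#'
#' \deqn{\sum_{(i,j)\in\Omega} c_{ij} (Z_{ij} - w_i^\top h_j)^2
#'   + \gamma\,\mathrm{Tr}(W L W^\top)
#'   + \lambda_1 \|W\|_F^2 + \lambda_2 \|H\|_F^2,}
#'
#' with \eqn{c_{ij} = \beta} on observed positives and \eqn{1-\beta} on
#' unobserved entries.  Optimization alternates a gradient step on the
#' smooth loss with the closed-form proximal map of each block's
#' regularizer, using the Lipschitz constants of the partial gradients as
#' step sizes, which makes the objective monotonically non-increasing.
#'
#' The model is transductive: drugs listed in `test_rows` contribute their
#' target columns but none of their side-effect labels, and predictions
#' exist only for drugs present at fit time.
#'
#' @param Y Binary drug x side-effect matrix.
#' @param X Binary drug x target matrix, same drugs in the same order.
#' @param S Symmetric drug chemical-similarity matrix in \[0, 1\] (e.g. from
#'   [tanimoto_matrix()]).
#' @param k_nn Neighbour count for the similarity graph (default 5).
#' @param hyper Hyper-parameters, see [gtmcc_hyper()].
#' @param test_rows Drugs whose side-effect labels are held out.
#' @param seed Integer seed for the factor initialization; required so that
#'   every fit is reproducible.
#' @return An object of class `"gtmcc"`; see [gtmcc_fit()] for its
#'   components.
#' @examples
#' sim <- simulate_dataset(synthetic_scenario(
#'   n = 30, c = 40, d = 20, t_true = 4, seed = 1))
#' fit <- gtmcc(sim$Y, sim$X, sim$S, hyper = gtmcc_hyper(t = 8), seed = 1)
#' fit
#' @export
gtmcc <- function(Y, X, S, k_nn = 5, hyper = gtmcc_hyper(),
                  test_rows = integer(0), seed) {
  if (missing(seed)) stop("an integer seed is required for reproducibility")
  problem <- build_problem(Y, X, test_rows = test_rows)
  graph <- similarity_graph(S, k_nn = k_nn)
  fit <- gtmcc_fit(problem, graph$L, hyper, seed = seed)
  fit$graph <- graph
  fit
}

#' Fit latent factors on a pre-built problem
#'
#' Lower-level entry point taking a [build_problem()] object and a
#' normalized Laplacian directly.  Initialization draws every entry of W
#' and H i.i.d. Gaussian with standard deviation 1/sqrt(t), so the initial
#' scores w_i'h_j are O(1).  Iteration stops when the relative objective
#' change falls below `hyper$rel_tol` or after `hyper$max_iters` outer
#' iterations.
#'
#' @param problem A [build_problem()] object.
#' @param L Normalized graph Laplacian, n x n.
#' @param hyper A [gtmcc_hyper()] object.
#' @param seed Integer seed for initialization.
#' @return An object of class `"gtmcc"`: a list with the factors `W`
#'   (t x n) and `H` (t x (c + d)), the `problem`, `hyper`, `seed`, and a
#'   `trace` list holding the per-iteration `objective` values, the step
#'   sizes `t_w` and `t_h`, the `iterations` run and a `converged` flag.
#' @export
gtmcc_fit <- function(problem, L, hyper = gtmcc_hyper(), seed) {
  if (missing(seed)) stop("an integer seed is required for reproducibility")
  stopifnot(inherits(problem, "cocompletion_problem"),
            inherits(hyper, "gtmcc_hyper"))
  n <- problem$n
  m <- problem$c + problem$d
  if (!all(dim(L) == n)) stop("Laplacian must be ", n, " x ", n)
  t <- hyper$t

  set.seed(as.integer(seed))
  W <- matrix(stats::rnorm(t * n, sd = 1 / sqrt(t)), t, n)
  H <- matrix(stats::rnorm(t * m, sd = 1 / sqrt(t)), t, m)

  # With L, gamma, lambda1 fixed, prox_w solves against
  # 2 gamma L + (2 lambda1 + t_w) I; eigendecompose 2 gamma L once and
  # rescale the spectrum per iteration (t_w changes every iteration).
  eig <- eigen(2 * hyper$gamma * L + 2 * hyper$lambda1 * diag(n),
               symmetric = TRUE)
  prox_w_eig <- function(G, t_w) {
    shrink <- 1 / (eig$values + t_w)
    t_w * (G %*% eig$vectors) %*% (shrink * t(eig$vectors))
  }

  C <- pu_weights(problem$Z, hyper$beta)
  OmC <- problem$Omega * C
  smooth_loss <- function(W, H) {
    sum(OmC * (problem$Z - crossprod(W, H))^2)
  }
  regs <- function(W, H) {
    hyper$gamma * sum((W %*% L) * W) +
      hyper$lambda1 * sum(W^2) + hyper$lambda2 * sum(H^2)
  }

  obj <- numeric(hyper$max_iters + 1)
  tw_trace <- th_trace <- numeric(hyper$max_iters)
  obj[1] <- smooth_loss(W, H) + regs(W, H)
  converged <- FALSE
  iters <- 0

  for (k in seq_len(hyper$max_iters)) {
    # W block: Lipschitz step from current H
    t_w <- max(2 * max(hyper$beta, 1 - hyper$beta) * spectral_norm(H)^2, 1e-8)
    repeat {
      M <- OmC * (crossprod(W, H) - problem$Z)
      G <- W - (2 * H %*% t(M)) / t_w
      W_new <- prox_w_eig(G, t_w)
      if (!hyper$backtrack) break
      if (smooth_loss(W_new, H) + regs(W_new, H) <=
            obj[k] + 1e-12 || t_w > 1e12) break
      t_w <- 2 * t_w
    }
    W <- W_new

    # H block: Lipschitz step from the updated W
    t_h <- max(2 * max(hyper$beta, 1 - hyper$beta) * spectral_norm(W)^2, 1e-8)
    obj_mid <- smooth_loss(W, H) + regs(W, H)
    repeat {
      M <- OmC * (crossprod(W, H) - problem$Z)
      V <- H - (2 * W %*% M) / t_h
      H_new <- prox_h(V, hyper$lambda2, t_h)
      if (!hyper$backtrack) break
      if (smooth_loss(W, H_new) + regs(W, H_new) <=
            obj_mid + 1e-12 || t_h > 1e12) break
      t_h <- 2 * t_h
    }
    H <- H_new

    iters <- k
    tw_trace[k] <- t_w
    th_trace[k] <- t_h
    obj[k + 1] <- smooth_loss(W, H) + regs(W, H)
    if (!is.finite(obj[k + 1])) {
      stop("optimization diverged (non-finite objective) at iteration ", k)
    }
    rel <- abs(obj[k + 1] - obj[k]) / max(obj[k], 1e-12)
    if (rel < hyper$rel_tol) {
      converged <- TRUE
      break
    }
  }

  dimnames(W) <- list(NULL, problem$drug_ids)
  dimnames(H) <- list(NULL, c(problem$se_ids, problem$target_ids))
  structure(
    list(W = W, H = H, problem = problem, hyper = hyper,
         seed = as.integer(seed),
         trace = list(objective = obj[seq_len(iters + 1)],
                      t_w = tw_trace[seq_len(iters)],
                      t_h = th_trace[seq_len(iters)],
                      iterations = iters, converged = converged)),
    class = "gtmcc"
  )
}

#' @export
print.gtmcc <- function(x, ...) {
  p <- x$problem
  cat("Graph-regularized transductive matrix co-completion fit\n")
  cat(sprintf("  drugs: %d, side effects: %d, targets: %d, latent dim: %d\n",
              p$n, p$c, p$d, x$hyper$t))
  cat(sprintf("  beta = %g, gamma = %g, lambda1 = %g, lambda2 = %g\n",
              x$hyper$beta, x$hyper$gamma, x$hyper$lambda1, x$hyper$lambda2))
  cat(sprintf("  %d iterations (%s), final objective %.6g\n",
              x$trace$iterations,
              if (x$trace$converged) "converged" else "max_iters reached",
              utils::tail(x$trace$objective, 1)))
  invisible(x)
}

#' @export
summary.gtmcc <- function(object, ...) {
  p <- object$problem
  scores <- crossprod(object$W, object$H)
  obs <- p$Omega == 1
  pos <- obs & p$Z == 1
  zero <- obs & p$Z == 0
  out <- list(
    dims = c(n = p$n, c = p$c, d = p$d, t = object$hyper$t),
    hyper = object$hyper,
    seed = object$seed,
    iterations = object$trace$iterations,
    converged = object$trace$converged,
    objective = utils::tail(object$trace$objective, 1),
    weighted_loss = weighted_loss(p, object$W, object$H, object$hyper$beta),
    mean_score_observed_pos = mean(scores[pos]),
    mean_score_unobserved = mean(scores[zero]),
    n_test_drugs = length(p$test_rows)
  )
  class(out) <- "summary.gtmcc"
  out
}

#' @export
print.summary.gtmcc <- function(x, ...) {
  cat("GTMCC fit summary\n")
  cat(sprintf("  n = %d drugs, c = %d side effects, d = %d targets, t = %d\n",
              x$dims["n"], x$dims["c"], x$dims["d"], x$dims["t"]))
  cat(sprintf("  seed %d; %d iterations (%s)\n", x$seed, x$iterations,
              if (x$converged) "converged" else "max_iters reached"))
  cat(sprintf("  objective %.6g, weighted loss %.6g\n",
              x$objective, x$weighted_loss))
  cat(sprintf("  mean score on observed positives: %.4f\n",
              x$mean_score_observed_pos))
  cat(sprintf("  mean score on unobserved entries: %.4f\n",
              x$mean_score_unobserved))
  if (x$n_test_drugs > 0) {
    cat(sprintf("  %d transductive test drugs (labels held out)\n",
                x$n_test_drugs))
  }
  invisible(x)
}

#' @export
coef.gtmcc <- function(object, ...) {
  list(W = object$W, H = object$H)
}

#' Predicted association scores
#'
#' Reconstructs the relevant block of W'H.  Higher scores indicate stronger
#' predicted association.  Being transductive, the model only scores drugs
#' present at fit time; there is no `newdata` argument.
#'
#' @param object A fitted [gtmcc()] model.
#' @param type `"side_effects"` for the n x c block, `"targets"` for the
#'   n x d block.
#' @param ... Unused.
#' @return A real score matrix with drug and label identifiers as dimnames.
#' @export
predict.gtmcc <- function(object, type = c("side_effects", "targets"), ...) {
  type <- match.arg(type)
  p <- object$problem
  scores <- crossprod(object$W, object$H)
  if (type == "side_effects") {
    if (p$c < 1) stop("model has no side-effect columns")
    scores[, seq_len(p$c), drop = FALSE]
  } else {
    if (p$d < 1) stop("model has no target columns")
    scores[, p$c + seq_len(p$d), drop = FALSE]
  }
}

#' @rdname predict.gtmcc
#' @param fit A fitted model.
#' @export
predict_side_effects <- function(fit) predict(fit, type = "side_effects")

#' @rdname predict.gtmcc
#' @export
predict_targets <- function(fit) predict(fit, type = "targets")

#' @export
fitted.gtmcc <- function(object, ...) {
  crossprod(object$W, object$H)
}

#' @export
residuals.gtmcc <- function(object, ...) {
  p <- object$problem
  (p$Z - crossprod(object$W, object$H)) * p$Omega
}

#' Objective trace plot
#'
#' Plots the PALM objective value against the iteration number; the curve
#' is non-increasing by construction.
#'
#' @param x A fitted [gtmcc()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gtmcc <- function(x, ...) {
  obj <- x$trace$objective
  graphics::plot(seq_along(obj) - 1, obj, type = "l",
                 xlab = "PALM iteration", ylab = "objective",
                 main = "Co-completion objective", ...)
  invisible(x)
}
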