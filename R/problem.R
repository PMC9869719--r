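# Co-completion problem: Z = [Y, X], observation mask, positive-unlabelled
# weighted loss, objective, partial gradients, proximal maps, step sizes.

#' Build a transductive co-completion problem
#'
#' Concatenates the drug-side-effect matrix Y and the drug-target matrix X
#' into Z = \[Y, X\] and records the observation mask Omega.  All X entries
#' (ones and zeroes) are inside Omega; the Y entries of training drugs are
#' inside Omega; the Y entries of the `test_rows` drugs are zeroed in Z and
#' excluded from the loss entirely, which makes the model transductive:
#' test drugs contribute their target/feature columns but none of their
#' side-effect labels.
#'
#' @param Y Binary drug x side-effect matrix (drugs in rows).
#' @param X Binary drug x target matrix with the same rows in the same
#'   order as `Y`.
#' @param test_rows Integer indices of drugs whose side-effect labels are
#'   held out (default none).
#' @return An object of class `"cocompletion_problem"`: a list with `Z`,
#'   `Omega`, `n`, `c`, `d`, `test_rows` and the identifier registries
#'   `drug_ids`, `se_ids`, `target_ids`.
#' @export
build_problem <- function(Y, X, test_rows = integer(0)) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) {
    stop("Y and X must have the same number of drugs (rows): ",
         nrow(Y), " vs ", nrow(X))
  }
  if (!is.null(rownames(Y)) && !is.null(rownames(X)) &&
      !identical(rownames(Y), rownames(X))) {
    stop("drug identifiers of Y and X do not match; align the rows first")
  }
  check_binary(Y, "Y")
  check_binary(X, "X")
  n <- nrow(Y); cc <- ncol(Y); d <- ncol(X)
  test_rows <- sort(unique(as.integer(test_rows)))
  if (length(test_rows) && (min(test_rows) < 1 || max(test_rows) > n)) {
    stop("test_rows out of range 1..", n)
  }
  Z <- cbind(Y, X)
  Omega <- matrix(1, n, cc + d)
  if (length(test_rows)) {
    Omega[test_rows, seq_len(cc)] <- 0
    Z[test_rows, seq_len(cc)] <- 0
  }
  structure(
    list(Z = Z, Omega = Omega, n = n, c = cc, d = d, test_rows = test_rows,
         drug_ids = rownames(Y), se_ids = colnames(Y), target_ids = colnames(X)),
    class = "cocompletion_problem"
  )
}

#' @export
print.cocompletion_problem <- function(x, ...) {
  cat("Transductive co-completion problem Z = [Y, X]\n")
  cat("  drugs (n):        ", x$n, "\n")
  cat("  side effects (c): ", x$c, "\n")
  cat("  targets (d):      ", x$d, "\n")
  cat("  held-out drugs:   ", length(x$test_rows), "\n")
  cat("  observed entries: ", sum(x$Omega), "of", length(x$Omega), "\n")
  invisible(x)
}

#' Hyper-parameters of the co-completion model
#'
#' Defaults are the selections of the sensitivity analysis on the real
#' corpus: latent dimension `t = 400`, positive weight `beta = 0.8`, graph
#' weight `gamma = 10`, and ridge penalties `lambda1 = 2`, `lambda2 = 1`.
#' `beta` is the weight on observed-positive squared errors; unobserved
#' entries get `1 - beta`, the positive-unlabelled (biased completion)
#' device.  For desk-scale synthetic problems a much smaller `t` is
#' appropriate (see the methods vignette).
#'
#' @param t Latent dimension (columns of Z are scored as w_i' h_j with
#'   w, h in R^t).
#' @param beta Weight on observed positives, strictly inside (0, 1).
#' @param gamma Graph-Laplacian regularization weight (>= 0).
#' @param lambda1,lambda2 Frobenius (ridge) penalties on W and H (>= 0).
#' @param max_iters Maximum number of PALM outer iterations.
#' @param rel_tol Relative objective-change stopping tolerance.
#' @param backtrack If `TRUE`, double a step size and redo the block update
#'   whenever an update increases the objective (a robustness guard; the
#'   Lipschitz steps make this a no-op in ordinary runs).
#' @return A list of class `"gtmcc_hyper"`.
#' @export
gtmcc_hyper <- function(t = 400, beta = 0.8, gamma = 10,
                        lambda1 = 2, lambda2 = 1,
                        max_iters = 500, rel_tol = 1e-6,
                        backtrack = FALSE) {
  if (t < 1 || t != round(t)) stop("t must be a positive integer")
  if (beta <= 0 || beta >= 1) stop("beta must lie strictly inside (0, 1)")
  if (gamma < 0 || lambda1 < 0 || lambda2 < 0) {
    stop("gamma, lambda1, lambda2 must be >= 0")
  }
  if (max_iters < 1) stop("max_iters must be >= 1")
  structure(
    list(t = as.integer(t), beta = beta, gamma = gamma,
         lambda1 = lambda1, lambda2 = lambda2,
         max_iters = as.integer(max_iters), rel_tol = rel_tol,
         backtrack = isTRUE(backtrack)),
    class = "gtmcc_hyper"
  )
}

# per-entry PU weights: beta on observed positives, (1-beta) on unobserved
pu_weights <- function(Z, beta) {
  ifelse(Z == 1, beta, 1 - beta)
}

#' Positive-unlabelled weighted squared loss
#'
#' The smooth data-fit term: sum over observed entries (i, j) in Omega of
#' `[beta 1(Z_ij = 1) + (1 - beta) 1(Z_ij = 0)] (Z_ij - w_i' h_j)^2`.
#'
#' @param problem A [build_problem()] object.
#' @param W Latent drug factors, t x n.
#' @param H Latent label/feature factors, t x (c + d).
#' @param beta Positive weight in (0, 1).
#' @return Non-negative scalar.
#' @export
weighted_loss <- function(problem, W, H, beta) {
  if (beta <= 0 || beta >= 1) stop("beta must lie strictly inside (0, 1)")
  check_factor_shapes(problem, W, H)
  P <- crossprod(W, H)
  sum(problem$Omega * pu_weights(problem$Z, beta) * (problem$Z - P)^2)
}

#' Full co-completion objective
#'
#' `weighted_loss + gamma Tr(W L W') + lambda1 ||W||_F^2 + lambda2 ||H||_F^2`.
#'
#' @inheritParams weighted_loss
#' @param L Normalized graph Laplacian, n x n (see
#'   [normalized_laplacian()]).
#' @param hyper A [gtmcc_hyper()] object.
#' @return Scalar objective value.
#' @export
gtmcc_objective <- function(problem, W, H, L, hyper) {
  check_factor_shapes(problem, W, H)
  if (!all(dim(L) == problem$n)) {
    stop("Laplacian must be n x n with n = ", problem$n)
  }
  weighted_loss(problem, W, H, hyper$beta) +
    hyper$gamma * sum((W %*% L) * W) +
    hyper$lambda1 * sum(W^2) +
    hyper$lambda2 * sum(H^2)
}

#' Partial gradients of the smooth weighted loss
#'
#' Gradients of the data-fit term only; the regularizers are handled by the
#' proximal maps.  With M = Omega * C * (W'H - Z) the gradients are
#' `dW = 2 H M'` and `dH = 2 W M`, where C holds the beta / (1 - beta)
#' entry weights.
#'
#' @inheritParams weighted_loss
#' @return A list with components `W` (t x n) and `H` (t x (c + d)).
#' @export
partial_gradients <- function(problem, W, H, beta) {
  check_factor_shapes(problem, W, H)
  P <- crossprod(W, H)
  M <- problem$Omega * pu_weights(problem$Z, beta) * (P - problem$Z)
  list(W = 2 * H %*% t(M), H = 2 * W %*% M)
}

#' Proximal map of the drug-factor regularizer
#'
#' Unique minimizer of
#' `gamma Tr(W L W') + lambda1 ||W||_F^2 + (t_w / 2) ||W - G||_F^2`,
#' i.e. `W = t_w G (2 gamma L + (2 lambda1 + t_w) I)^(-1)`, computed by a
#' linear solve against the symmetric positive-definite system rather than
#' explicit inversion.
#'
#' @param G Gradient-step point, t x n.
#' @param L Normalized Laplacian, n x n.
#' @param gamma,lambda1 Regularization weights (>= 0).
#' @param t_w Step size (> 0).
#' @return t x n matrix.
#' @export
prox_w <- function(G, L, gamma, lambda1, t_w) {
  if (t_w <= 0) stop("t_w must be > 0")
  n <- ncol(G)
  if (!all(dim(L) == n)) stop("L must be ", n, " x ", n)
  M <- 2 * gamma * L + diag(2 * lambda1 + t_w, n)
  # M is SPD for t_w > 0; solve M W' = t_w G'
  t_w * t(solve(M, t(G)))
}

#' Proximal map of the label-factor ridge
#'
#' Minimizer of `lambda2 ||H||_F^2 + (t_h / 2) ||H - V||_F^2`, i.e. the
#' elementwise shrinkage `H = t_h V / (2 lambda2 + t_h)`.
#'
#' @param V Gradient-step point.
#' @param lambda2 Ridge weight (>= 0).
#' @param t_h Step size (> 0).
#' @return Matrix of the same shape as `V`.
#' @export
prox_h <- function(V, lambda2, t_h) {
  if (t_h <= 0) stop("t_h must be > 0")
  t_h * V / (2 * lambda2 + t_h)
}

#' Lipschitz step sizes for the PALM block updates
#'
#' The partial gradient of the weighted loss in W is Lipschitz with
#' constant `2 max(beta, 1 - beta) sigma_max(H)^2` (and symmetrically for
#' H), since every entry weight is bounded by max(beta, 1 - beta).  Each
#' step size is floored at 1e-8 to guard the degenerate all-zero factor
#' case.
#'
#' @param W,H Current factors.
#' @param beta Positive weight in (0, 1).
#' @return A list with `t_w` and `t_h`.
#' @export
step_sizes <- function(W, H, beta) {
  if (!all(is.finite(W)) || !all(is.finite(H))) {
    stop("factors must be finite")
  }
  s <- 2 * max(beta, 1 - beta)
  list(t_w = max(s * spectral_norm(H)^2, 1e-8),
       t_h = max(s * spectral_norm(W)^2, 1e-8))
}

# largest singular value; norm(, "2") on the smaller Gram side
spectral_norm <- function(X) {
  if (all(X == 0)) return(0)
  norm(X, type = "2")
}

check_factor_shapes <- function(problem, W, H) {
  if (ncol(W) != problem$n) {
    stop("W must have one column per drug (", problem$n, "), got ", ncol(W))
  }
  if (ncol(H) != problem$c + problem$d) {
    stop("H must have c + d = ", problem$c + problem$d,
         " columns, got ", ncol(H))
  }
  if (nrow(W) != nrow(H)) {
    stop("W and H must share the latent dimension t")
  }
  invisible(TRUE)
}
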