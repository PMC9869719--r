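# Seeded synthetic data: jointly low-rank binary association matrices with
# positive-unlabelled masking and a consistent chemical-similarity matrix.
#
# All randomness flows from the scenario seed through fixed offsets:
# seed + 0 for the generating factors, seed + 1 for similarity noise,
# seed + 2 for the positive-unlabelled mask.

#' Define a synthetic co-completion scenario
#'
#' @param n,c,d Numbers of drugs, side effects and targets.
#' @param t_true Ground-truth rank of the concatenated matrix.
#' @param positive_density Fraction of ones in the ground-truth Z.
#' @param observe_frac Probability that a true positive is revealed in the
#'   observed matrices (positive-unlabelled masking).
#' @param similarity_noise Standard deviation of the symmetric perturbation
#'   added to the factor-derived similarity matrix; 0 makes the graph
#'   assumption (similar drugs share latent factors) hold exactly.
#' @param seed Integer master seed.
#' @return A list of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(n, c, d, t_true,
                               positive_density = 0.06,
                               observe_frac = 1,
                               similarity_noise = 0,
                               seed) {
  if (t_true > min(n, c + d)) {
    stop("t_true must not exceed min(n, c + d)")
  }
  if (positive_density <= 0 || positive_density >= 1) {
    stop("positive_density must lie in (0, 1)")
  }
  if (observe_frac <= 0 || observe_frac > 1) {
    stop("observe_frac must lie in (0, 1]")
  }
  if (similarity_noise < 0) stop("similarity_noise must be >= 0")
  structure(
    list(n = as.integer(n), c = as.integer(c), d = as.integer(d),
         t_true = as.integer(t_true),
         positive_density = positive_density,
         observe_frac = observe_frac,
         similarity_noise = similarity_noise,
         seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' Desk-scale scenario mirroring the real corpus shape
#'
#' A scaled-down analogue of a drug/side-effect/target corpus: 120 drugs,
#' 200 side effects, 100 targets, true rank 10, and a positive density of
#' 0.06 so that roughly 94% of the side-effect block is zero — the same
#' order of sparsity as real side-effect data.  Positives are revealed with
#' probability 0.5 and the similarity matrix is noise-free.
#'
#' @param seed Integer seed (default 1).
#' @return A [synthetic_scenario()] object.
#' @export
paper_shape_scenario <- function(seed = 1) {
  synthetic_scenario(n = 120, c = 200, d = 100, t_true = 10,
                     positive_density = 0.06, observe_frac = 0.5,
                     similarity_noise = 0, seed = seed)
}

#' Generate the low-rank binary ground truth and similarity matrix
#'
#' Draws Gaussian factors W_true (t x n) and H_true (t x (c + d)), sets
#' Z_true = 1 where W_true' H_true exceeds its (1 - density) quantile, and
#' derives the drug similarity matrix from the cosine similarity of the
#' W_true columns mapped to \[0, 1\] — so drugs with similar latent factors
#' really are "chemically" similar and the graph regularizer's assumption
#' holds by construction.  Optional symmetric Gaussian noise of magnitude
#' `similarity_noise` is added and the matrix re-symmetrized and clipped.
#'
#' @param scenario A [synthetic_scenario()] object.
#' @return A list of class `"gtmcc_sim"` with `Z_true`, `Y_true`, `X_true`,
#'   `S`, `W_true`, `H_true` and the `scenario`.  Observed matrices are
#'   added by [apply_pu_mask()].
#' @export
generate_ground_truth <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n; cc <- scenario$c; d <- scenario$d; t <- scenario$t_true

  set.seed(scenario$seed)
  W <- matrix(stats::rnorm(t * n), t, n)
  H <- matrix(stats::rnorm(t * (cc + d)), t, cc + d)
  M <- crossprod(W, H)
  thr <- stats::quantile(M, 1 - scenario$positive_density, names = FALSE)
  if (thr >= max(M)) {
    stop("degenerate quantile threshold; positive_density infeasible")
  }
  Z <- (M > thr) * 1

  # cosine similarity of latent drug factors mapped to [0, 1]
  nrm <- sqrt(colSums(W^2))
  cosine <- crossprod(W) / (nrm %o% nrm)
  S <- (cosine + 1) / 2
  if (scenario$similarity_noise > 0) {
    set.seed(scenario$seed + 1L)
    E <- matrix(stats::rnorm(n * n, sd = scenario$similarity_noise), n, n)
    S <- S + (E + t(E)) / 2
  }
  S <- pmin(pmax((S + t(S)) / 2, 0), 1)
  diag(S) <- 1

  drug_ids <- sprintf("D%04d", seq_len(n))
  se_ids <- sprintf("SE%04d", seq_len(cc))
  target_ids <- sprintf("T%04d", seq_len(d))
  dimnames(Z) <- list(drug_ids, c(se_ids, target_ids))
  dimnames(S) <- list(drug_ids, drug_ids)

  structure(
    list(Z_true = Z,
         Y_true = Z[, seq_len(cc), drop = FALSE],
         X_true = Z[, cc + seq_len(d), drop = FALSE],
         S = S, W_true = W, H_true = H, scenario = scenario),
    class = "gtmcc_sim"
  )
}

#' Apply positive-unlabelled masking to a synthetic ground truth
#'
#' Each true positive of Z_true is revealed independently with probability
#' `observe_frac`; zeroes are never flipped, so the observed matrices
#' contain no false positives.  The hidden positives are recorded as the
#' evaluation ground truth.
#'
#' @param dataset A [generate_ground_truth()] result.
#' @param observe_frac Reveal probability (default: the scenario's value).
#' @param seed Masking seed (default: scenario seed + 2).
#' @return The dataset with `Y`, `X` (observed blocks) and
#'   `hidden_positives` (two-column index matrix into Z_true) added.
#' @export
apply_pu_mask <- function(dataset, observe_frac = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "gtmcc_sim"))
  sc <- dataset$scenario
  if (is.null(observe_frac)) observe_frac <- sc$observe_frac
  if (observe_frac <= 0 || observe_frac > 1) {
    stop("observe_frac must lie in (0, 1]")
  }
  if (is.null(seed)) seed <- sc$seed + 2L
  Z <- dataset$Z_true
  pos <- which(Z == 1, arr.ind = TRUE)
  set.seed(as.integer(seed))
  keep <- stats::runif(nrow(pos)) < observe_frac
  Z_obs <- Z
  Z_obs[pos[!keep, , drop = FALSE]] <- 0
  dataset$Y <- Z_obs[, seq_len(sc$c), drop = FALSE]
  dataset$X <- Z_obs[, sc$c + seq_len(sc$d), drop = FALSE]
  dataset$hidden_positives <- pos[!keep, , drop = FALSE]
  dataset
}

#' Generate a complete synthetic dataset in one call
#'
#' [generate_ground_truth()] followed by [apply_pu_mask()].
#'
#' @param scenario A [synthetic_scenario()] object.
#' @return A `"gtmcc_sim"` list with both the ground truth and the observed
#'   matrices.
#' @export
simulate_dataset <- function(scenario) {
  apply_pu_mask(generate_ground_truth(scenario))
}

#' @export
print.gtmcc_sim <- function(x, ...) {
  sc <- x$scenario
  cat("Synthetic co-completion dataset\n")
  cat(sprintf("  n = %d drugs, c = %d side effects, d = %d targets, rank %d\n",
              sc$n, sc$c, sc$d, sc$t_true))
  cat(sprintf("  positive density %.3f, observe_frac %.2f, seed %d\n",
              mean(x$Z_true), sc$observe_frac, sc$seed))
  if (!is.null(x$hidden_positives)) {
    cat(sprintf("  hidden positives: %d of %d\n",
                nrow(x$hidden_positives), sum(x$Z_true)))
  }
  invisible(x)
}

#' Held-out-positive AUC on a synthetic dataset
#'
#' Scores the hidden positives of one block of a synthetic dataset against
#' every true-zero entry of that block, using a fitted model's
#' reconstruction.  This is the generator's recovery yardstick: a fit that
#' has learned the low-rank structure ranks hidden positives far above
#' true zeroes.
#'
#' @param fit A fitted [gtmcc()] / [gtmcc_fit()] model.
#' @param dataset The `"gtmcc_sim"` dataset the fit was trained on.
#' @param block `"side_effects"` (Y block) or `"targets"` (X block).
#' @return AUC of hidden positives versus true zeroes of the block.
#' @export
heldout_positive_auc <- function(fit, dataset,
                                 block = c("side_effects", "targets")) {
  block <- match.arg(block)
  stopifnot(inherits(dataset, "gtmcc_sim"))
  if (is.null(dataset$hidden_positives)) {
    stop("dataset has no hidden positives; apply_pu_mask() first")
  }
  sc <- dataset$scenario
  cols <- if (block == "side_effects") seq_len(sc$c) else sc$c + seq_len(sc$d)
  scores <- fitted(fit)
  hp <- dataset$hidden_positives
  hp <- hp[hp[, 2] %in% cols, , drop = FALSE]
  if (nrow(hp) == 0) stop("no hidden positives in the ", block, " block")
  zero_idx <- which(dataset$Z_true[, cols, drop = FALSE] == 0, arr.ind = TRUE)
  zero_idx[, 2] <- zero_idx[, 2] + if (block == "targets") sc$c else 0L
  labels <- rep(c(1, 0), c(nrow(hp), nrow(zero_idx)))
  auc_rank(labels, c(scores[hp], scores[zero_idx]))
}
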