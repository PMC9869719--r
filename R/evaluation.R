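# Cross-validation protocols and multi-label ranking metrics.
#
# Local CV masks all side-effect labels of held-out drugs (cold-start);
# global CV masks a random tenth of the known (drug, side effect) pairs;
# target CV does the same on the drug-target block.  Metrics: AUC, average
# precision, label-ranking average precision, coverage error, ranking loss.

#' Drug-wise (local) cross-validation folds
#'
#' Partitions the drugs into `n_folds` near-equal random subsets.  Each
#' fold's drugs become the transductive `test_rows` of the fitting problem:
#' all of their side-effect labels are masked, imitating prediction for
#' novel drugs.
#'
#' @param n_drugs Number of drugs.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list of fold specifications, each a list with `fold_id`,
#'   `mode = "local"`, `test_items` (sorted drug indices) and `seed`.
#' @export
local_cv_folds <- function(n_drugs, n_folds = 10, seed) {
  if (n_folds > n_drugs) {
    stop("n_folds (", n_folds, ") exceeds the number of drugs (", n_drugs, ")")
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n_drugs)
  assign <- fold_assignment(n_drugs, n_folds)
  lapply(seq_len(n_folds), function(f) {
    list(fold_id = f, mode = "local",
         test_items = sort(perm[assign == f]), seed = as.integer(seed))
  })
}

#' Pair-wise (global) cross-validation folds
#'
#' Partitions the known positive (drug, label) pairs into `n_folds`
#' near-equal random subsets.  Each fold's pairs are set to zero during
#' fitting (so the model sees them as unobserved, weight 1 - beta) and used
#' as test positives afterwards.
#'
#' @param positive_entries Two-column integer matrix of (row, col) indices
#'   of the known positives.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list of fold specifications with `test_items` a two-column
#'   index matrix.
#' @export
global_cv_folds <- function(positive_entries, n_folds = 10, seed) {
  positive_entries <- as.matrix(positive_entries)
  np <- nrow(positive_entries)
  if (np < n_folds) {
    stop("fewer positive pairs (", np, ") than folds (", n_folds, ")")
  }
  set.seed(as.integer(seed))
  perm <- sample.int(np)
  assign <- fold_assignment(np, n_folds)
  lapply(seq_len(n_folds), function(f) {
    idx <- sort(perm[assign == f])
    list(fold_id = f, mode = "global",
         test_items = positive_entries[idx, , drop = FALSE],
         seed = as.integer(seed))
  })
}

# sizes differing by at most 1: the first (n %% k) folds get the extra item
fold_assignment <- function(n, k) {
  rep(seq_len(k), times = tabulate(rep_len(seq_len(k), n), nbins = k))
}

#' Sample unobserved entries as negatives
#'
#' Draws `n_required` distinct zero-entries of `Y`, excluding any entries
#' listed in `exclude`.  Used to balance test positives 1:1 with sampled
#' negatives in the global and target protocols.
#'
#' @param Y Binary matrix.
#' @param n_required Number of negatives to draw.
#' @param exclude Optional two-column index matrix of entries that must not
#'   be drawn.
#' @param seed Integer seed.
#' @return Two-column integer matrix of (row, col) indices.
#' @export
sample_negatives <- function(Y, n_required, exclude = NULL, seed) {
  zeros <- which(Y == 0)
  if (!is.null(exclude) && nrow(exclude <- as.matrix(exclude)) > 0) {
    excl_lin <- (exclude[, 2] - 1) * nrow(Y) + exclude[, 1]
    zeros <- setdiff(zeros, excl_lin)
  }
  if (length(zeros) < n_required) {
    stop("only ", length(zeros), " eligible zero entries; need ", n_required)
  }
  set.seed(as.integer(seed))
  chosen <- sample(zeros, n_required)
  cbind(row = (chosen - 1) %% nrow(Y) + 1,
        col = (chosen - 1) %/% nrow(Y) + 1)
}

#' AUC and average precision for a binary labelling
#'
#' AUC is the rank-based (Mann-Whitney) area under the ROC curve with tied
#' positive/negative score pairs receiving half credit.  Average precision
#' summarizes the precision-recall curve as `sum (R_k - R_{k-1}) P_k` over
#' the distinct score thresholds taken in decreasing order, so tied scores
#' enter as a single threshold.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Real score vector of the same length.
#' @return A list with `auc` and `ap`.
#' @export
binary_metrics <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  check_binary(labels, "labels")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop("both classes must be present to compute AUC/AP")
  }
  list(auc = auc_rank(labels, scores), ap = average_precision(labels, scores))
}

# Mann-Whitney AUC via mean ranks; ties get half credit automatically
auc_rank <- function(labels, scores) {
  r <- rank(scores, ties.method = "average")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

# step-wise interpolation-free AP over distinct decreasing thresholds
average_precision <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  pred <- seq_along(lab)
  # keep only the last position of each tied-score run
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[last]
  pred <- pred[last]
  recall <- tp / sum(labels)
  precision <- tp / pred
  sum(diff(c(0, recall)) * precision)
}

#' Multi-label ranking metrics
#'
#' Row-wise label-ranking average precision (LRAP), coverage error and
#' ranking loss, averaged over the rows of `Y_true`.
#'
#' For each sample, a label's rank is the number of labels scored at or
#' above it (ranks start at 1).  LRAP averages, over the true labels, the
#' fraction of labels ranked at or above that label which are themselves
#' true.  Coverage error is the deepest rank over the true labels — how far
#' down the predicted ranking one must go to cover every true label.
#' Ranking loss is the fraction of (true, false) label pairs ordered
#' incorrectly, with score ties counted as half an inversion (the same
#' convention as the AUC).
#'
#' Rows with no true label are skipped for all three metrics (LRAP and
#' coverage are undefined there), as are rows with no false label for the
#' ranking loss; a message reports how many rows were skipped.
#'
#' @param Y_true Binary matrix of true labels (samples x labels).
#' @param scores Real score matrix of the same shape.
#' @return A list with `lrap`, `co_error`, `rloss` and `n_skipped` (rows
#'   without any true label).
#' @export
ranking_metrics <- function(Y_true, scores) {
  Y_true <- as.matrix(Y_true)
  scores <- as.matrix(scores)
  if (!all(dim(Y_true) == dim(scores))) stop("shape mismatch")
  check_binary(Y_true, "Y_true")
  lrap <- cov <- rl <- numeric(0)
  skipped <- 0
  for (i in seq_len(nrow(Y_true))) {
    y <- Y_true[i, ]
    s <- scores[i, ]
    pos <- which(y == 1)
    if (length(pos) == 0) {
      skipped <- skipped + 1
      next
    }
    # rank_j = #{k : s_k >= s_j}; L_j = #{true k : s_k >= s_j}
    rnk <- vapply(pos, function(j) sum(s >= s[j]), numeric(1))
    Lj <- vapply(pos, function(j) sum(s[pos] >= s[j]), numeric(1))
    lrap <- c(lrap, mean(Lj / rnk))
    cov <- c(cov, max(rnk))
    if (length(pos) < length(y)) {
      rl <- c(rl, 1 - auc_rank(y, s))
    }
  }
  if (length(lrap) == 0) {
    stop("every row lacks a true label; ranking metrics undefined")
  }
  if (skipped > 0) {
    message(skipped, " row(s) without any true label skipped")
  }
  list(lrap = mean(lrap), co_error = mean(cov), rloss = mean(rl),
       n_skipped = skipped)
}

#' Local (cold-start drug) cross-validation
#'
#' For each repeat and fold: hold out the fold's drugs as transductive test
#' rows, fit the model, score their side-effect block, and compute all five
#' metrics — AUC and AP over the flattened held-out block, and the
#' multi-label LRAP, coverage error and ranking loss over its rows.
#'
#' Repeat r uses seed `seed + r - 1` for its fold partition, so any single
#' repeat is reproducible in isolation.
#'
#' @param Y,X,S Binary association matrices and drug similarity matrix.
#' @param hyper A [gtmcc_hyper()] object.
#' @param k_nn Similarity-graph neighbour count.
#' @param n_folds,n_repeats Protocol size (paper protocol: 10 and 10).
#' @param seed Master seed.
#' @return A data.frame with one row per repeat x fold: `repeat_id`,
#'   `fold_id`, `mode`, `auc`, `ap`, `lrap`, `co_error`, `rloss`.
#' @export
run_local_cv <- function(Y, X, S, hyper = gtmcc_hyper(), k_nn = 5,
                         n_folds = 10, n_repeats = 1, seed) {
  graph <- similarity_graph(S, k_nn = k_nn)
  out <- list()
  for (r in seq_len(n_repeats)) {
    rep_seed <- as.integer(seed) + r - 1
    folds <- local_cv_folds(nrow(Y), n_folds, seed = rep_seed)
    for (fs in folds) {
      prob <- build_problem(Y, X, test_rows = fs$test_items)
      fit <- gtmcc_fit(prob, graph$L, hyper,
                       seed = rep_seed * 131 + fs$fold_id)
      sc <- predict_side_effects(fit)[fs$test_items, , drop = FALSE]
      truth <- Y[fs$test_items, , drop = FALSE]
      bm <- binary_metrics(as.vector(truth), as.vector(sc))
      rm <- suppressMessages(ranking_metrics(truth, sc))
      out[[length(out) + 1]] <- data.frame(
        repeat_id = r, fold_id = fs$fold_id, mode = "local",
        auc = bm$auc, ap = bm$ap, lrap = rm$lrap,
        co_error = rm$co_error, rloss = rm$rloss)
    }
  }
  do.call(rbind, out)
}

#' Global (masked-pair) cross-validation
#'
#' For each repeat and fold: zero out the fold's known (drug, side effect)
#' pairs, fit on the remainder, then score the masked positives against an
#' equal number of sampled unobserved entries (negative:positive ratio 1).
#' Only AUC and AP are computed; the multi-label metrics are specific to
#' whole-row (local) evaluation.
#'
#' @inheritParams run_local_cv
#' @return A data.frame with columns `repeat_id`, `fold_id`, `mode`,
#'   `auc`, `ap`.
#' @export
run_global_cv <- function(Y, X, S, hyper = gtmcc_hyper(), k_nn = 5,
                          n_folds = 10, n_repeats = 1, seed) {
  graph <- similarity_graph(S, k_nn = k_nn)
  positives <- which(Y == 1, arr.ind = TRUE)
  out <- list()
  for (r in seq_len(n_repeats)) {
    rep_seed <- as.integer(seed) + r - 1
    folds <- global_cv_folds(positives, n_folds, seed = rep_seed)
    for (fs in folds) {
      Y_train <- Y
      Y_train[fs$test_items] <- 0
      prob <- build_problem(Y_train, X)
      fit <- gtmcc_fit(prob, graph$L, hyper,
                       seed = rep_seed * 131 + fs$fold_id)
      sc <- predict_side_effects(fit)
      neg <- sample_negatives(Y, nrow(fs$test_items),
                              seed = rep_seed * 977 + fs$fold_id)
      labels <- rep(c(1, 0), c(nrow(fs$test_items), nrow(neg)))
      scores <- c(sc[fs$test_items], sc[neg])
      bm <- binary_metrics(labels, scores)
      out[[length(out) + 1]] <- data.frame(
        repeat_id = r, fold_id = fs$fold_id, mode = "global",
        auc = bm$auc, ap = bm$ap)
    }
  }
  do.call(rbind, out)
}

#' Target-imputation cross-validation
#'
#' Masks one tenth (for `n_folds = 10`) of the known drug-target pairs per
#' fold, trains with all side-effect data plus the remaining target pairs,
#' and scores the masked target positives against an equal number of
#' sampled unobserved target entries.
#'
#' @inheritParams run_local_cv
#' @return A data.frame with columns `fold_id`, `mode`, `auc`, `ap`.
#' @export
run_target_cv <- function(Y, X, S, hyper = gtmcc_hyper(), k_nn = 5,
                          n_folds = 10, seed) {
  graph <- similarity_graph(S, k_nn = k_nn)
  positives <- which(X == 1, arr.ind = TRUE)
  folds <- global_cv_folds(positives, n_folds, seed = as.integer(seed))
  out <- list()
  for (fs in folds) {
    X_train <- X
    X_train[fs$test_items] <- 0
    prob <- build_problem(Y, X_train)
    fit <- gtmcc_fit(prob, graph$L, hyper,
                     seed = as.integer(seed) * 131 + fs$fold_id)
    sc <- predict_targets(fit)
    neg <- sample_negatives(X, nrow(fs$test_items),
                            seed = as.integer(seed) * 977 + fs$fold_id)
    labels <- rep(c(1, 0), c(nrow(fs$test_items), nrow(neg)))
    scores <- c(sc[fs$test_items], sc[neg])
    bm <- binary_metrics(labels, scores)
    out[[length(out) + 1]] <- data.frame(
      fold_id = fs$fold_id, mode = "target", auc = bm$auc, ap = bm$ap)
  }
  do.call(rbind, out)
}

#' Summarize metric reports as mean +/- standard deviation
#'
#' @param reports A data.frame from one of the `run_*_cv()` functions.
#' @return A data.frame with one row per metric: `metric`, `mean`, `sd`.
#' @export
summarize_metrics <- function(reports) {
  metric_cols <- intersect(c("auc", "ap", "lrap", "co_error", "rloss"),
                           names(reports))
  data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(reports[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(reports[[m]]), numeric(1)),
    row.names = NULL
  )
}
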