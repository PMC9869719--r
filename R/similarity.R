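# Chemical-similarity graph: Tanimoto similarities, kNN adjacency,
# normalized graph Laplacian.

#' Tanimoto similarity between two binary fingerprint vectors
#'
#' Computes the Tanimoto (Jaccard) coefficient |a AND b| / |a OR b|, the
#' standard measure of chemical similarity between binary substructure
#' fingerprints.  Two all-zero fingerprints are defined to have similarity 0:
#' absence of any set bit carries no evidence of shared substructure.
#'
#' @param a,b Numeric or integer vectors of equal length with entries 0/1.
#' @return A single number in \[0, 1\].
#' @examples
#' tanimoto_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  check_binary(a, "a")
  check_binary(b, "b")
  union <- sum(a | b)
  if (union == 0) return(0)
  sum(a & b) / union
}

#' Pairwise Tanimoto similarity matrix
#'
#' Builds the n x n drug chemical-similarity matrix from a fingerprint table
#' (drugs in rows, fingerprint bits in columns).  The diagonal is 1 for every
#' drug with at least one set bit and 0 for empty fingerprints.
#'
#' Computed via bit-count algebra: for binary rows,
#' |a AND b| = a . b and |a OR b| = |a| + |b| - a . b.
#'
#' @param fingerprints Binary matrix, one row per drug; row names are used as
#'   drug identifiers when present.
#' @return Symmetric n x n matrix of Tanimoto similarities with the drug
#'   identifiers as dimnames.
#' @seealso [tanimoto_similarity()], [read_fingerprints()]
#' @export
tanimoto_matrix <- function(fingerprints) {
  fingerprints <- as.matrix(fingerprints)
  if (nrow(fingerprints) < 2) {
    stop("need at least two drugs to build a similarity matrix")
  }
  check_binary(fingerprints, "fingerprints")
  storage.mode(fingerprints) <- "double"
  inter <- tcrossprod(fingerprints)          # |a AND b|
  sz <- diag(inter)                          # |a|
  union <- outer(sz, sz, "+") - inter        # |a OR b|
  S <- ifelse(union > 0, inter / union, 0)
  # exact symmetry despite floating point
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(fingerprints), rownames(fingerprints))
  S
}

#' k-nearest-neighbour adjacency from a similarity matrix
#'
#' Keeps the edge (i, j) with weight `S[i, j]` whenever j is among the
#' `k_nn` drugs most similar to i *or* i is among the `k_nn` most similar to
#' j (union symmetrization), and zeroes everything else including the
#' diagonal.  The union rule is used rather than mutual kNN because mutual
#' kNN can disconnect outlier drugs from the graph entirely.  Ties at the
#' neighbour boundary are broken by ascending drug index so results are
#' platform-independent.
#'
#' @param S Symmetric similarity matrix.
#' @param k_nn Number of neighbours per drug (default 5).  Values >= n are
#'   clamped to n - 1 with a warning.
#' @return Sparse-patterned (but densely stored) symmetric adjacency matrix
#'   with zero diagonal.
#' @export
knn_adjacency <- function(S, k_nn = 5) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (ncol(S) != n) stop("similarity matrix must be square")
  if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix must be symmetric")
  if (k_nn < 1) stop("k_nn must be >= 1")
  if (k_nn >= n) {
    warning("k_nn = ", k_nn, " >= number of drugs ", n, "; clamped to ", n - 1)
    k_nn <- n - 1
  }
  neighbour <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    sims <- S[i, ]
    sims[i] <- -Inf                        # never self
    # order(): decreasing similarity, ties by smaller index
    top <- order(sims, decreasing = TRUE)[seq_len(k_nn)]
    neighbour[i, top] <- TRUE
  }
  A <- S * (neighbour | t(neighbour))
  diag(A) <- 0
  dimnames(A) <- dimnames(S)
  A
}

#' Normalized graph Laplacian
#'
#' Computes L = D^(-1/2) (D - A) D^(-1/2) with D = Diag(A 1) the degree
#' matrix.  Isolated drugs (zero degree) use the pseudo-inverse convention
#' 0^(-1/2) = 0, so their rows and columns of L are identically zero and
#' those drugs are simply unregularized by the graph.  Eigenvalues of L lie
#' in \[0, 2\].
#'
#' @param A Symmetric non-negative adjacency matrix with zero diagonal.
#' @return Symmetric n x n Laplacian matrix.
#' @export
normalized_laplacian <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  if (any(A < 0)) stop("adjacency must be non-negative")
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(as.numeric(deg > 0), n) - (dinv %o% dinv) * A
  L <- (L + t(L)) / 2
  dimnames(L) <- dimnames(A)
  L
}

#' Build the chemical-similarity graph used by the regularizer
#'
#' Convenience constructor bundling [knn_adjacency()] and
#' [normalized_laplacian()].
#'
#' @inheritParams knn_adjacency
#' @return An object of class `"similarity_graph"`: a list with elements
#'   `A` (kNN adjacency), `L` (normalized Laplacian) and `k_nn`.
#' @export
similarity_graph <- function(S, k_nn = 5) {
  A <- knn_adjacency(S, k_nn)
  structure(
    list(A = A, L = normalized_laplacian(A), k_nn = k_nn),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  n <- nrow(x$A)
  cat("Drug chemical-similarity graph\n")
  cat("  drugs:      ", n, "\n")
  cat("  k_nn:       ", x$k_nn, "\n")
  cat("  edges:      ", sum(x$A > 0) / 2, "\n")
  cat("  isolated:   ", sum(rowSums(x$A) == 0), "\n")
  invisible(x)
}

# entries must be exactly 0/1
check_binary <- function(x, what) {
  if (!all(x %in% c(0, 1))) {
    stop(what, " must be binary (entries 0/1)")
  }
  invisible(TRUE)
}
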