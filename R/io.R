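# Readers and writers: pair lists, fingerprint tables, similarity matrices,
# the model archive, prediction tables and metric reports.

# tab first, then comma
detect_delimiter <- function(lines) {
  if (any(grepl("\t", lines))) "\t" else ","
}

#' Read a (drug, label) pair list into a binary association matrix
#'
#' Accepts TSV or CSV with at least two columns (delimiter auto-detected,
#' tab first).  A header line is recognised when its fields look like
#' column names (`drug`, `compound`, `side`, `effect`, `label`, `protein`,
#' `target`, `id`).  Duplicate pairs are collapsed with a message.  Row and
#' column identifiers are ordered lexicographically so the matrix layout is
#' platform-independent.
#'
#' @param path File path.
#' @param delimiter Optional explicit delimiter overriding auto-detection.
#' @return Binary matrix with drug identifiers as rownames and label
#'   identifiers as colnames.
#' @export
read_pair_list <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty pair-list file: ", path)
  sep <- if (is.null(delimiter)) detect_delimiter(lines) else delimiter
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad)) {
    stop("malformed pair-list row at line ", bad[1], " of ", path)
  }
  first <- tolower(trimws(fields[[1]][1:2]))
  header_like <- "^(drug|compound|chemical|side|effect|label|protein|target).*|^id$"
  has_header <- any(grepl(header_like, first))
  if (has_header) fields <- fields[-1]
  if (length(fields) == 0) stop("pair-list file has a header but no data: ", path)
  drugs <- trimws(vapply(fields, `[`, character(1), 1))
  labels <- trimws(vapply(fields, `[`, character(1), 2))
  if (any(!nzchar(drugs)) || any(!nzchar(labels))) {
    stop("empty identifier in pair list ", path)
  }
  key <- paste(drugs, labels, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate pair(s) collapsed in ", basename(path))
    drugs <- drugs[!dup]; labels <- labels[!dup]
  }
  drug_ids <- sort(unique(drugs))
  label_ids <- sort(unique(labels))
  M <- matrix(0, length(drug_ids), length(label_ids),
              dimnames = list(drug_ids, label_ids))
  M[cbind(match(drugs, drug_ids), match(labels, label_ids))] <- 1
  M
}

#' Write a binary association matrix as a pair list
#'
#' One `drug_id<TAB>label_id` line per positive entry, with a header.
#' [read_pair_list()] reads the result back losslessly.
#'
#' @param M Binary association matrix with dimnames.
#' @param path Output path.
#' @export
write_pair_list <- function(M, path) {
  check_binary(M, "M")
  pos <- which(M == 1, arr.ind = TRUE)
  pos <- pos[order(rownames(M)[pos[, 1]], colnames(M)[pos[, 2]]), ,
             drop = FALSE]
  lines <- c("drug_id\tlabel_id",
             paste(rownames(M)[pos[, 1]], colnames(M)[pos[, 2]], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fingerprint table
#'
#' TSV with a header, column 1 the drug identifier and column 2 either a
#' bit string (e.g. 881 characters of 0/1) or a comma-separated list of
#' set-bit indices (1-based); the dialect is detected from the column-2
#' content.
#'
#' @param path File path.
#' @param n_bits Fingerprint length for the index-list dialect (default
#'   881, the PubChem substructure-key length); ignored for bit strings.
#' @return Binary matrix, one row per drug, with drug identifiers as
#'   rownames.
#' @export
read_fingerprints <- function(path, n_bits = 881) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(tab) < 2) stop("fingerprint file needs >= 2 columns: ", path)
  ids <- trimws(tab[[1]])
  val <- trimws(tab[[2]])
  if (anyDuplicated(ids)) stop("duplicate drug identifiers in ", path)
  bitstring <- all(grepl("^[01]+$", val))
  if (bitstring) {
    lens <- nchar(val)
    if (length(unique(lens)) != 1) {
      stop("fingerprint bit strings have differing lengths in ", path)
    }
    fp <- t(vapply(strsplit(val, ""), function(x) as.numeric(x),
                   numeric(lens[1])))
  } else {
    fp <- matrix(0, length(ids), n_bits)
    for (i in seq_along(val)) {
      if (!nzchar(val[i])) next
      idx <- as.integer(strsplit(val[i], ",", fixed = TRUE)[[1]])
      if (anyNA(idx) || any(idx < 1) || any(idx > n_bits)) {
        stop("bad bit index for drug ", ids[i], " in ", path)
      }
      fp[i, idx] <- 1
    }
  }
  rownames(fp) <- ids
  fp
}

#' Read / write a square similarity matrix
#'
#' Square TSV with drug identifiers as both the header row and the first
#' column.
#'
#' @param path File path.
#' @return Symmetric numeric matrix with drug identifiers as dimnames.
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  S <- as.matrix(tab)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square: ", path)
  if (!identical(rownames(S), colnames(S))) {
    stop("row and column identifiers differ in ", path)
  }
  if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix not symmetric: ", path)
  S
}

#' @rdname read_similarity
#' @param S Symmetric similarity matrix with dimnames.
#' @export
write_similarity <- function(S, path) {
  df <- data.frame(drug_id = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop side effects with too few associated drugs
#'
#' Removes label columns whose column sum is below `min_drugs`.  Rare
#' side effects give the model too few positive instances to learn from;
#' the conventional cutoff is five associated drugs.
#'
#' @param Y Binary association matrix.
#' @param min_drugs Minimum number of associated drugs per label
#'   (default 5).
#' @return `Y` restricted to the retained columns.
#' @export
apply_min_label_filter <- function(Y, min_drugs = 5) {
  if (min_drugs < 0) stop("min_drugs must be >= 0")
  keep <- colSums(Y) >= min_drugs
  if (!any(keep)) stop("min-label filter removed every column")
  if (any(!keep)) {
    message(sum(!keep), " label(s) with < ", min_drugs, " drugs removed")
  }
  Y[, keep, drop = FALSE]
}

#' Merge two drug-protein association sources
#'
#' Column-wise union over the merged protein set; drugs present in only
#' one source are kept with zero fill (outer union, logged).  Overlapping
#' (drug, protein) pairs collapse to a single 1.
#'
#' @param X_a,X_b Binary association matrices with drug rownames and
#'   protein colnames.
#' @return Binary matrix over the union of drugs and proteins.
#' @export
merge_protein_sources <- function(X_a, X_b) {
  if (is.null(rownames(X_a)) || is.null(rownames(X_b)) ||
      is.null(colnames(X_a)) || is.null(colnames(X_b))) {
    stop("both matrices need drug rownames and protein colnames")
  }
  drugs <- sort(union(rownames(X_a), rownames(X_b)))
  if (!setequal(rownames(X_a), rownames(X_b))) {
    message("drug universes differ; taking the outer union (",
            length(drugs), " drugs, zero fill)")
  }
  prots <- sort(union(colnames(X_a), colnames(X_b)))
  M <- matrix(0, length(drugs), length(prots),
              dimnames = list(drugs, prots))
  M[rownames(X_a), colnames(X_a)] <- pmax(M[rownames(X_a), colnames(X_a)],
                                          X_a)
  M[rownames(X_b), colnames(X_b)] <- pmax(M[rownames(X_b), colnames(X_b)],
                                          X_b)
  M
}

#' Persist / restore a fitted model
#'
#' The archive is a single JSON document holding the factor matrices (full
#' double precision), the problem dimensions and mask, identifier
#' registries, hyper-parameters, seed and objective trace — a plain
#' portable container loadable for prediction without refitting.
#'
#' @param fit A fitted `"gtmcc"` model.
#' @param path Output path (conventionally `.json`).
#' @export
write_gtmcc <- function(fit, path) {
  stopifnot(inherits(fit, "gtmcc"))
  p <- fit$problem
  payload <- list(
    format = "gtmcc-model", version = 1L,
    t = fit$hyper$t, n = p$n, c = p$c, d = p$d,
    hyper = unclass(fit$hyper), seed = fit$seed,
    drug_ids = p$drug_ids, se_ids = p$se_ids, target_ids = p$target_ids,
    test_rows = p$test_rows,
    W = unname(fit$W), H = unname(fit$H),
    Z = unname(p$Z), Omega = unname(p$Omega),
    trace = fit$trace
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gtmcc
#' @export
read_gtmcc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "gtmcc-model")) {
    stop("not a gtmcc model archive: ", path)
  }
  hyper <- do.call(gtmcc_hyper, x$hyper[c("t", "beta", "gamma", "lambda1",
                                          "lambda2", "max_iters", "rel_tol",
                                          "backtrack")])
  prob <- structure(
    list(Z = matrix(as.numeric(x$Z), x$n, x$c + x$d),
         Omega = matrix(as.numeric(x$Omega), x$n, x$c + x$d),
         n = x$n, c = x$c, d = x$d,
         test_rows = as.integer(x$test_rows),
         drug_ids = x$drug_ids, se_ids = x$se_ids,
         target_ids = x$target_ids),
    class = "cocompletion_problem")
  dimnames(prob$Z) <- dimnames(prob$Omega) <-
    list(x$drug_ids, c(x$se_ids, x$target_ids))
  W <- matrix(as.numeric(x$W), x$t, x$n, dimnames = list(NULL, x$drug_ids))
  H <- matrix(as.numeric(x$H), x$t, x$c + x$d,
              dimnames = list(NULL, c(x$se_ids, x$target_ids)))
  structure(list(W = W, H = H, problem = prob, hyper = hyper,
                 seed = as.integer(x$seed), trace = x$trace),
            class = "gtmcc")
}

#' Write ranked prediction tables
#'
#' One TSV per block with columns `drug_id`, `label_id`, `score`, `rank`
#' (rank 1 = the drug's highest-scoring label).  Already-known positives
#' are excluded by default, since ranked novel associations are the use
#' case; set `include_known = TRUE` to keep them.
#'
#' @param fit A fitted `"gtmcc"` model.
#' @param path Output path.
#' @param type `"side_effects"` or `"targets"`.
#' @param include_known Keep entries observed as positive at fit time?
#' @return The path, invisibly.
#' @export
write_predictions <- function(fit, path,
                              type = c("side_effects", "targets"),
                              include_known = FALSE) {
  type <- match.arg(type)
  p <- fit$problem
  scores <- predict(fit, type = type)
  known <- if (type == "side_effects") {
    p$Z[, seq_len(p$c), drop = FALSE]
  } else {
    p$Z[, p$c + seq_len(p$d), drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    rnk <- rank(-s, ties.method = "first")
    keep <- if (include_known) rep(TRUE, length(s)) else known[i, ] == 0
    data.frame(drug_id = rownames(scores)[i],
               label_id = colnames(scores)[keep],
               score = s[keep], rank = rnk[keep])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$drug_id, out$rank), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-fold and summary metric reports
#'
#' `<prefix>_folds.csv` holds one row per fold x repeat;
#' `<prefix>_summary.csv` holds mean and standard deviation per metric.
#'
#' @param reports A data.frame from one of the `run_*_cv()` functions.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_metric_reports <- function(reports, prefix) {
  folds_path <- paste0(prefix, "_folds.csv")
  summary_path <- paste0(prefix, "_summary.csv")
  utils::write.csv(reports, folds_path, row.names = FALSE)
  utils::write.csv(summarize_metrics(reports), summary_path,
                   row.names = FALSE)
  invisible(c(folds_path, summary_path))
}
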