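## All-vs-all evaluation: distance matrices, sigmoid similarity, and
## clustering-based performance measures (Rand index, precision, recall,
## F-measure) from a class-by-cluster confusion matrix.

#' All-vs-all geodesic distance matrix
#'
#' Runs [esa_compare()] for every unordered pair of structures. With
#' `both_directions = TRUE` each pair is compared both ways and the two
#' thetas averaged; otherwise the single value is mirrored. Failed pairs
#' are recorded as `NA` with a warning; more than `max_missing` missing is
#' an error.
#'
#' @param structures A named list of `esa_chain` objects / PDB paths, or a
#'   directory containing `.pdb` files.
#' @param labels Optional ids (default: names of `structures` or file
#'   names).
#' @param both_directions Compare each pair in both orders (default FALSE).
#' @param max_missing Maximum tolerated fraction of failed pairs (0.2).
#' @param ... Passed to [esa_compare()] (criterion, feature_set, ...).
#' @return An object of class `esa_distmat`: list with `labels` and
#'   `values` (symmetric N x N matrix, zero diagonal).
#' @export
esa_distance_matrix <- function(structures, labels = NULL,
                                both_directions = FALSE,
                                max_missing = 0.2, ...) {
  if (is.character(structures) && length(structures) == 1L &&
      dir.exists(structures)) {
    files <- sort(list.files(structures, pattern = "\\.(pdb|ent)$",
                             full.names = TRUE))
    structures <- as.list(files)
    if (is.null(labels)) labels <- sub("\\.(pdb|ent)$", "", basename(files))
  }
  N <- length(structures)
  if (N < 2L) stop("need at least 2 structures")
  if (is.null(labels))
    labels <- if (!is.null(names(structures))) names(structures)
              else paste0("S", seq_len(N))
  chains <- lapply(structures, .as_chain, model_id = 1L, chain_id = NA)
  D <- matrix(0, N, N, dimnames = list(labels, labels))
  failed <- 0L
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      th <- tryCatch({
        t1 <- esa_compare(chains[[i]], chains[[j]], ...)$theta
        if (both_directions)
          (t1 + esa_compare(chains[[j]], chains[[i]], ...)$theta) / 2
        else t1
      }, error = function(e) {
        warning("pair (", labels[i], ", ", labels[j], ") failed: ",
                conditionMessage(e))
        NA_real_
      })
      if (is.na(th)) failed <- failed + 1L
      D[i, j] <- D[j, i] <- th
    }
  }
  if (failed / (N * (N - 1L) / 2) > max_missing)
    stop(failed, " of ", N * (N - 1L) / 2, " pairs failed (> ",
         100 * max_missing, "%)")
  structure(list(labels = labels, values = D), class = "esa_distmat")
}

#' @export
print.esa_distmat <- function(x, ...) {
  cat("Geodesic distance matrix: ", length(x$labels), " structures, ",
      sum(is.na(x$values)) / 2, " missing pair(s)\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Write / read a distance matrix as delimited text
#'
#' @param x An `esa_distmat`.
#' @param file Output (input) path; tab-delimited with id header row and
#'   column.
#' @name esa_distmat_io
#' @export
write_distance_matrix <- function(x, file) {
  stopifnot(inherits(x, "esa_distmat"))
  utils::write.table(x$values, file, sep = "\t", quote = FALSE,
                     col.names = NA)
}

#' @rdname esa_distmat_io
#' @export
read_distance_matrix <- function(file) {
  v <- as.matrix(utils::read.table(file, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  structure(list(labels = rownames(v), values = v), class = "esa_distmat")
}

#' Sigmoid conversion of distances to similarities
#'
#' `s(x) = 2 / (1 + exp(alpha * x))`: maps distance 0 to similarity 1,
#' strictly decreasing, approaching 0 for large distances. Used to put
#' geodesic distances (and, externally, RMSDs) on a common (0, 1] scale.
#'
#' @param x Non-negative distances (vector or matrix).
#' @param alpha Steepness, `> 0` (default 1).
#' @return Similarities with the shape of `x`.
#' @export
sigmoid_similarity <- function(x, alpha = 1) {
  if (any(x < 0, na.rm = TRUE)) stop("distances must be non-negative")
  if (alpha <= 0) stop("alpha must be positive")
  2 / (1 + exp(alpha * x))
}

#' Performance measures from a confusion matrix
#'
#' Rows are true classes, columns predicted classes. Per class `i`:
#' `precision_i = M_ii / colsum_i`, `recall_i = M_ii / rowsum_i`,
#' `F_i = 2 P R / (P + R)`. Two overall Rand-index readings are reported:
#' the accuracy form `sum_i M_ii / sum_ij M_ij` and the standard
#' pair-counting Rand index computed from the contingency table. Classes
#' with an empty row or column get `NA` for the undefined measures and are
#' excluded from macro averages (with a message).
#'
#' @param M Square numeric matrix of non-negative counts.
#' @return An object of class `esa_metrics`: list with `per_class` (data
#'   frame of precision/recall/F), `RI` (accuracy form), `rand_index`
#'   (pair-counting), `macro_precision`, `macro_recall`, `macro_f`,
#'   `confusion`.
#' @export
confusion_metrics <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("confusion matrix must be square")
  if (any(M < 0)) stop("confusion matrix counts must be non-negative")
  if (sum(M) == 0) stop("empty confusion matrix")
  nc <- nrow(M)
  rs <- rowSums(M)
  cs <- colSums(M)
  precision <- ifelse(cs > 0, diag(M) / cs, NA_real_)
  recall <- ifelse(rs > 0, diag(M) / rs, NA_real_)
  f <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
              2 * precision * recall / (precision + recall), NA_real_)
  f[!is.na(precision) & !is.na(recall) & (precision + recall) == 0] <- 0
  if (anyNA(c(precision, recall)))
    message("empty row/column: undefined per-class measures reported as NA ",
            "and excluded from macro averages")
  n <- sum(M)
  pairs2 <- function(v) sum(v * (v - 1) / 2)
  S <- pairs2(as.vector(M))
  rand <- if (n < 2) NA_real_ else
    (n * (n - 1) / 2 + 2 * S - pairs2(rs) - pairs2(cs)) / (n * (n - 1) / 2)
  structure(list(
    per_class = data.frame(precision = precision, recall = recall,
                           f_measure = f,
                           row.names = rownames(M) %||% paste0("class", 1:nc)),
    RI = sum(diag(M)) / n,
    rand_index = rand,
    macro_precision = mean(precision, na.rm = TRUE),
    macro_recall = mean(recall, na.rm = TRUE),
    macro_f = mean(f, na.rm = TRUE),
    confusion = M), class = "esa_metrics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.esa_metrics <- function(x, digits = 4, ...) {
  cat("Clustering performance (", nrow(x$confusion), " classes, n = ",
      sum(x$confusion), ")\n", sep = "")
  print(round(x$per_class, digits))
  cat("RI (accuracy form) = ", round(x$RI, digits),
      "; Rand index (pair counting) = ", round(x$rand_index, digits),
      "\n", sep = "")
  cat("macro P/R/F = ", round(x$macro_precision, digits), " / ",
      round(x$macro_recall, digits), " / ", round(x$macro_f, digits),
      "\n", sep = "")
  invisible(x)
}

#' Cluster a distance matrix and score against known classes
#'
#' Evaluation harness: the distance matrix is converted to features --
#' classical multidimensional scaling to `min(N-1, 10)` dimensions for
#' k-means and fuzzy c-means, or sigmoid similarity plus normalized
#' spectral embedding for spectral k-means -- clustered with the named
#' standard algorithm, clusters are mapped to classes by maximum-agreement
#' assignment, and [confusion_metrics()] is returned. Deterministic for a
#' fixed seed.
#'
#' @param D An `esa_distmat` (complete: no missing entries).
#' @param true_labels Class label per structure (same order as
#'   `D$labels`), or a two-column data frame (id, class).
#' @param method `"kmeans"`, `"cmeans"` (fuzzy) or `"spectral"`.
#' @param n_clusters Number of clusters; default the number of distinct
#'   true labels.
#' @param seed Random seed (default 1).
#' @param alpha Sigmoid steepness for the spectral affinity.
#' @return An `esa_metrics` with an extra `assignment` element (cluster id
#'   per structure after class mapping).
#' @export
cluster_and_score <- function(D, true_labels,
                              method = c("kmeans", "cmeans", "spectral"),
                              n_clusters = NULL, seed = 1, alpha = 1) {
  stopifnot(inherits(D, "esa_distmat"))
  method <- match.arg(method)
  if (anyNA(D$values)) stop("distance matrix has missing entries")
  if (is.data.frame(true_labels)) {
    idx <- match(D$labels, true_labels[[1L]])
    if (anyNA(idx)) stop("labels file does not cover all structure ids")
    true_labels <- true_labels[[2L]][idx]
  }
  true_labels <- as.character(true_labels)
  if (length(true_labels) != length(D$labels))
    stop("one true label per structure required")
  classes <- sort(unique(true_labels))
  if (is.null(n_clusters)) n_clusters <- length(classes)
  N <- length(D$labels)

  set.seed(seed)
  if (n_clusters == 1L) {
    cluster <- rep(1L, N)
  } else if (method %in% c("kmeans", "cmeans")) {
    emb <- stats::cmdscale(D$values, k = min(N - 1L, 10L))
    if (method == "kmeans") {
      cluster <- stats::kmeans(emb, centers = n_clusters, nstart = 20L,
                               iter.max = 100L)$cluster
    } else {
      cm <- e1071::cmeans(emb, centers = n_clusters, iter.max = 200L)
      cluster <- apply(cm$membership, 1L, which.max)
    }
  } else {
    S <- sigmoid_similarity(D$values, alpha)
    dg <- 1 / sqrt(pmax(rowSums(S), 1e-12))
    L <- S * outer(dg, dg)
    ev <- eigen(L, symmetric = TRUE)
    U <- ev$vectors[, seq_len(n_clusters), drop = FALSE]
    rn <- sqrt(rowSums(U^2))
    U <- U / pmax(rn, 1e-12)
    cluster <- stats::kmeans(U, centers = n_clusters, nstart = 20L,
                             iter.max = 100L)$cluster
  }

  perm <- .map_clusters(true_labels, cluster, classes, n_clusters)
  mapped <- perm[cluster]
  M <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_len(N))
    M[true_labels[i], mapped[i]] <- M[true_labels[i], mapped[i]] + 1L
  out <- confusion_metrics(M)
  out$assignment <- stats::setNames(mapped, D$labels)
  out$method <- method
  out
}

## Maximum-agreement cluster -> class assignment. Exhaustive permutation
## search (exact) for up to 8 clusters, greedy beyond.
.map_clusters <- function(true_labels, cluster, classes, n_clusters) {
  A <- matrix(0L, n_clusters, length(classes))  # cluster x class agreement
  for (i in seq_along(cluster)) {
    cc <- match(true_labels[i], classes)
    A[cluster[i], cc] <- A[cluster[i], cc] + 1L
  }
  nc <- max(n_clusters, length(classes))
  Af <- matrix(0L, nc, nc)
  Af[seq_len(n_clusters), seq_len(length(classes))] <- A
  if (nc <= 8L) {
    best <- NULL
    best_score <- -1L
    for (p in .permutations(nc)) {
      sc <- sum(Af[cbind(seq_len(nc), p)])
      if (sc > best_score) {
        best_score <- sc
        best <- p
      }
    }
    assign <- best
  } else {
    assign <- integer(nc)
    used <- logical(nc)
    for (r in order(-apply(Af, 1L, max))) {
      cand <- order(-Af[r, ])
      assign[r] <- cand[!used[cand]][1L]
      used[assign[r]] <- TRUE
    }
  }
  cls <- classes[pmin(assign, length(classes))][seq_len(n_clusters)]
  cls[is.na(cls)] <- classes[1L]
  cls
}

## All permutations of 1..n, built by inserting n at each position.
.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Write a metrics report as JSON and a delimited table
#'
#' @param x An `esa_metrics`.
#' @param json_file,table_file Optional output paths (JSON report and a
#'   tab-delimited measure table).
#' @return The report list, invisibly.
#' @export
write_metrics <- function(x, json_file = NULL, table_file = NULL) {
  stopifnot(inherits(x, "esa_metrics"))
  rep <- list(per_class = x$per_class, RI = x$RI,
              rand_index = x$rand_index,
              macro_precision = x$macro_precision,
              macro_recall = x$macro_recall, macro_f = x$macro_f,
              confusion = x$confusion)
  if (!is.null(json_file))
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"), json_file)
  if (!is.null(table_file)) {
    tab <- data.frame(measure = c("RI", "rand_index", "macro_precision",
                                  "macro_recall", "macro_f"),
                      value = c(x$RI, x$rand_index, x$macro_precision,
                                x$macro_recall, x$macro_f))
    utils::write.table(tab, table_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(rep)
}
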