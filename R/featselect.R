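#' Build a k-nearest-neighbor similarity graph between samples
#'
#' Undirected kNN graph over the `S` samples in a feature block:
#' samples i and j are linked if either is among the other's `k_nn`
#' Euclidean nearest neighbors (union rule). Linked pairs get a heat
#' kernel weight `exp(-||x_i - x_j||^2 / bandwidth)` (or weight 1 with
#' `kernel = "binary"`); the diagonal is zero by convention.
#'
#' @param x numeric `S x d` feature block.
#' @param k_nn neighbor count, `1 <= k_nn < S`.
#' @param bandwidth positive heat-kernel scale; default the squared
#'   median pairwise distance within the block (scale-free).
#' @param kernel `"heat"` (default) or `"binary"`.
#' @return A `sample_graph`: list with `weights` (`S x S` symmetric),
#'   `k_nn`, `bandwidth`.
#' @export
build_sample_graph <- function(x, k_nn = 5, bandwidth = NULL,
                               kernel = c("heat", "binary")) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  S <- nrow(x)
  if (S < 3) stop("need at least 3 samples to build a sample graph")
  if (k_nn < 1 || k_nn >= S) stop("k_nn must satisfy 1 <= k_nn < S (S = ", S, ")")
  d <- as.matrix(stats::dist(x))
  if (is.null(bandwidth)) {
    med <- stats::median(d[upper.tri(d)])
    bandwidth <- if (med > 0) med^2 else 1
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  adj <- matrix(FALSE, S, S)
  for (i in seq_len(S)) {
    ord <- order(d[i, ])
    ord <- ord[ord != i][seq_len(k_nn)]
    adj[i, ord] <- TRUE
  }
  adj <- adj | t(adj)                    # union of directed neighborhoods
  diag(adj) <- FALSE
  W <- matrix(0, S, S)
  if (kernel == "heat") {
    W[adj] <- exp(-d[adj]^2 / bandwidth)
  } else {
    W[adj] <- 1
  }
  structure(list(weights = W, k_nn = k_nn, bandwidth = bandwidth),
            class = "sample_graph")
}

#' Laplacian score of one feature
#'
#' Locality-preserving feature score of He et al.: with `W` the sample
#' graph weights, `D = diag(rowSums(W))`, `L = D - W`, and the feature
#' centered by its degree-weighted mean,
#' `f~ = f - (f' D 1 / 1' D 1) 1`, the score is
#' `(f~' L f~) / (f~' D f~)`. Lower scores mean the feature varies
#' smoothly over the sample-similarity graph, i.e. preserves the
#' between-sample structure; a constant feature has an undefined ratio
#' and is given `+Inf` (worst).
#'
#' @param feature numeric length-`S` vector.
#' @param graph a `sample_graph`.
#' @return nonnegative score (`+Inf` for degenerate features).
#' @export
laplacian_score <- function(feature, graph) {
  W <- graph$weights
  stopifnot(length(feature) == nrow(W))
  deg <- rowSums(W)
  denom_mean <- sum(deg)
  mu <- if (denom_mean > 0) sum(feature * deg) / denom_mean else mean(feature)
  f <- feature - mu
  fDf <- sum(deg * f^2)
  if (fDf <= .Machine$double.eps * max(1, sum(deg))) {
    return(Inf)
  }
  # f' L f via the edge sum: 1/2 * sum_ij W_ij (f_i - f_j)^2
  fLf <- 0.5 * sum(W * outer(f, f, FUN = function(a, b) (a - b)^2))
  fLf / fDf
}

#' Unsupervised per-iteration feature selection
#'
#' Applies Laplacian-score selection independently inside every
#' metaclustering iteration's column block of the frequency matrix: a
#' kNN sample graph is built from that block alone, each column is
#' scored, and the `top_m` lowest-scoring (most locality-preserving)
#' columns are retained; ties break by ascending column index. The
#' procedure never sees class labels, so it cannot bias downstream
#' cross-validation.
#'
#' @param F a `freq_matrix` (or plain matrix with a `column_meta`
#'   attribute-compatible data.frame passed via `column_meta`).
#' @param k_nn,bandwidth,kernel graph parameters, see
#'   [build_sample_graph()].
#' @param top_m number of features kept per iteration (default 40, the
#'   usual companion of 50 metaclusters per solution); capped at the
#'   block width.
#' @return A `selection_result`: data.frame with columns `iteration`,
#'   `metacluster`, `column` (index into `F$values`), `score`,
#'   `retained`.
#' @export
select_features <- function(F, k_nn = 5, bandwidth = NULL, top_m = 40,
                            kernel = c("heat", "binary")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(F, "freq_matrix"))
  if (top_m < 1) stop("top_m must be >= 1")
  meta <- F$column_meta
  out <- lapply(unique(meta$iteration), function(it) {
    cols <- which(meta$iteration == it)
    block <- F$values[, cols, drop = FALSE]
    graph <- build_sample_graph(block, k_nn = k_nn, bandwidth = bandwidth,
                                kernel = kernel)
    scores <- apply(block, 2, laplacian_score, graph = graph)
    n_keep <- min(top_m, length(cols))
    keep_local <- order(scores, seq_along(scores))[seq_len(n_keep)]
    if (any(!is.finite(scores[keep_local]))) {
      message("iteration ", it, ": constant feature(s) scored +Inf")
    }
    data.frame(iteration = it, metacluster = meta$metacluster[cols],
               column = cols, score = unname(scores),
               retained = seq_along(cols) %in% keep_local)
  })
  res <- do.call(rbind, out)
  class(res) <- c("selection_result", "data.frame")
  res
}

#' Matrix of retained feature columns
#'
#' @param F a `freq_matrix`.
#' @param selection a `selection_result` from [select_features()]; if
#'   `NULL`, all columns are returned (selection disabled).
#' @param iterations optional subset of iteration ids to keep.
#' @return numeric matrix of the retained columns (manifest row order).
#' @export
selected_matrix <- function(F, selection = NULL, iterations = NULL) {
  keep <- if (is.null(selection)) {
    seq_len(ncol(F$values))
  } else {
    selection$column[selection$retained]
  }
  if (!is.null(iterations)) {
    keep <- intersect(keep, which(F$column_meta$iteration %in% iterations))
  }
  F$values[, sort(keep), drop = FALSE]
}

#' Write a selection result to CSV
#' @param selection a `selection_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(selection, path) {
  data.table::fwrite(as.data.frame(selection)[, c("iteration", "metacluster",
                                                  "score", "retained")],
                     path)
  invisible(path)
}
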