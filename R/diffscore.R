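#' Per-metacluster case-control significance
#'
#' For every frequency column (one metacluster of one solution), a
#' two-sided Wilcoxon rank-sum test compares the frequencies of class-0
#' versus class-1 samples; exact p-values are used when both groups
#' have at most 25 samples (and the data are tie-free), otherwise the
#' normal approximation with tie correction. The test can be restricted
#' to a user-specified comparison subset of samples (e.g. a single
#' timepoint), which need not coincide with the classification cohort.
#' The p-values `w_j` rank cell populations for visualization; they are
#' deliberately not multiplicity-corrected and should not be read as
#' confirmatory statistics.
#'
#' @param F a `freq_matrix`.
#' @param labels per-sample binary 0/1 labels (manifest row order).
#' @param comparison_samples optional character vector of sample ids (or
#'   logical/integer index) restricting the comparison.
#' @return A `cluster_significance`: data.frame with `iteration`,
#'   `metacluster`, `column`, `p_value`, `direction` (sign of
#'   median class-1 minus class-0 frequency).
#' @export
cluster_significance <- function(F, labels, comparison_samples = NULL) {
  stopifnot(inherits(F, "freq_matrix"))
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(F$values))
  idx <- seq_len(nrow(F$values))
  if (!is.null(comparison_samples)) {
    idx <- if (is.character(comparison_samples)) {
      match(comparison_samples, F$sample_ids)
    } else {
      which(seq_len(nrow(F$values)) %in% seq_len(nrow(F$values))[comparison_samples])
    }
    if (anyNA(idx)) stop("comparison subset names unknown sample ids")
  }
  a <- idx[labels[idx] == 0]
  b <- idx[labels[idx] == 1]
  if (length(a) == 0 || length(b) == 0) {
    stop("comparison subset leaves a class empty (class 0: ", length(a),
         ", class 1: ", length(b), " samples)")
  }
  use_exact <- length(a) <= 25 && length(b) <= 25
  res <- lapply(seq_len(ncol(F$values)), function(j) {
    xa <- F$values[a, j]
    xb <- F$values[b, j]
    p <- suppressWarnings(
      stats::wilcox.test(xa, xb, exact = use_exact, correct = TRUE)$p.value
    )
    if (is.na(p)) p <- 1            # zero-variance tie-only configuration
    data.frame(p_value = min(p, 1),
               direction = sign(stats::median(xb) - stats::median(xa)))
  })
  out <- cbind(F$column_meta, column = seq_len(ncol(F$values)),
               do.call(rbind, res))
  class(out) <- c("cluster_significance", "data.frame")
  out
}

#' Subsample cells across a cohort for visualization
#'
#' Uniform, seeded sampling of up to `n_cells` cells pooled over all
#' samples, with an optional exclusion predicate (e.g. a granulocyte
#' gate: the most abundant populations can be masked from the *view*
#' so rarer ones stay visible — modeling always uses every cell). The
#' provenance of every drawn cell (sample and row index) is retained.
#'
#' @param cohort a `cyto_cohort`.
#' @param n_cells target subsample size (default 30000).
#' @param exclude optional predicate `function(values_matrix)` returning
#'   a logical per-cell vector, `TRUE` = exclude; applied per sample.
#' @param seed RNG seed.
#' @return list with `values` (`n x m` matrix), `provenance`
#'   (data.frame `sample_id`, `cell`).
#' @export
subsample_cells <- function(cohort, n_cells = 30000, exclude = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "cyto_cohort"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  pools <- lapply(cohort$samples, function(s) {
    keep <- rep(TRUE, s$n_cells)
    if (!is.null(exclude)) keep <- !as.logical(exclude(s$values))
    which(keep)
  })
  prov <- do.call(rbind, lapply(names(pools), function(sid) {
    if (length(pools[[sid]]) == 0) return(NULL)
    data.frame(sample_id = sid, cell = pools[[sid]], stringsAsFactors = FALSE)
  }))
  if (is.null(prov) || nrow(prov) == 0) stop("no eligible cells to subsample")
  if (nrow(prov) <= n_cells) {
    if (nrow(prov) < n_cells) {
      warning("only ", nrow(prov), " eligible cells (< ", n_cells,
              "); taking all", call. = FALSE)
    }
    take <- seq_len(nrow(prov))
  } else {
    set.seed(seed)
    take <- sort(sample.int(nrow(prov), n_cells))
  }
  prov <- prov[take, , drop = FALSE]
  rownames(prov) <- NULL
  # provenance rows stay grouped in cohort order, so rbind in order of
  # appearance keeps values row-aligned with provenance
  values <- do.call(rbind, lapply(unique(prov$sample_id), function(sid) {
    cohort$samples[[sid]]$values[prov$cell[prov$sample_id == sid], ,
                                 drop = FALSE]
  }))
  list(values = values, provenance = prov)
}

#' 2-D embedding of cells
#'
#' Pluggable dimensionality reduction over the analysis channels.
#' Built-in methods: `"tsne"` (default; requires the Rtsne package) and
#' `"pca2"` (first two principal components); alternatively pass a
#' function `(matrix, seed) -> n x 2 matrix`.
#'
#' @param x numeric `n x m` cell matrix.
#' @param method `"tsne"`, `"pca2"`, or a function.
#' @param seed RNG seed for stochastic methods.
#' @param perplexity t-SNE perplexity (auto-shrunk for tiny inputs).
#' @return `n x 2` coordinate matrix.
#' @export
embed_2d <- function(x, method = "tsne", seed = 1L, perplexity = 30) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 cells to embed")
  if (is.function(method)) {
    coords <- method(x, seed)
  } else if (identical(method, "pca2")) {
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    coords <- p$x[, seq_len(min(2, ncol(p$x))), drop = FALSE]
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
  } else if (identical(method, "tsne")) {
    if (!requireNamespace("Rtsne", quietly = TRUE)) {
      stop("method 'tsne' needs the Rtsne package; use method = 'pca2' instead")
    }
    set.seed(seed)
    perp <- min(perplexity, floor((nrow(x) - 1) / 3))
    if (perp < 1) perp <- 1
    xu <- x + stats::rnorm(length(x), sd = 1e-10)  # Rtsne rejects duplicates
    coords <- Rtsne::Rtsne(xu, dims = 2, perplexity = perp,
                           check_duplicates = FALSE, pca = TRUE,
                           verbose = FALSE)$Y
  } else {
    stop("unknown embedding method '", method, "'")
  }
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(x), ncol(coords) == 2)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Cell-to-center similarity kernel
#'
#' `exp(-alpha * ||center - cell||_2)`: 1 when the cell sits on the
#' center, decaying with Euclidean distance at user-defined rate
#' `alpha`.
#'
#' @param cell,center numeric vectors of equal length.
#' @param alpha positive decay constant.
#' @return similarity in `(0, 1]`.
#' @export
cell_similarity <- function(cell, center, alpha = 1) {
  if (alpha <= 0) stop("alpha must be positive")
  stopifnot(length(cell) == length(center))
  exp(-alpha * sqrt(sum((center - cell)^2)))
}

# dense cross-distance: rows of a vs rows of b
cross_dist <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Per-cell differentiation scores
#'
#' Maps metacluster-level significance onto single cells: within each
#' metaclustering solution *m*, a cell's score is the similarity-
#' weighted average of that solution's metacluster p-values,
#' `p_i^m = sum_j s_ji w_j / sum_j s_ji` with
#' `s_ji = exp(-alpha ||c_j - x_i||)`; the final score is the mean of
#' `p_i^m` over the `I` solutions. Low scores flag cells in populations
#' whose frequency differs between the comparison groups. By default
#' channels are standardized (jointly over cells and centers) before
#' the similarity computation only, making `alpha = 1` scale-free.
#'
#' @param cells numeric `n x m` cell matrix (same channels as the
#'   metacluster centers).
#' @param solutions list of `metacluster_solution`s.
#' @param significance a `cluster_significance` covering every
#'   (iteration, metacluster) of `solutions`.
#' @param alpha positive similarity decay (default 1).
#' @param standardize standardize channels before computing similarities.
#' @return numeric length-`n` vector of scores.
#' @export
differentiation_scores <- function(cells, solutions, significance, alpha = 1,
                                   standardize = TRUE) {
  if (alpha <= 0) stop("alpha must be positive")
  cells <- as.matrix(cells)
  per_solution <- vapply(solutions, function(sol) {
    w_rows <- significance$iteration == sol$iteration_id
    if (sum(w_rows) != sol$k_prime) {
      stop("significance table does not cover iteration ", sol$iteration_id)
    }
    w <- significance$p_value[w_rows][order(significance$metacluster[w_rows])]
    centers <- sol$meta_centers
    xs <- cells
    cs <- centers
    if (standardize) {
      mu <- colMeans(rbind(xs, cs))
      sdev <- apply(rbind(xs, cs), 2, stats::sd)
      sdev[sdev == 0] <- 1
      xs <- sweep(sweep(xs, 2, mu), 2, sdev, "/")
      cs <- sweep(sweep(cs, 2, mu), 2, sdev, "/")
    }
    s <- exp(-alpha * cross_dist(xs, cs))
    tot <- rowSums(s)
    p <- as.numeric(s %*% w) / tot
    dead <- !is.finite(p) | tot == 0
    if (any(dead)) {
      # numeric underflow: fall back to the nearest center's p-value
      nearest <- max.col(-cross_dist(xs[dead, , drop = FALSE], cs), "first")
      p[dead] <- w[nearest]
      message(sum(dead), " cell(s) hit similarity underflow; used nearest-center w")
    }
    p
  }, numeric(nrow(cells)))
  rowMeans(as.matrix(per_solution))
}

#' Build a differentiation map
#'
#' Convenience wrapper: subsample cells, embed them in 2-D, compute
#' metacluster significance and per-cell differentiation scores.
#'
#' @param cohort a `cyto_cohort`.
#' @param ensemble a `metacluster_ensemble`.
#' @param F the cohort's `freq_matrix`.
#' @param labels per-sample 0/1 labels (manifest order).
#' @param n_cells subsample size (default 30000).
#' @param comparison_samples optional comparison subset, see
#'   [cluster_significance()].
#' @param exclude optional per-cell exclusion predicate, see
#'   [subsample_cells()].
#' @param alpha similarity decay.
#' @param method embedding method, see [embed_2d()].
#' @param seed RNG seed.
#' @return A `differentiation_map`: list with `cells`, `provenance`,
#'   `coords`, `scores`, `significance`, `alpha`, `method`, `seed`.
#' @export
differentiation_map <- function(cohort, ensemble, F, labels, n_cells = 30000,
                                comparison_samples = NULL, exclude = NULL,
                                alpha = 1, method = "tsne", seed = 1L) {
  sub <- subsample_cells(cohort, n_cells = n_cells, exclude = exclude,
                         seed = seed)
  sig <- cluster_significance(F, labels, comparison_samples)
  scores <- differentiation_scores(sub$values, ensemble$solutions, sig,
                                   alpha = alpha)
  coords <- embed_2d(sub$values, method = method, seed = seed)
  structure(list(cells = sub$values, provenance = sub$provenance,
                 coords = coords, scores = scores, significance = sig,
                 alpha = alpha,
                 method = if (is.function(method)) "custom" else method,
                 seed = seed),
            class = "differentiation_map")
}

#' Render a differentiation map
#'
#' Scatter of the 2-D embedding colored by `-log10(score)` (brighter =
#' stronger association with the outcome), written as an image plus a
#' per-cell CSV (`sample_id`, `cell`, `dim1`, `dim2`, `score`) and a
#' JSON of the map parameters. Optionally a per-marker panel grid.
#'
#' @param map a `differentiation_map`.
#' @param out_dir output directory (created if absent).
#' @param name basename for the artifact files.
#' @param device `"png"` or `"svg"`.
#' @param marker_grid also write a grid of per-marker expression maps.
#' @return invisibly, the paths written.
#' @export
render_map <- function(map, out_dir, name = "differentiation_map",
                       device = c("png", "svg"), marker_grid = FALSE) {
  device <- match.arg(device)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  df <- data.frame(sample_id = map$provenance$sample_id,
                   cell = map$provenance$cell,
                   dim1 = map$coords[, 1], dim2 = map$coords[, 2],
                   score = map$scores)
  csv_path <- file.path(out_dir, paste0(name, ".csv"))
  data.table::fwrite(df, csv_path)
  df$neglog <- -log10(pmax(df$score, 1e-300))
  rng <- range(df$neglog)
  if (diff(rng) == 0) df$neglog <- rng[1]  # constant scores: flat palette
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                        color = .data$neglog)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.8) +
    ggplot2::scale_color_viridis_c(name = expression(-log[10](score))) +
    ggplot2::labs(x = "dim 1", y = "dim 2",
                  title = "Cells colored by differentiation score") +
    ggplot2::theme_minimal()
  img_path <- file.path(out_dir, paste0(name, ".", device))
  ggplot2::ggsave(img_path, p, width = 7, height = 6, dpi = 150,
                  device = device)
  paths <- c(csv_path, img_path)
  if (marker_grid) {
    long <- do.call(rbind, lapply(colnames(map$cells), function(ch) {
      data.frame(dim1 = df$dim1, dim2 = df$dim2, marker = ch,
                 expr = map$cells[, ch])
    }))
    g <- ggplot2::ggplot(long, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                            color = .data$expr)) +
      ggplot2::geom_point(size = 0.2) +
      ggplot2::scale_color_viridis_c(name = "expression") +
      ggplot2::facet_wrap(~marker) +
      ggplot2::theme_minimal()
    grid_path <- file.path(out_dir, paste0(name, "_markers.", device))
    ggplot2::ggsave(grid_path, g, width = 10, height = 8, dpi = 150,
                    device = device)
    paths <- c(paths, grid_path)
  }
  json_path <- file.path(out_dir, paste0(name, "_params.json"))
  jsonlite::write_json(list(alpha = map$alpha, method = map$method,
                            seed = map$seed, n_cells = nrow(map$cells)),
                       json_path, auto_unbox = TRUE)
  invisible(c(paths, json_path))
}
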