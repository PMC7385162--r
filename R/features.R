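#' Metacluster frequency features
#'
#' Builds the `S x P` frequency matrix whose entry gives the proportion
#' of sample *i*'s cells assigned to metacluster *j*, with column blocks
#' ordered by metaclustering iteration (`P = sum of K'_m` over the `I`
#' solutions). Because clustering used phenotypic *and* functional
#' channels jointly, these frequencies carry functional information and
#' are the default classification input. Within each iteration's block
#' every row sums to 1.
#'
#' @param cohort a `cyto_cohort`.
#' @param ensemble a `metacluster_ensemble` (see [repeated_metacluster()]).
#' @return A `freq_matrix`: list with `values` (`S x P` matrix, rows
#'   named by sample in manifest order), `column_meta` (data.frame
#'   `iteration`, `metacluster`), `sample_ids`.
#' @export
frequency_features <- function(cohort, ensemble) {
  stopifnot(inherits(cohort, "cyto_cohort"),
            inherits(ensemble, "metacluster_ensemble"))
  sample_ids <- cohort$manifest$sample_id
  blocks <- lapply(ensemble$solutions, function(sol) {
    kp <- sol$k_prime
    block <- t(vapply(seq_along(sample_ids), function(i) {
      cells <- cohort$samples[[sample_ids[i]]]
      sc <- ensemble$clusterings[[i]]
      labels <- assign_cells(cells, sc, sol)
      tabulate(labels, nbins = kp) / cells$n_cells
    }, numeric(kp)))
    colnames(block) <- sprintf("iter%d_mc%d", sol$iteration_id, seq_len(kp))
    block
  })
  values <- do.call(cbind, blocks)
  rownames(values) <- sample_ids
  column_meta <- do.call(rbind, lapply(ensemble$solutions, function(sol) {
    data.frame(iteration = sol$iteration_id, metacluster = seq_len(sol$k_prime))
  }))
  structure(list(values = values, column_meta = column_meta,
                 sample_ids = sample_ids),
            class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("freq_matrix: %d samples x %d metacluster frequency features (%d iterations)\n",
              nrow(x$values), ncol(x$values), length(unique(x$column_meta$iteration))))
  invisible(x)
}

#' Functional marker mean-expression features
#'
#' For every functional marker *t*, the `S x P` matrix of mean marker-*t*
#' expression of sample *i*'s cells inside metacluster *j*; the `f`
#' per-marker matrices are horizontally concatenated into an
#' `S x (P * f)` block matrix. A (sample, metacluster) combination that
#' received no cells has no defined mean; it is encoded as missing and,
#' when `impute = TRUE`, filled with that column's cross-sample mean so
#' the matrix can enter a classifier without fabricating a zero signal
#' level.
#'
#' @param cohort a `cyto_cohort`.
#' @param ensemble a `metacluster_ensemble`.
#' @param functional_channels channels to summarize; default all panel
#'   channels with the functional role.
#' @param impute impute empty cells with the column cross-sample mean.
#' @return A `functional_matrix`: list with `values`
#'   (`S x (P * f)`), `column_meta` (`iteration`, `metacluster`,
#'   `marker`), `n_imputed`.
#' @export
functional_features <- function(cohort, ensemble, functional_channels = NULL,
                                impute = TRUE) {
  stopifnot(inherits(cohort, "cyto_cohort"),
            inherits(ensemble, "metacluster_ensemble"))
  if (is.null(functional_channels)) {
    functional_channels <- panel_channels(cohort$panel, "functional")
  }
  if (length(functional_channels) == 0) stop("no functional channels to summarize")
  bad <- setdiff(functional_channels,
                 panel_channels(cohort$panel, "functional"))
  if (length(bad)) stop("not functional panel channels: ", paste(bad, collapse = ", "))
  sample_ids <- cohort$manifest$sample_id
  S <- length(sample_ids)
  # per-solution S x (K'_m) mean-expression matrix for each marker
  per_marker <- lapply(functional_channels, function(t) {
    blocks <- lapply(ensemble$solutions, function(sol) {
      kp <- sol$k_prime
      block <- matrix(NA_real_, S, kp)
      for (i in seq_len(S)) {
        cells <- cohort$samples[[sample_ids[i]]]
        labels <- assign_cells(cells, ensemble$clusterings[[i]], sol)
        sums <- rowsum(cells$values[, t], labels)
        counts <- tabulate(labels, nbins = kp)
        idx <- as.integer(rownames(sums))
        block[i, idx] <- sums[, 1] / counts[idx]
      }
      colnames(block) <- sprintf("iter%d_mc%d_%s", sol$iteration_id,
                                 seq_len(kp), t)
      block
    })
    do.call(cbind, blocks)
  })
  values <- do.call(cbind, per_marker)
  rownames(values) <- sample_ids
  n_imputed <- sum(is.na(values))
  if (impute && n_imputed > 0) {
    for (j in which(colSums(is.na(values)) > 0)) {
      mu <- mean(values[, j], na.rm = TRUE)
      values[is.na(values[, j]), j] <- mu
    }
  }
  base_meta <- do.call(rbind, lapply(ensemble$solutions, function(sol) {
    data.frame(iteration = sol$iteration_id, metacluster = seq_len(sol$k_prime))
  }))
  column_meta <- do.call(rbind, lapply(functional_channels, function(t) {
    cbind(base_meta, marker = t)
  }))
  structure(list(values = values, column_meta = column_meta,
                 n_imputed = n_imputed),
            class = "functional_matrix")
}

#' Export a feature matrix to CSV
#'
#' Header columns follow the `iter{m}_mc{j}` (and `_marker` suffixed)
#' naming; the first column is `sample_id`.
#'
#' @param x a `freq_matrix` or `functional_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a feature matrix written by [write_features_csv()]
#' @param path CSV path.
#' @return A `freq_matrix` (column metadata reparsed from the header).
#' @export
read_features_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  meta <- do.call(rbind, lapply(colnames(values), function(nm) {
    m <- regmatches(nm, regexec("^iter([0-9]+)_mc([0-9]+)", nm))[[1]]
    data.frame(iteration = as.integer(m[2]), metacluster = as.integer(m[3]))
  }))
  structure(list(values = values, column_meta = meta,
                 sample_ids = rownames(values)),
            class = "freq_matrix")
}
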