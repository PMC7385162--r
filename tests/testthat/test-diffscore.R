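
# toy freq_matrix for significance tests
toy_F <- function(values, iteration = 1L) {
  colnames(values) <- sprintf("iter%d_mc%d", iteration, seq_len(ncol(values)))
  rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  structure(list(values = values,
                 column_meta = data.frame(iteration = iteration,
                                          metacluster = seq_len(ncol(values))),
                 sample_ids = rownames(values)),
            class = "freq_matrix")
}

test_that("rank-sum significance matches enumeration and its symmetries", {
  F <- toy_F(matrix(c(1, 2, 3, 4, 5, 6), ncol = 1))
  sig <- cluster_significance(F, labels = c(0, 0, 0, 1, 1, 1))
  expect_equal(sig$p_value, 0.1)          # 2/20 of all rank assignments
  expect_equal(sig$direction, 1)
  sig_swapped <- cluster_significance(F, labels = c(1, 1, 1, 0, 0, 0))
  expect_equal(sig_swapped$p_value, sig$p_value)
  expect_equal(sig_swapped$direction, -1)
  # identical multisets: maximal p
  F_tie <- toy_F(matrix(c(1, 2, 3, 1, 2, 3), ncol = 1))
  expect_equal(cluster_significance(F_tie, c(0, 0, 0, 1, 1, 1))$p_value, 1)
})

test_that("exact rank-sum p-values agree with full enumeration (sizes <= 7)", {
  set.seed(13)
  for (trial in 1:30) {
    na <- sample(2:7, 1)
    nb <- sample(2:7, 1)
    xa <- stats::runif(na)
    xb <- stats::runif(nb) + sample(c(0, 0.5), 1)
    F <- toy_F(matrix(c(xa, xb), ncol = 1))
    sig <- cluster_significance(F, labels = rep(c(0, 1), c(na, nb)))
    expect_equal(sig$p_value, enum_wilcox_p(xa, xb), tolerance = 1e-12)
  }
})

test_that("comparison subsets restrict the test and guard empty groups", {
  set.seed(3)
  F <- toy_F(matrix(stats::runif(20), ncol = 2))
  labels <- rep(c(0, 1), each = 5)
  subset_ids <- sprintf("s%02d", c(1:3, 6:8))
  sig_sub <- cluster_significance(F, labels, comparison_samples = subset_ids)
  manual <- suppressWarnings(stats::wilcox.test(
    F$values[1:3, 1], F$values[6:8, 1], exact = TRUE)$p.value)
  expect_equal(sig_sub$p_value[1], manual)
  expect_error(cluster_significance(F, labels,
                                    comparison_samples = sprintf("s%02d", 1:3)),
               "class empty|leaves a class")
})

test_that("subsampling is uniform, seeded, and honors exclusion masks", {
  synth <- tiny_cohort(n_patients_per_class = 2, cells_per_sample = 100)
  sub1 <- subsample_cells(synth$cohort, n_cells = 50, seed = 5)
  sub2 <- subsample_cells(synth$cohort, n_cells = 50, seed = 5)
  expect_identical(sub1$provenance, sub2$provenance)
  expect_identical(sub1$values, sub2$values)
  expect_equal(nrow(sub1$values), 50)
  # n >= total: identity subset with a warning
  expect_warning(all_cells <- subsample_cells(synth$cohort, n_cells = 1e6),
                 "taking all")
  expect_equal(nrow(all_cells$values), total_cells(synth$cohort))
  # excluding one sample's cells entirely
  banned <- synth$cohort$manifest$sample_id[1]
  excl <- local({
    first_vals <- synth$cohort$samples[[banned]]$values
    function(v) rep(identical(dim(v), dim(first_vals)) &&
                      all(v == first_vals), nrow(v))
  })
  sub3 <- subsample_cells(synth$cohort, n_cells = 50, exclude = excl, seed = 1)
  expect_false(banned %in% sub3$provenance$sample_id)
  # provenance rows match the values rows
  i <- 17
  expect_equal(unname(sub1$values[i, ]),
               unname(synth$cohort$samples[[sub1$provenance$sample_id[i]]]$values[
                 sub1$provenance$cell[i], ]))
})

test_that("2-D embeddings: linear sanity, determinism, pluggability", {
  collinear <- matrix(c(0, 1, 2, 0, 2, 4), ncol = 2)
  co <- embed_2d(collinear, method = "pca2")
  expect_equal(stats::sd(co[, 2]), 0, tolerance = 1e-10)  # stays collinear
  two <- embed_2d(matrix(c(0, 1, 0, 1), 2, 2), method = "pca2")
  expect_false(identical(two[1, ], two[2, ]))
  set.seed(8)
  x <- matrix(stats::rnorm(200), 50, 4)
  e1 <- embed_2d(x, method = "tsne", seed = 4)
  e2 <- embed_2d(x, method = "tsne", seed = 4)
  expect_identical(e1, e2)
  custom <- function(x, seed) cbind(x[, 1], x[, 2])
  expect_equal(embed_2d(x, method = custom)[, 1], x[, 1])
  expect_error(embed_2d(x, method = "umappy"), "unknown embedding")
})

test_that("cell similarity kernel has the right closed form and limits", {
  expect_equal(cell_similarity(c(1, 2), c(1, 2), alpha = 3), 1)
  expect_equal(cell_similarity(0, 2, alpha = 0.5), exp(-1))
  d <- c(0.1, 1, 5, 50)
  s <- vapply(d, function(z) cell_similarity(0, z, alpha = 1), numeric(1))
  expect_false(is.unsorted(rev(s), strictly = TRUE))  # monotone decreasing
  expect_error(cell_similarity(0, 1, alpha = 0), "alpha")
})

# two-center single-solution fixture for score arithmetic
two_center_solution <- function(w = c(0.01, 1)) {
  centers <- matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "x"))
  sol <- structure(list(iteration_id = 1L, meta_centers = centers,
                        cluster_to_meta = data.frame(sample_id = "s",
                                                     cluster = 1:2,
                                                     metacluster = 1:2),
                        k_prime = 2L),
                   class = "metacluster_solution")
  sig <- data.frame(iteration = 1L, metacluster = 1:2, column = 1:2,
                    p_value = w, direction = c(1, -1))
  list(sol = sol, sig = sig)
}

test_that("differentiation scores are similarity-weighted p averages", {
  fx <- two_center_solution(w = c(0.01, 1))
  # equidistant cell: plain average
  sc <- differentiation_scores(matrix(0, 1, 1), list(fx$sol), fx$sig,
                               alpha = 1, standardize = FALSE)
  expect_equal(sc, 0.505)
  # constant w: every cell scores w
  fxc <- two_center_solution(w = c(0.3, 0.3))
  cells <- matrix(stats::rnorm(10), 10, 1)
  expect_equal(differentiation_scores(cells, list(fxc$sol), fxc$sig,
                                      standardize = FALSE),
               rep(0.3, 10))
  # huge alpha: a cell on a center converges to that center's w
  on_center <- matrix(-1, 1, 1)
  sc_inf <- differentiation_scores(on_center, list(fx$sol), fx$sig,
                                   alpha = 200, standardize = FALSE)
  expect_equal(sc_inf, 0.01, tolerance = 1e-6)
})

test_that("scores stay within each solution's [min w, max w] band", {
  synth <- tiny_cohort(n_patients_per_class = 3, cells_per_sample = 120)
  ens <- tiny_ensemble(synth, k_per_sample = 10, k_prime = 4, n_iterations = 3)
  F <- frequency_features(synth$cohort, ens)
  sig <- cluster_significance(F, synth$cohort$manifest$class)
  sub <- subsample_cells(synth$cohort, n_cells = 200, seed = 2)
  scores <- differentiation_scores(sub$values, ens$solutions, sig)
  expect_gte(min(scores), min(sig$p_value))
  expect_lte(max(scores), max(sig$p_value))
})

test_that("extreme alpha underflow falls back to the nearest center's w", {
  fx <- two_center_solution(w = c(0.2, 0.9))
  far_cell <- matrix(1500, 1, 1)   # exp(-alpha*d) underflows for both centers
  expect_message(
    sc <- differentiation_scores(far_cell, list(fx$sol), fx$sig,
                                 alpha = 2, standardize = FALSE),
    "underflow")
  expect_equal(sc, 0.9)            # nearest center is the one at +1
})

test_that("render_map writes image, per-cell CSV and parameter JSON", {
  synth <- tiny_cohort(n_patients_per_class = 2, cells_per_sample = 80)
  ens <- tiny_ensemble(synth, k_per_sample = 8, k_prime = 3, n_iterations = 2)
  F <- frequency_features(synth$cohort, ens)
  map <- differentiation_map(synth$cohort, ens, F,
                             synth$cohort$manifest$class, n_cells = 60,
                             method = "pca2", seed = 1)
  out <- file.path(tempfile(), "nested")   # absent dir gets created
  paths <- render_map(map, out)
  expect_true(all(file.exists(paths)))
  df <- read.csv(file.path(out, "differentiation_map.csv"))
  expect_equal(nrow(df), 60)
  expect_identical(names(df), c("sample_id", "cell", "dim1", "dim2", "score"))
  # constant scores: degenerate colorbar handled
  map$scores <- rep(0.5, length(map$scores))
  expect_no_error(render_map(map, out, name = "flat"))
})
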