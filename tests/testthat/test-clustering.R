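test_that("cluster_sample recovers the obvious 1-D two-cluster split", {
  cm <- cell_matrix("s1", matrix(c(0, 0.1, 10, 10.1), ncol = 1,
                                 dimnames = list(NULL, "x")))
  sc <- cluster_sample(cm, k = 2, seed = 3)
  expect_setequal(round(sort(sc$centers[, 1]), 6), c(0.05, 10.05))
  expect_equal(sort(sc$sizes), c(2, 2))
  expect_equal(sc$assignments[1], sc$assignments[2])
  expect_equal(sc$assignments[3], sc$assignments[4])
})

test_that("degenerate cluster counts behave: singletons, k = 1, k > n", {
  vals <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "x"))
  cm <- cell_matrix("s1", vals)
  singles <- cluster_sample(cm, k = 3, seed = 1)
  expect_equal(sort(singles$centers[, 1]), c(1, 2, 3))
  expect_equal(singles$sizes, rep(1L, 3))
  same <- cell_matrix("s2", matrix(rep(2.5, 5), ncol = 1,
                                   dimnames = list(NULL, "x")))
  one <- cluster_sample(same, k = 1, seed = 1)
  expect_equal(nrow(one$centers), 1)
  expect_equal(unname(one$centers[1, 1]), 2.5)
  expect_error(cluster_sample(cm, k = 4, seed = 1), "lower k")
  expect_error(cluster_sample(cm, k = 0, seed = 1), "positive")
})

test_that("centers equal the mean of member cells and sizes sum to n", {
  synth <- tiny_cohort(n_patients_per_class = 2, cells_per_sample = 120)
  cm <- synth$cohort$samples[[1]]
  sc <- cluster_sample(cm, k = 8, seed = 5)
  expect_equal(sum(sc$sizes), cm$n_cells)
  for (c in seq_len(nrow(sc$centers))) {
    expect_equal(unname(sc$centers[c, ]),
                 unname(colMeans(cm$values[sc$assignments == c, , drop = FALSE])))
  }
})

test_that("k-means matches the exhaustive partition oracle on tiny instances", {
  set.seed(99)
  for (trial in 1:4) {
    n <- sample(6:8, 1)
    k <- sample(2:3, 1)
    x <- matrix(stats::rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    cm <- cell_matrix("t", x)
    sc <- cluster_sample(cm, k = k, seed = trial)
    expect_equal(wss_of(x, sc$assignments), best_wss_exhaustive(x, k),
                 tolerance = 1e-8)
  }
})

test_that("pool_centers concatenates with row-aligned provenance", {
  synth <- tiny_cohort(n_patients_per_class = 2, cells_per_sample = 80)
  scs <- lapply(synth$cohort$samples[1:2], cluster_sample, k = 3, seed = 1)
  pooled <- pool_centers(scs)
  expect_equal(nrow(pooled$centers), 6)
  expect_equal(pooled$provenance$sample_id, rep(c("s001", "s002"), each = 3))
  expect_equal(pooled$provenance$cluster, rep(1:3, 2))
  expect_equal(length(pooled$weights), 6)
  one <- pool_centers(scs[1])
  expect_equal(one$centers, scs[[1]]$centers)
  expect_error(pool_centers(list()), "no sample clusterings")
  bad <- scs
  colnames(bad[[2]]$centers) <- rev(colnames(bad[[2]]$centers))
  expect_error(pool_centers(bad), "channel order")
})

test_that("metacluster separates well-separated pooled centers", {
  pooled <- list(centers = matrix(c(0, 0.1, 10, 10.1), ncol = 1,
                                  dimnames = list(NULL, "x")),
                 provenance = data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                                         cluster = rep(1:2, 2)))
  sol <- metacluster(pooled, k_prime = 2, seed = 1)
  m <- sol$cluster_to_meta$metacluster
  expect_equal(m[1], m[2])   # the two low centers share a metacluster
  expect_equal(m[3], m[4])   # and the two high ones
  expect_true(m[1] != m[3])
  expect_error(metacluster(pooled, k_prime = 5), "exceeds")
  # K' = K: identity up to labeling
  all_sep <- metacluster(pooled, k_prime = 4, seed = 1)
  expect_equal(sort(unique(all_sep$cluster_to_meta$metacluster)), 1:4)
  # identical centers collapse to one metacluster
  flat <- list(centers = matrix(1, 3, 1, dimnames = list(NULL, "x")),
               provenance = data.frame(sample_id = "s1", cluster = 1:3))
  expect_equal(metacluster(flat, k_prime = 1, seed = 1)$k_prime, 1)
})

test_that("repeated_metacluster is deterministic and yields P = I * K'", {
  synth <- tiny_cohort(n_patients_per_class = 2, cells_per_sample = 150)
  e1 <- tiny_ensemble(synth, k_per_sample = 15, k_prime = 4, n_iterations = 3)
  e2 <- tiny_ensemble(synth, k_per_sample = 15, k_prime = 4, n_iterations = 3)
  expect_identical(lapply(e1$solutions, function(s) s$cluster_to_meta),
                   lapply(e2$solutions, function(s) s$cluster_to_meta))
  expect_equal(sum(vapply(e1$solutions, function(s) s$k_prime, numeric(1))),
               3 * 4)
  # distinct seeds across iterations give distinct solutions
  maps <- vapply(e1$solutions, function(s)
    paste(s$cluster_to_meta$metacluster, collapse = ","), character(1))
  expect_gt(length(unique(maps)), 1)
  single <- repeated_metacluster(synth$cohort, k_per_sample = 15, k_prime = 4,
                                 n_iterations = 1, master_seed = 11)
  expect_length(single$solutions, 1)
})

test_that("every cell gets exactly one metacluster label that sums to n_cells", {
  synth <- tiny_cohort(n_patients_per_class = 2, cells_per_sample = 100)
  ens <- tiny_ensemble(synth, k_per_sample = 10, k_prime = 3, n_iterations = 2)
  for (sol in ens$solutions) {
    for (i in seq_along(synth$cohort$samples)) {
      cm <- synth$cohort$samples[[i]]
      labels <- assign_cells(cm, ens$clusterings[[i]], sol)
      expect_length(labels, cm$n_cells)
      expect_false(anyNA(labels))
      expect_true(all(labels >= 1 & labels <= sol$k_prime))
      expect_equal(sum(tabulate(labels, sol$k_prime)), cm$n_cells)
    }
  }
  expect_error(assign_cells(synth$cohort$samples[[2]], ens$clusterings[[1]],
                            ens$solutions[[1]]), "does not belong")
})

test_that("a substitute clusterer drives both stages and keeps invariants", {
  # deterministic grid-quantile clusterer honoring (x, k, seed) -> assignments
  quantile_clusterer <- function(x, k, seed) {
    v <- x[, 1]
    br <- stats::quantile(v, probs = seq(0, 1, length.out = k + 1))
    br[1] <- -Inf; br[length(br)] <- Inf
    as.integer(cut(v, breaks = unique(br), include.lowest = TRUE))
  }
  synth <- tiny_cohort(n_patients_per_class = 2, cells_per_sample = 100)
  ens <- repeated_metacluster(synth$cohort, k_per_sample = 6, k_prime = 3,
                              n_iterations = 2, master_seed = 1,
                              clusterer = quantile_clusterer)
  F <- frequency_features(synth$cohort, ens)
  for (it in unique(F$column_meta$iteration)) {
    block <- F$values[, F$column_meta$iteration == it, drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, nrow(block)), tolerance = 1e-12)
  }
})
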