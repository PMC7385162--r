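# Seed derivation: a small counter-based mixing scheme so that every
# sample and every metaclustering iteration gets its own reproducible
# seed from one master seed, independently of execution order (and hence
# of any parallel scheduling). Streams keep stages from colliding.
child_seed <- function(master_seed, stream, index) {
  s <- (as.double(master_seed) * 2654435761 + stream * 97003 + index * 8191) %%
    2147483629
  as.integer(s) + 1L
}

# k-means++ seeding: first center uniform, each next center drawn with
# probability proportional to squared distance to the nearest chosen
# center. Consumes the current RNG stream.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 <= 0)) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2)
    }
    dj <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  x[centers, , drop = FALSE]
}

#' Default k-means clusterer
#'
#' Returns a clusterer function with the signature
#' `function(x, k, seed) -> integer assignments` used by both
#' clustering stages: k-means with k-means++ initialization and
#' `nstart` restarts, keeping the solution with the lowest total
#' within-cluster sum of squares. Any function honouring the same
#' contract (deterministic given `seed`, assignments in `1..k`) can be
#' substituted in either stage, e.g. an adapter around FlowSOM- or
#' PhenoGraph-style clustering.
#'
#' @param nstart number of k-means++ restarts (default 10).
#' @param iter.max maximum Lloyd/Hartigan-Wong iterations per restart.
#' @return a clusterer `function(x, k, seed)`.
#' @export
kmeans_clusterer <- function(nstart = 10, iter.max = 100) {
  force(nstart); force(iter.max)
  function(x, k, seed) {
    x <- as.matrix(x)
    n <- nrow(x)
    ux <- unique(x)
    if (nrow(ux) <= k) {
      # fewer distinct points than requested clusters: each distinct
      # value becomes its own cluster (empty clusters are dropped by
      # the caller)
      return(match(apply(x, 1, paste, collapse = "\r"),
                   apply(ux, 1, paste, collapse = "\r")))
    }
    set.seed(seed)
    best <- NULL
    best_ss <- Inf
    for (r in seq_len(nstart)) {
      init <- kmeanspp_centers(x, k)
      km <- tryCatch(
        stats::kmeans(x, centers = init, iter.max = iter.max),
        error = function(e) NULL,
        warning = function(w) suppressWarnings(
          stats::kmeans(x, centers = init, iter.max = iter.max,
                        algorithm = "MacQueen"))
      )
      if (is.null(km)) next
      if (km$tot.withinss < best_ss) {
        best_ss <- km$tot.withinss
        best <- km$cluster
      }
    }
    if (is.null(best)) stop("k-means failed for all restarts")
    best
  }
}

#' Cluster the cells of one sample
#'
#' First pipeline stage: the cells of each sample are coarsely
#' over-clustered (default in production-scale panels: 1000 clusters per
#' sample) so that every cell contributes to some pooled center and no
#' downsampling is needed. Empty clusters are dropped and centers are
#' recomputed as the exact mean of member cells.
#'
#' @param cells a [cell_matrix()].
#' @param k number of within-sample clusters (upper bound; at most
#'   `n_cells`).
#' @param seed RNG seed for the clusterer.
#' @param clusterer a clusterer function, see [kmeans_clusterer()].
#' @return A `sample_clustering`: list with `sample_id`, `assignments`
#'   (per-cell cluster index in `1..k_eff`), `centers` (`k_eff x m`),
#'   `sizes`.
#' @export
cluster_sample <- function(cells, k, seed = 1L, clusterer = kmeans_clusterer()) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (k < 1) stop("k must be a positive integer")
  if (k > cells$n_cells) {
    stop("k (", k, ") exceeds the number of cells (", cells$n_cells,
         ") in sample '", cells$sample_id, "'; lower k")
  }
  assignments <- as.integer(clusterer(cells$values, as.integer(k), seed))
  # drop empty clusters, relabel contiguously, recompute exact centers
  used <- sort(unique(assignments))
  assignments <- match(assignments, used)
  k_eff <- length(used)
  m <- ncol(cells$values)
  centers <- matrix(0, k_eff, m, dimnames = list(NULL, colnames(cells$values)))
  sizes <- tabulate(assignments, nbins = k_eff)
  for (j in seq_len(m)) {
    centers[, j] <- rowsum(cells$values[, j], assignments)[, 1] / sizes
  }
  structure(list(sample_id = cells$sample_id, assignments = assignments,
                 centers = centers, sizes = sizes),
            class = "sample_clustering")
}

#' Pool cluster centers across samples
#'
#' Concatenates all within-sample cluster centers into one `K x m`
#' matrix with row-aligned provenance (which sample and which
#' within-sample cluster each pooled row came from) and cluster sizes
#' as weights (kept for diagnostics; metaclustering itself is
#' unweighted).
#'
#' @param clusterings list of `sample_clustering` objects sharing one
#'   channel order.
#' @return list with `centers` (`K x m`), `provenance`
#'   (data.frame `sample_id`, `cluster`), `weights`.
#' @export
pool_centers <- function(clusterings) {
  if (length(clusterings) == 0) stop("no sample clusterings to pool")
  ch <- lapply(clusterings, function(sc) colnames(sc$centers))
  if (!all(vapply(ch, identical, logical(1), y = ch[[1]]))) {
    stop("channel order differs between sample clusterings")
  }
  centers <- do.call(rbind, lapply(clusterings, function(sc) sc$centers))
  provenance <- do.call(rbind, lapply(clusterings, function(sc) {
    data.frame(sample_id = sc$sample_id, cluster = seq_len(nrow(sc$centers)),
               stringsAsFactors = FALSE)
  }))
  rownames(provenance) <- NULL
  list(centers = centers, provenance = provenance,
       weights = unlist(lapply(clusterings, function(sc) sc$sizes), use.names = FALSE))
}

#' Metacluster pooled centers
#'
#' Clusters the pooled within-sample centers into `k_prime`
#' metaclusters, defining one stochastic cell-population solution. The
#' `cluster_to_meta` mapping is total: every pooled cluster (hence every
#' cell) belongs to exactly one metacluster.
#'
#' @param pooled output of [pool_centers()].
#' @param k_prime number of metaclusters (at most `K`, the number of
#'   pooled centers).
#' @param seed RNG seed.
#' @param iteration_id which metaclustering iteration this solution is.
#' @param clusterer a clusterer function, see [kmeans_clusterer()].
#' @return A `metacluster_solution`: list with `iteration_id`,
#'   `meta_centers` (`K'_m x m`), `cluster_to_meta` (data.frame
#'   `sample_id`, `cluster`, `metacluster`), `k_prime`.
#' @export
metacluster <- function(pooled, k_prime, seed = 1L, iteration_id = 1L,
                        clusterer = kmeans_clusterer()) {
  K <- nrow(pooled$centers)
  if (k_prime > K) stop("k_prime (", k_prime, ") exceeds the number of pooled centers (", K, ")")
  if (k_prime < 1) stop("k_prime must be a positive integer")
  assign_meta <- as.integer(clusterer(pooled$centers, as.integer(k_prime), seed))
  used <- sort(unique(assign_meta))
  assign_meta <- match(assign_meta, used)
  k_eff <- length(used)
  sizes <- tabulate(assign_meta, nbins = k_eff)
  m <- ncol(pooled$centers)
  meta_centers <- matrix(0, k_eff, m,
                         dimnames = list(NULL, colnames(pooled$centers)))
  for (j in seq_len(m)) {
    meta_centers[, j] <- rowsum(pooled$centers[, j], assign_meta)[, 1] / sizes
  }
  cluster_to_meta <- pooled$provenance
  cluster_to_meta$metacluster <- assign_meta
  structure(list(iteration_id = as.integer(iteration_id),
                 meta_centers = meta_centers,
                 cluster_to_meta = cluster_to_meta,
                 k_prime = k_eff),
            class = "metacluster_solution")
}

#' Repeated metaclustering over a cohort
#'
#' The core population-discovery routine. Every sample is clustered once
#' (no downsampling: all cells of all samples contribute), the centers
#' are pooled, and the pooled centers are re-clustered `n_iterations`
#' times with independent derived seeds, giving `I` stochastic
#' metaclustering solutions whose variability downstream stages exploit.
#'
#' @param cohort a `cyto_cohort` (see [load_cohort()]).
#' @param k_per_sample within-sample cluster count `k_i` (capped at each
#'   sample's cell count). Default 1000.
#' @param k_prime metaclusters per solution. Default 50.
#' @param n_iterations number of metaclustering solutions `I`. Default 50.
#' @param master_seed single seed governing both stages.
#' @param clusterer clusterer used in both stages ([kmeans_clusterer()]
#'   by default; pluggable).
#' @param recluster_each if `TRUE`, the within-sample clustering stage is
#'   re-run for every iteration instead of being shared (slower; default
#'   `FALSE`: stochasticity enters at the metaclustering stage).
#' @return A `metacluster_ensemble`: list with `clusterings` (per-sample
#'   `sample_clustering`, shared case), `solutions` (list of `I`
#'   `metacluster_solution`s), `k_per_sample`, `master_seed`.
#' @export
repeated_metacluster <- function(cohort, k_per_sample = 1000, k_prime = 50,
                                 n_iterations = 50, master_seed = 1L,
                                 clusterer = kmeans_clusterer(),
                                 recluster_each = FALSE) {
  stopifnot(inherits(cohort, "cyto_cohort"))
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  cluster_once <- function(stream) {
    lapply(seq_along(cohort$samples), function(i) {
      s <- cohort$samples[[i]]
      cluster_sample(s, k = min(k_per_sample, s$n_cells),
                     seed = child_seed(master_seed, stream, i),
                     clusterer = clusterer)
    })
  }
  clusterings <- cluster_once(stream = 1L)
  solutions <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    cl_it <- if (recluster_each && it > 1L) cluster_once(stream = 100L + it) else clusterings
    pooled <- pool_centers(cl_it)
    solutions[[it]] <- metacluster(pooled, k_prime = k_prime,
                                   seed = child_seed(master_seed, 2L, it),
                                   iteration_id = it, clusterer = clusterer)
  }
  structure(list(clusterings = clusterings, solutions = solutions,
                 k_per_sample = k_per_sample, master_seed = master_seed,
                 recluster_each = recluster_each),
            class = "metacluster_ensemble")
}

#' @export
print.metacluster_ensemble <- function(x, ...) {
  K <- sum(vapply(x$clusterings, function(sc) nrow(sc$centers), numeric(1)))
  P <- sum(vapply(x$solutions, function(s) s$k_prime, numeric(1)))
  cat(sprintf("metacluster_ensemble: %d samples, K = %d pooled clusters, I = %d solutions, P = %d metaclusters\n",
              length(x$clusterings), K, length(x$solutions), P))
  invisible(x)
}

#' Per-cell metacluster labels for one sample under one solution
#'
#' Composes the per-cell within-sample assignment with the solution's
#' cluster-to-metacluster map; every cell receives exactly one label.
#'
#' @param cells the sample's [cell_matrix()] (used for identity checks).
#' @param clustering the sample's `sample_clustering`.
#' @param solution a `metacluster_solution` covering the sample.
#' @return integer vector of per-cell metacluster labels.
#' @export
assign_cells <- function(cells, clustering, solution) {
  if (!identical(cells$sample_id, clustering$sample_id)) {
    stop("clustering does not belong to sample '", cells$sample_id, "'")
  }
  map <- solution$cluster_to_meta
  map <- map[map$sample_id == clustering$sample_id, , drop = FALSE]
  lut <- rep(NA_integer_, max(map$cluster, clustering$assignments))
  lut[map$cluster] <- map$metacluster
  labels <- lut[clustering$assignments]
  if (anyNA(labels)) {
    stop("internal consistency error: unmapped within-sample cluster for sample '",
         cells$sample_id, "'")
  }
  labels
}
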