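#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list; values
#' mirror the production-scale defaults of each stage (k_i = 1000
#' within-sample clusters, K' = 50 metaclusters, I = 50 solutions, top
#' 40 features per solution, B = 500 CV iterations, 30000 visualization
#' cells). Override any entry via the `config` argument of
#' [run_pipeline()] or a YAML config file.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    panel = NULL,                    # path to panel YAML/JSON
    manifest = NULL,                 # path to manifest CSV
    output_dir = "cytopool_output",
    master_seed = 1L,
    clustering = list(k_per_sample = 1000, k_prime = 50, n_iterations = 50,
                      recluster_each = FALSE),
    feature_selection = list(enabled = TRUE, k_nn = 5, bandwidth = NULL,
                             top_m = 40, kernel = "heat"),
    cv = list(B = 500, train_fraction = 0.5, ntree = 100, n_trials = 0),
    viz = list(enabled = TRUE, n_cells = 30000, alpha = 1, method = "tsne",
               comparison_samples = NULL)
  )
}

# deep-merge overrides into defaults
merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' @param config a YAML file path or a (possibly partial) nested list;
#'   missing entries take [default_config()] values.
#' @return validated configuration list.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  problems <- character(0)
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(!is.null(cfg$manifest), "manifest path is required")
  chk(!is.null(cfg$panel), "panel path is required")
  if (!is.null(cfg$manifest)) chk(file.exists(cfg$manifest),
                                  paste0("manifest not found: ", cfg$manifest))
  if (!is.null(cfg$panel)) chk(file.exists(cfg$panel),
                               paste0("panel not found: ", cfg$panel))
  chk(cfg$clustering$k_per_sample >= 1, "clustering.k_per_sample must be >= 1")
  chk(cfg$clustering$k_prime >= 2, "clustering.k_prime must be >= 2")
  chk(cfg$clustering$n_iterations >= 1, "clustering.n_iterations must be >= 1")
  chk(cfg$feature_selection$top_m >= 1, "feature_selection.top_m must be >= 1")
  chk(cfg$feature_selection$k_nn >= 1, "feature_selection.k_nn must be >= 1")
  chk(cfg$cv$B >= 1, "cv.B must be >= 1")
  chk(cfg$cv$train_fraction > 0 && cfg$cv$train_fraction < 1,
      "cv.train_fraction must be in (0,1)")
  chk(cfg$viz$n_cells >= 1, "viz.n_cells must be >= 1")
  chk(cfg$viz$alpha > 0, "viz.alpha must be positive")
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  cfg
}

config_hash <- function(cfg) rlang::hash(cfg)

write_provenance <- function(dir, stage, cfg, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, config_hash = config_hash(cfg),
           master_seed = cfg$master_seed,
           package_version = as.character(utils::packageVersion("cytopool"))),
      extra),
    file.path(dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

check_provenance <- function(dir, stage, producing_cmd) {
  p <- file.path(dir, paste0(stage, "_provenance.json"))
  if (!file.exists(p)) {
    stop("missing artifacts for stage '", stage, "': run `", producing_cmd,
         "` first")
  }
  jsonlite::read_json(p)
}

#' Persist a metaclustering ensemble
#'
#' One pair of CSVs per iteration — metacluster centers (channels as
#' columns) and the (sample_id, cluster, metacluster) map — plus the
#' per-sample per-cell cluster assignments, so downstream stages can be
#' rerun from disk.
#'
#' @param ensemble a `metacluster_ensemble`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_solutions <- function(ensemble, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sol in ensemble$solutions) {
    data.table::fwrite(as.data.frame(sol$meta_centers),
                       file.path(dir, sprintf("iter%03d_centers.csv",
                                              sol$iteration_id)))
    data.table::fwrite(sol$cluster_to_meta,
                       file.path(dir, sprintf("iter%03d_map.csv",
                                              sol$iteration_id)))
  }
  assignments <- do.call(rbind, lapply(ensemble$clusterings, function(sc) {
    data.frame(sample_id = sc$sample_id, cell = seq_along(sc$assignments),
               cluster = sc$assignments)
  }))
  data.table::fwrite(assignments, file.path(dir, "assignments.csv"))
  invisible(dir)
}

#' Reload a persisted metaclustering ensemble
#'
#' Inverse of [write_solutions()]: reads the per-cell assignments and
#' per-iteration maps and recomputes per-sample centers/sizes from the
#' cohort's cells.
#'
#' @param dir directory written by [write_solutions()].
#' @param cohort the `cyto_cohort` the solutions were computed on.
#' @return a `metacluster_ensemble`.
#' @export
read_solutions <- function(dir, cohort) {
  apath <- file.path(dir, "assignments.csv")
  if (!file.exists(apath)) stop("no persisted solutions in ", dir)
  assignments <- as.data.frame(data.table::fread(apath))
  clusterings <- lapply(cohort$manifest$sample_id, function(sid) {
    a <- assignments$cluster[assignments$sample_id == sid]
    cells <- cohort$samples[[sid]]
    if (length(a) != cells$n_cells) {
      stop("persisted assignments for '", sid, "' do not match the cohort")
    }
    k_eff <- max(a)
    sizes <- tabulate(a, nbins = k_eff)
    centers <- matrix(0, k_eff, ncol(cells$values),
                      dimnames = list(NULL, colnames(cells$values)))
    for (j in seq_len(ncol(cells$values))) {
      centers[, j] <- rowsum(cells$values[, j], a)[, 1] / sizes
    }
    structure(list(sample_id = sid, assignments = a, centers = centers,
                   sizes = sizes), class = "sample_clustering")
  })
  map_files <- sort(list.files(dir, pattern = "^iter[0-9]+_map\\.csv$",
                               full.names = TRUE))
  solutions <- lapply(map_files, function(mf) {
    it <- as.integer(sub("^iter0*([0-9]+)_map\\.csv$", "\\1", basename(mf)))
    cmap <- as.data.frame(data.table::fread(mf))
    centers <- as.matrix(data.table::fread(
      file.path(dir, sprintf("iter%03d_centers.csv", it))))
    structure(list(iteration_id = it, meta_centers = centers,
                   cluster_to_meta = cmap, k_prime = nrow(centers)),
              class = "metacluster_solution")
  })
  structure(list(clusterings = clusterings, solutions = solutions,
                 k_per_sample = NA, master_seed = NA, recluster_each = FALSE),
            class = "metacluster_ensemble")
}

#' Run the full pipeline
#'
#' Executes load -> repeated metaclustering -> frequency features ->
#' unsupervised feature selection -> patient-level bootstrapped CV ->
#' differentiation-score visualization, writing every artifact family
#' (solutions, features, selection, CV result, map) under
#' `config$output_dir` with provenance JSONs (config hash, master seed,
#' package version). Deterministic: rerunning an identical config
#' reproduces all numeric artifacts byte-for-byte.
#'
#' @param config a config list or YAML path, see [read_config()].
#' @param verbose log one line per stage.
#' @return invisibly, a list with the in-memory stage results and a
#'   `results` summary (AUROC, B_effective, P, retained feature count,
#'   per-stage runtimes) that is also written to `results.json`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cfg <- read_config(config)
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  times <- list()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  cohort <- load_cohort(cfg$manifest, cfg$panel, verbose = FALSE)
  labels <- cohort$manifest$class
  times$load <- toc(t0)
  say("load: %d samples, %d cells, %d channels", length(cohort$samples),
      total_cells(cohort), length(panel_channels(cohort$panel)))

  t0 <- tic()
  ensemble <- repeated_metacluster(
    cohort, k_per_sample = cfg$clustering$k_per_sample,
    k_prime = cfg$clustering$k_prime,
    n_iterations = cfg$clustering$n_iterations,
    master_seed = cfg$master_seed,
    recluster_each = isTRUE(cfg$clustering$recluster_each))
  K <- sum(vapply(ensemble$clusterings, function(sc) nrow(sc$centers), numeric(1)))
  P <- sum(vapply(ensemble$solutions, function(s) s$k_prime, numeric(1)))
  sol_dir <- file.path(out, "solutions")
  write_solutions(ensemble, sol_dir)
  write_provenance(sol_dir, "cluster", cfg, list(K = K, P = P))
  times$cluster <- toc(t0)
  say("cluster: K = %d pooled clusters, I = %d solutions, P = %d metaclusters",
      K, length(ensemble$solutions), P)

  t0 <- tic()
  F <- frequency_features(cohort, ensemble)
  write_features_csv(F, file.path(out, "frequency_features.csv"))
  write_provenance(out, "featurize", cfg, list(P = P))
  times$featurize <- toc(t0)
  say("featurize: %d x %d frequency matrix", nrow(F$values), ncol(F$values))

  selection <- NULL
  if (isTRUE(cfg$feature_selection$enabled)) {
    t0 <- tic()
    selection <- select_features(F, k_nn = cfg$feature_selection$k_nn,
                                 bandwidth = cfg$feature_selection$bandwidth,
                                 top_m = cfg$feature_selection$top_m,
                                 kernel = cfg$feature_selection$kernel)
    write_selection_csv(selection, file.path(out, "feature_selection.csv"))
    write_provenance(out, "select", cfg,
                     list(retained = sum(selection$retained)))
    times$select <- toc(t0)
    say("select: retained %d / %d features", sum(selection$retained), P)
  }

  t0 <- tic()
  features <- selected_matrix(F, selection)
  cv <- run_cv(features, labels, cohort$manifest$patient_id,
               B = cfg$cv$B, train_fraction = cfg$cv$train_fraction,
               classifier = rf_classifier(ntree = cfg$cv$ntree),
               seed = cfg$master_seed)
  write_cv_csv(cv, file.path(out, "cv_predictions.csv"),
               file.path(out, "cv_summary.json"))
  write_provenance(out, "classify", cfg, list(auroc = cv$auroc))
  times$classify <- toc(t0)
  say("classify: AUROC = %.4f (B_effective = %d, d = %d features)",
      cv$auroc, cv$B_effective, ncol(features))

  map <- NULL
  if (isTRUE(cfg$viz$enabled)) {
    t0 <- tic()
    map <- differentiation_map(cohort, ensemble, F, labels,
                               n_cells = cfg$viz$n_cells,
                               comparison_samples = cfg$viz$comparison_samples,
                               alpha = cfg$viz$alpha, method = cfg$viz$method,
                               seed = cfg$master_seed)
    render_map(map, file.path(out, "viz"))
    write_provenance(file.path(out, "viz"), "viz", cfg,
                     list(n_cells = nrow(map$cells)))
    times$viz <- toc(t0)
    say("viz: %d cells mapped (method = %s)", nrow(map$cells), map$method)
  }

  results <- list(auroc = cv$auroc, B_effective = cv$B_effective,
                  K = K, P = P,
                  retained_features = if (is.null(selection)) P else
                    sum(selection$retained),
                  n_samples = length(cohort$samples),
                  total_cells = total_cells(cohort),
                  master_seed = cfg$master_seed,
                  config_hash = config_hash(cfg),
                  runtime_seconds = times)
  jsonlite::write_json(results, file.path(out, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, ensemble = ensemble, F = F,
                 selection = selection, cv = cv, map = map,
                 results = results, config = cfg))
}
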