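#' Define a synthetic cell population
#'
#' One Gaussian cell population on the transformed (post-arcsinh)
#' expression scale: diagonal covariance, a cohort-level base frequency,
#' and a multiplicative frequency effect applied in class-1 samples
#' (1.0 = null; shifted frequency vectors are renormalized to sum to 1).
#'
#' @param name population name.
#' @param mean length-`m` channel mean vector.
#' @param variance length-`m` vector of positive channel variances
#'   (recycled if length 1).
#' @param base_frequency base proportion of cells in the population.
#' @param effect class-1 multiplicative frequency shift (default 1).
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, mean, variance = 0.1225, base_frequency,
                            effect = 1) {
  variance <- rep_len(as.numeric(variance), length(mean))
  if (any(variance <= 0)) stop("variances must be positive")
  if (base_frequency <= 0 || base_frequency >= 1) {
    stop("base_frequency must be in (0, 1)")
  }
  if (effect <= 0) stop("effect must be positive")
  structure(list(name = as.character(name), mean = as.numeric(mean),
                 variance = variance, base_frequency = as.numeric(base_frequency),
                 effect = as.numeric(effect)),
            class = "population_spec")
}

#' Default synthetic fixture populations
#'
#' Five well-separated Gaussian immune-like populations over 10 channels
#' (6 phenotypic + 4 functional), channel sd 0.35 on the arcsinh scale,
#' base frequencies (0.30, 0.25, 0.20, 0.15, 0.10). One population
#' ("mono_act", base 0.15) carries a 1.5x frequency effect in class 1;
#' set `effect = 1` for a fully null design.
#'
#' @param effect multiplicative effect planted on the effect population.
#' @return list of [population_spec()]s.
#' @export
default_fixture_specs <- function(effect = 1.5) {
  sd2 <- 0.35^2
  list(
    population_spec("tcell",    c(4.0, 0.5, 0.5, 3.0, 0.5, 0.5,  1.0, 0.5, 0.5, 1.0),
                    sd2, 0.30),
    population_spec("bcell",    c(0.5, 4.0, 0.5, 0.5, 3.0, 0.5,  0.5, 1.0, 0.5, 0.5),
                    sd2, 0.25),
    population_spec("nk",       c(0.5, 0.5, 4.0, 0.5, 0.5, 3.0,  0.5, 0.5, 1.5, 0.5),
                    sd2, 0.20),
    population_spec("mono_act", c(3.0, 0.5, 3.0, 0.5, 3.0, 0.5,  2.5, 2.0, 0.5, 1.5),
                    sd2, 0.15, effect = effect),
    population_spec("dc",       c(0.5, 3.0, 0.5, 3.0, 0.5, 3.0,  0.5, 0.5, 2.0, 2.5),
                    sd2, 0.10)
  )
}

#' Default synthetic fixture panel
#'
#' 10 channels matching [default_fixture_specs()]: `pheno1..6`
#' phenotypic, `func1..4` functional, transform "none" (populations are
#' simulated directly on the transformed scale).
#'
#' @return A [marker_panel()].
#' @export
default_fixture_panel <- function() {
  marker_panel(c(paste0("pheno", 1:6), paste0("func", 1:4)),
               role = c(rep("phenotypic", 6), rep("functional", 4)),
               transform = "none")
}

# Dirichlet(kappa * target) draw via independent gammas
rdirichlet1 <- function(target, kappa) {
  g <- stats::rgamma(length(target), shape = kappa * target, rate = 1)
  if (sum(g) == 0) g[which.max(target)] <- 1
  g / sum(g)
}

#' Generate a synthetic cytometry cohort
#'
#' Multi-sample Gaussian-mixture cohort with known ground truth. Class
#' target frequency vectors are the population base frequencies, with
#' each population's `effect` applied multiplicatively in class 1 and
#' the vector renormalized. Per sample, population proportions are
#' drawn from a Dirichlet centered on the class target with
#' concentration `freq_noise_kappa` (larger = less inter-sample
#' variation), cell counts from a multinomial, and cell expression from
#' the population Gaussians.
#'
#' @param specs list of [population_spec()]s (base frequencies must sum
#'   to 1; at least 2 populations).
#' @param n_patients_per_class patients per class (default 10).
#' @param samples_per_patient samples per patient (default 1).
#' @param cells_per_sample cells per sample (>= 50; default 2000).
#' @param freq_noise_kappa Dirichlet concentration (default 100,
#'   i.e. ~20-25% coefficient of variation for mid-frequency
#'   populations — typical inter-sample immune variation).
#' @param seed RNG seed.
#' @return A `synthetic_cohort`: list with `cohort` (a `cyto_cohort`),
#'   `truth` (per-sample `cell_populations` labels, `target_frequencies`,
#'   `sample_frequencies`, `effect_populations`), `specs`.
#' @export
generate_cohort <- function(specs, n_patients_per_class = 10,
                            samples_per_patient = 1, cells_per_sample = 2000,
                            freq_noise_kappa = 100, seed = 1L) {
  if (length(specs) < 2) stop("need at least 2 populations")
  base <- vapply(specs, function(p) p$base_frequency, numeric(1))
  if (abs(sum(base) - 1) > 1e-8) {
    stop("population base frequencies must sum to 1 (got ", sum(base), ")")
  }
  if (cells_per_sample < 50) stop("cells_per_sample must be >= 50")
  m <- length(specs[[1]]$mean)
  if (any(vapply(specs, function(p) length(p$mean), integer(1)) != m)) {
    stop("all population mean vectors must share one length")
  }
  pop_names <- vapply(specs, function(p) p$name, character(1))
  effects <- vapply(specs, function(p) p$effect, numeric(1))
  target <- list("0" = base, "1" = {
    shifted <- base * effects
    shifted / sum(shifted)
  })
  panel <- if (m == 10) default_fixture_panel() else {
    n_pheno <- max(1, ceiling(m * 0.6))
    marker_panel(c(paste0("pheno", seq_len(n_pheno)),
                   if (m > n_pheno) paste0("func", seq_len(m - n_pheno))),
                 role = c(rep("phenotypic", n_pheno),
                          rep("functional", m - n_pheno)),
                 transform = "none")
  }
  channels <- panel_channels(panel)

  n_samples <- 2 * n_patients_per_class * samples_per_patient
  manifest <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n_samples)),
    patient_id = sprintf("p%03d", rep(seq_len(2 * n_patients_per_class),
                                      each = samples_per_patient)),
    class = rep(c(0L, 1L), each = n_patients_per_class * samples_per_patient),
    path = NA_character_, stringsAsFactors = FALSE
  )

  set.seed(seed)
  samples <- vector("list", n_samples)
  cell_pops <- vector("list", n_samples)
  sample_freqs <- matrix(0, n_samples, length(specs),
                         dimnames = list(manifest$sample_id, pop_names))
  for (i in seq_len(n_samples)) {
    tv <- target[[as.character(manifest$class[i])]]
    props <- rdirichlet1(tv, freq_noise_kappa)
    counts <- as.integer(stats::rmultinom(1, cells_per_sample, props))
    pop_of_cell <- rep(seq_along(specs), counts)
    x <- matrix(0, cells_per_sample, m, dimnames = list(NULL, channels))
    for (p in seq_along(specs)) {
      if (counts[p] == 0) next
      rows <- pop_of_cell == p
      x[rows, ] <- matrix(stats::rnorm(counts[p] * m,
                                       mean = rep(specs[[p]]$mean, each = counts[p]),
                                       sd = rep(sqrt(specs[[p]]$variance),
                                                each = counts[p])),
                          counts[p], m)
    }
    perm <- sample.int(cells_per_sample)      # shuffle so pops interleave
    samples[[i]] <- cell_matrix(manifest$sample_id[i], x[perm, , drop = FALSE])
    cell_pops[[i]] <- pop_names[pop_of_cell[perm]]
    sample_freqs[i, ] <- counts / cells_per_sample
  }
  names(samples) <- manifest$sample_id
  names(cell_pops) <- manifest$sample_id
  cohort <- structure(list(samples = samples, manifest = manifest, panel = panel),
                      class = "cyto_cohort")
  structure(list(
    cohort = cohort,
    truth = list(cell_populations = cell_pops,
                 target_frequencies = target,
                 sample_frequencies = sample_freqs,
                 effect_populations = pop_names[effects != 1]),
    specs = specs),
    class = "synthetic_cohort")
}

#' Generate a null synthetic cohort
#'
#' As [generate_cohort()] but with every population effect forced to 1,
#' so class labels are independent of the data by construction; the
#' truth's `effect_populations` is empty.
#'
#' @inheritParams generate_cohort
#' @return A `synthetic_cohort`.
#' @export
generate_null_cohort <- function(specs, n_patients_per_class = 10,
                                 samples_per_patient = 1,
                                 cells_per_sample = 2000,
                                 freq_noise_kappa = 100, seed = 1L) {
  null_specs <- lapply(specs, function(p) {
    p$effect <- 1
    p
  })
  generate_cohort(null_specs, n_patients_per_class = n_patients_per_class,
                  samples_per_patient = samples_per_patient,
                  cells_per_sample = cells_per_sample,
                  freq_noise_kappa = freq_noise_kappa, seed = seed)
}

#' Write a synthetic cohort to disk
#'
#' Emits one CSV per sample, a manifest CSV with resolved paths, a panel
#' YAML, and a truth JSON — a valid on-disk cohort for [load_cohort()]
#' and the command-line interface.
#'
#' @param synth a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_cohort_csv <- function(synth, dir) {
  stopifnot(inherits(synth, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- synth$cohort$manifest
  for (i in seq_len(nrow(manifest))) {
    p <- file.path(dir, paste0(manifest$sample_id[i], ".csv"))
    write_cells_csv(synth$cohort$samples[[manifest$sample_id[i]]], p)
    manifest$path[i] <- p
  }
  man_path <- file.path(dir, "manifest.csv")
  data.table::fwrite(manifest, man_path)
  write_panel(synth$cohort$panel, file.path(dir, "panel.yaml"))
  jsonlite::write_json(
    list(effect_populations = synth$truth$effect_populations,
         target_frequencies = synth$truth$target_frequencies,
         cell_populations = synth$truth$cell_populations),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(man_path)
}
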