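#' Random-forest classifier for the CV pipeline
#'
#' Wraps [randomForest::randomForest()] in the pluggable classifier
#' contract used by [run_cv()]: a list with `fit(x, y)` returning a
#' model and `predict_prob(model, x)` returning class-1 probabilities.
#' Any probabilistic classifier honouring the contract can substitute.
#'
#' @param ntree number of trees (default 100); `mtry` is left at the
#'   randomForest default (`sqrt(d)` for classification).
#' @return classifier contract list.
#' @export
rf_classifier <- function(ntree = 100) {
  force(ntree)
  list(
    fit = function(x, y) {
      randomForest::randomForest(x = as.matrix(x), y = factor(y, levels = c(0, 1)),
                                 ntree = ntree)
    },
    predict_prob = function(model, x) {
      unname(stats::predict(model, newdata = as.matrix(x), type = "prob")[, "1"])
    }
  )
}

#' Split patients into training and test halves
#'
#' Splits operate on patients, never on samples: all samples of a
#' patient land on the same side, so repeated measures cannot leak
#' between training and test. `floor(train_fraction * n_patients)`
#' patients go to training, the remainder to test.
#'
#' @param patients character vector of unique patient ids.
#' @param train_fraction fraction of patients trained on (default 0.5).
#' @param seed RNG seed.
#' @param class_of optional named vector mapping patient id to class
#'   label; when supplied, the split is stratified by class
#'   (`floor(train_fraction * n_c)` training patients drawn within each
#'   class). Stratification keeps the training class composition
#'   independent of the test composition, which removes the pessimistic
#'   null bias of simple random halves (see the methods vignette);
#'   simple random halves remain the default.
#' @return list with `train` and `test` patient-id vectors.
#' @export
split_patients <- function(patients, train_fraction = 0.5, seed = 1L,
                           class_of = NULL) {
  patients <- unique(patients)
  if (length(patients) < 2) stop("need at least 2 patients to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  set.seed(seed)
  if (is.null(class_of)) {
    n_train <- max(1L, floor(train_fraction * length(patients)))
    train <- sample(patients, n_train)
  } else {
    train <- unlist(lapply(split(patients, class_of[patients]), function(pc) {
      sample(pc, max(1L, floor(train_fraction * length(pc))))
    }), use.names = FALSE)
  }
  list(train = train, test = setdiff(patients, train))
}

#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney rank statistic: the probability that a
#' uniformly chosen positive sample scores above a uniformly chosen
#' negative one, with ties counting one half.
#'
#' @param y binary 0/1 labels.
#' @param scores predicted class-1 probabilities (or any scores).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(y, scores) {
  y <- as.integer(y)
  ok <- !is.na(scores)
  y <- y[ok]; scores <- scores[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUROC")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Patient-level bootstrapped cross-validation
#'
#' The ensemble leave-group-out scheme: for each of `B` iterations, a
#' random half of the patients (and all their samples) trains the
#' classifier, the held-out samples receive predicted class-1
#' probabilities, and after all iterations each sample's final
#' prediction `y*` is the median probability over the iterations in
#' which it was held out. AUROC is computed from `(y, y*)`. Iterations
#' whose training half lacks a class are skipped (not resampled), so
#' `B` is an upper bound; the effective count is reported.
#'
#' @param features numeric `S x d` matrix, row-aligned with `labels`
#'   and `patient_ids`; no missing values.
#' @param labels binary 0/1 sample labels.
#' @param patient_ids per-sample patient ids.
#' @param B bootstrap iterations (default 500).
#' @param train_fraction patient fraction trained on (default 0.5).
#' @param classifier pluggable contract, see [rf_classifier()].
#' @param seed master seed; each iteration derives its own child seed.
#' @param stratified if `TRUE`, patient splits are class-stratified
#'   (logged). Off by default; useful for imbalanced cohorts and for
#'   null controls, where simple random halves carry a pessimistic
#'   AUROC bias (training class composition anti-correlates with the
#'   held-out composition).
#' @return A `cv_result`: list with `y_star`, `auroc`, `n_test_appearances`,
#'   `per_iteration` (data.frame `iteration`, `sample_id`, `prob`),
#'   `B`, `B_effective`, `excluded_samples`.
#' @export
run_cv <- function(features, labels, patient_ids, B = 500,
                   train_fraction = 0.5, classifier = rf_classifier(),
                   seed = 1L, stratified = FALSE) {
  features <- as.matrix(features)
  S <- nrow(features)
  stopifnot(length(labels) == S, length(patient_ids) == S)
  if (anyNA(features)) stop("features contain missing values")
  if (B < 1) stop("B must be >= 1")
  labels <- as.integer(labels)
  patient_ids <- as.character(patient_ids)
  patients <- unique(patient_ids)
  class_of <- NULL
  if (stratified) {
    per_patient <- unique(data.frame(p = patient_ids, y = labels))
    class_of <- stats::setNames(per_patient$y, per_patient$p)
    message("run_cv: using class-stratified patient splits")
  }
  sample_ids <- rownames(features)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(S))
  probs <- vector("list", B)
  skipped <- 0L
  for (b in seq_len(B)) {
    sb <- child_seed(seed, 3L, b)
    sp <- split_patients(patients, train_fraction, seed = sb,
                         class_of = class_of)
    tr <- patient_ids %in% sp$train
    if (length(unique(labels[tr])) < 2) {
      skipped <- skipped + 1L
      warning("iteration ", b, " skipped: training half lacks a class",
              call. = FALSE)
      next
    }
    set.seed(sb)
    model <- classifier$fit(features[tr, , drop = FALSE], labels[tr])
    p <- classifier$predict_prob(model, features[!tr, , drop = FALSE])
    probs[[b]] <- data.frame(iteration = b, sample_id = sample_ids[!tr],
                             prob = p, stringsAsFactors = FALSE)
  }
  per_iteration <- do.call(rbind, probs)
  if (is.null(per_iteration) || nrow(per_iteration) == 0) {
    stop("no usable CV iterations (every training half lacked a class)")
  }
  appearances <- table(factor(per_iteration$sample_id, levels = sample_ids))
  y_star <- vapply(sample_ids, function(s) {
    p <- per_iteration$prob[per_iteration$sample_id == s]
    if (length(p) == 0) NA_real_ else stats::median(p)
  }, numeric(1))
  never_tested <- sample_ids[appearances == 0]
  if (length(never_tested)) {
    warning("sample(s) never held out in any iteration, excluded from AUROC: ",
            paste(never_tested, collapse = ", "), call. = FALSE)
  }
  ok <- !is.na(y_star)
  structure(list(y_star = y_star,
                 auroc = auroc(labels[ok], y_star[ok]),
                 n_test_appearances = as.integer(appearances),
                 per_iteration = per_iteration,
                 B = B, B_effective = B - skipped,
                 excluded_samples = never_tested,
                 labels = labels, sample_ids = sample_ids),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: AUROC = %.4f over %d samples (B = %d, effective %d)\n",
              x$auroc, length(x$y_star), x$B, x$B_effective))
  invisible(x)
}

#' Ensemble vs single-solution classification comparison
#'
#' Contrasts the pooled multi-solution feature set against individual
#' metaclustering solutions: in each of `n_trials` paired trials, the
#' baseline arm runs CV on one uniformly drawn iteration's (selected)
#' feature block, the ensemble arm on all retained blocks. Both arms
#' re-randomize only their CV splits between trials; the metaclustering
#' is fixed. The stochastic clustering solutions disagree, and pooling
#' them is what buys the accuracy and stability gain this comparison
#' measures.
#'
#' @param F a `freq_matrix`.
#' @param selection optional `selection_result` applied to both arms.
#' @param labels,patient_ids per-sample metadata, row-aligned with `F`.
#' @param n_trials number of paired trials (>= 1).
#' @param B,train_fraction,classifier CV settings per trial.
#' @param seed master seed.
#' @return list with `single_auc`, `ensemble_auc` (length `n_trials`),
#'   `single_iteration` (which solution each baseline trial drew),
#'   `mean_single`, `mean_ensemble`, `var_single`, `var_ensemble`.
#' @export
compare_ensemble_vs_single <- function(F, selection = NULL, labels, patient_ids,
                                       n_trials = 20, B = 100,
                                       train_fraction = 0.5,
                                       classifier = rf_classifier(), seed = 1L) {
  stopifnot(inherits(F, "freq_matrix"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  iters <- unique(F$column_meta$iteration)
  if (length(iters) < 2) {
    warning("only one metaclustering solution available; the two arms coincide",
            call. = FALSE)
  }
  ens_features <- selected_matrix(F, selection)
  single_auc <- numeric(n_trials)
  ensemble_auc <- numeric(n_trials)
  single_iteration <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    st <- child_seed(seed, 4L, t)
    set.seed(st)
    it <- sample(iters, 1)
    single_iteration[t] <- it
    x_single <- selected_matrix(F, selection, iterations = it)
    # paired design: both arms see identical CV splits within a trial
    cv_seed <- child_seed(st, 5L, 1L)
    single_auc[t] <- run_cv(x_single, labels, patient_ids, B = B,
                            train_fraction = train_fraction,
                            classifier = classifier, seed = cv_seed)$auroc
    ensemble_auc[t] <- run_cv(ens_features, labels, patient_ids, B = B,
                              train_fraction = train_fraction,
                              classifier = classifier, seed = cv_seed)$auroc
  }
  list(single_auc = single_auc, ensemble_auc = ensemble_auc,
       single_iteration = single_iteration,
       mean_single = mean(single_auc), mean_ensemble = mean(ensemble_auc),
       var_single = stats::var(single_auc), var_ensemble = stats::var(ensemble_auc))
}

#' Write a CV result to CSV + JSON summary
#'
#' @param cv a `cv_result`.
#' @param csv_path per-sample CSV (`sample_id`, `true_label`, `y_star`,
#'   `n_test_appearances`).
#' @param json_path optional JSON summary `{auroc, B, B_effective}`.
#' @return `csv_path`, invisibly.
#' @export
write_cv_csv <- function(cv, csv_path, json_path = NULL) {
  df <- data.frame(sample_id = cv$sample_ids, true_label = cv$labels,
                   y_star = unname(cv$y_star),
                   n_test_appearances = cv$n_test_appearances)
  data.table::fwrite(df, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(auroc = cv$auroc, B = cv$B,
                              B_effective = cv$B_effective),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
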