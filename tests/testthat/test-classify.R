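test_that("patient splits use the floor rule and keep patients intact", {
  p10 <- split_patients(paste0("p", 1:10), seed = 1)
  expect_length(p10$train, 5)
  expect_length(p10$test, 5)
  p7 <- split_patients(paste0("p", 1:7), seed = 1)
  expect_length(p7$train, 3)
  expect_length(p7$test, 4)
  expect_length(intersect(p7$train, p7$test), 0)
  expect_setequal(c(p7$train, p7$test), paste0("p", 1:7))
  expect_error(split_patients("p1"), "at least 2")
  expect_error(split_patients(paste0("p", 1:4), train_fraction = 1.2),
               "train_fraction")
})

test_that("all samples of a patient land on the same side of every split", {
  patient_ids <- rep(paste0("p", 1:6), each = 6)  # 6 samples per patient
  for (b in 1:25) {
    sp <- split_patients(unique(patient_ids), seed = b)
    side <- ifelse(patient_ids %in% sp$train, "train", "test")
    per_patient <- tapply(side, patient_ids, function(s) length(unique(s)))
    expect_true(all(per_patient == 1))
  }
})

test_that("auroc reproduces hand-checked values and symmetries", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)   # all ties
  y <- c(0, 0, 1, 1, 1)
  s <- c(0.2, 0.7, 0.4, 0.6, 0.9)
  expect_equal(auroc(y, s) + auroc(y, -s), 1)            # sign reversal
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("auroc agrees with an independent library implementation", {
  set.seed(11)
  for (trial in 1:5) {
    n <- 60
    y <- sample(rep(c(0, 1), n / 2))
    s <- round(stats::runif(n), 2)
    expect_equal(auroc(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("auroc matches the O(n^2) pairwise oracle to 1e-12", {
  set.seed(7)
  for (trial in 1:10) {
    n <- sample(10:200, 1)
    y <- sample(c(0, 1), n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(stats::runif(n), sample(c(1, 3, 6), 1))  # induce some ties
    expect_equal(auroc(y, s), brute_auroc(y, s), tolerance = 1e-12)
  }
})

# linearly separable toy features: two distant blobs by class
separable_features <- function(n_patients = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n_patients)
  x <- matrix(stats::rnorm(2 * n_patients * 3, mean = rep(y * 10, 3)),
              ncol = 3)
  rownames(x) <- sprintf("s%02d", seq_along(y))
  list(x = x, y = y, patients = sprintf("p%02d", seq_along(y)))
}

test_that("run_cv scores a separable cohort perfectly and is reproducible", {
  f <- separable_features()
  cv <- run_cv(f$x, f$y, f$patients, B = 20, seed = 3)
  expect_equal(cv$auroc, 1.0)
  expect_true(all(cv$y_star >= 0 & cv$y_star <= 1, na.rm = TRUE))
  cv2 <- run_cv(f$x, f$y, f$patients, B = 20, seed = 3)
  expect_identical(cv$y_star, cv2$y_star)
  expect_identical(cv$auroc, cv2$auroc)
})

test_that("B = 1 returns the raw probabilities of the single iteration", {
  f <- separable_features(n_patients = 5)
  cv <- suppressWarnings(run_cv(f$x, f$y, f$patients, B = 1, seed = 9))
  tested <- !is.na(cv$y_star)
  expect_equal(sum(tested), nrow(cv$per_iteration))
  expect_equal(unname(cv$y_star[tested][order(names(cv$y_star)[tested])]),
               cv$per_iteration$prob[order(cv$per_iteration$sample_id)])
})

test_that("permuted labels give near-chance AUROC on average", {
  # a single random labeling of 40 samples can be genuinely (anti-)
  # predictable by chance, so the null check averages over permutations
  set.seed(21)
  n_patients <- 20
  x <- matrix(stats::rnorm(2 * n_patients * 5), ncol = 5)
  rownames(x) <- sprintf("s%02d", seq_len(2 * n_patients))
  aucs <- vapply(1:5, function(r) {
    set.seed(200 + r)
    y <- sample(rep(c(0, 1), n_patients))
    run_cv(x, y, sprintf("p%02d", seq_len(2 * n_patients)), B = 50,
           seed = r)$auroc
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("no CV iteration ever shares a patient across train and test", {
  synth <- tiny_cohort(n_patients_per_class = 3, cells_per_sample = 100)
  man <- synth$cohort$manifest
  x <- matrix(stats::rnorm(nrow(man) * 4), ncol = 4,
              dimnames = list(man$sample_id, NULL))
  # track the splits through a spying classifier
  seen <- list()
  spy <- list(
    fit = function(x, y) rownames(x),
    predict_prob = function(model, x) {
      seen[[length(seen) + 1]] <<- list(train = model, test = rownames(x))
      rep(0.5, nrow(x))
    })
  cv <- suppressWarnings(
    run_cv(x, man$class, man$patient_id, B = 30, classifier = spy, seed = 2))
  patient_of <- stats::setNames(man$patient_id, man$sample_id)
  for (s in seen) {
    expect_length(intersect(patient_of[s$train], patient_of[s$test]), 0)
  }
  # one predict call per non-skipped iteration
  expect_length(seen, cv$B_effective)
  expect_gte(cv$B_effective, 1)
})

test_that("ensemble and single arms coincide for a one-solution ensemble", {
  synth <- tiny_cohort(n_patients_per_class = 3, cells_per_sample = 150)
  ens <- tiny_ensemble(synth, k_per_sample = 12, k_prime = 4, n_iterations = 1)
  F <- frequency_features(synth$cohort, ens)
  cmp <- suppressWarnings(compare_ensemble_vs_single(
    F, NULL, synth$cohort$manifest$class, synth$cohort$manifest$patient_id,
    n_trials = 3, B = 5, seed = 1))
  expect_identical(cmp$single_auc, cmp$ensemble_auc)
  expect_error(compare_ensemble_vs_single(
    F, NULL, synth$cohort$manifest$class, synth$cohort$manifest$patient_id,
    n_trials = 0), "n_trials")
})

test_that("cv artifacts round trip to CSV/JSON", {
  f <- separable_features(n_patients = 5)
  cv <- run_cv(f$x, f$y, f$patients, B = 5, seed = 2)
  csvp <- tempfile(fileext = ".csv")
  jsonp <- tempfile(fileext = ".json")
  write_cv_csv(cv, csvp, jsonp)
  df <- read.csv(csvp)
  expect_equal(nrow(df), length(f$y))
  expect_identical(names(df), c("sample_id", "true_label", "y_star",
                                "n_test_appearances"))
  js <- jsonlite::read_json(jsonp)
  expect_equal(js$auroc, cv$auroc)
})
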