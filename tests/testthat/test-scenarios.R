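test_that("two-fold split halves the lines with the odd line in training", {
  ids357 <- sprintf("L%03d", 1:357)
  folds <- two_fold_split(ids357, seed = 1)
  for (f in folds) {
    expect_length(f$train_ids, 179L)
    expect_length(f$test_ids, 178L)
    expect_length(intersect(f$train_ids, f$test_ids), 0L)
    expect_setequal(c(f$train_ids, f$test_ids), ids357)
  }
  ## each non-odd line is tested exactly once
  expect_length(intersect(folds[[1]]$test_ids, folds[[2]]$test_ids), 0L)
  ids100 <- sprintf("L%03d", 1:100)
  f100 <- two_fold_split(ids100, seed = 2)
  expect_length(f100[[1]]$train_ids, 50L)
  expect_length(f100[[1]]$test_ids, 50L)
})

test_that("two-fold split is deterministic in the seed", {
  ids <- sprintf("L%02d", 1:41)
  expect_identical(two_fold_split(ids, 7), two_fold_split(ids, 7))
  expect_false(identical(two_fold_split(ids, 7)[[1]]$test_ids,
                         two_fold_split(ids, 8)[[1]]$test_ids))
})

test_that("prediction accuracy averages within-experiment correlations", {
  n <- 8
  mk <- function(vals, exp_id) data.frame(
    line_id = paste0("L", 1:n), experiment_id = exp_id,
    plant_id = paste0("p", 1:n, exp_id), day = 1, value = vals)
  pred <- stats::setNames(as.numeric(1:n), paste0("L", 1:n))
  ## perfect and perfectly inverted observations
  rec_perfect <- as_phenotype_records(mk(1:n + 10, "E1"))
  expect_equal(prediction_accuracy(pred, rec_perfect, 1, paste0("L", 1:n)), 1)
  rec_neg <- as_phenotype_records(mk(rev(1:n) + 10, "E1"))
  expect_equal(prediction_accuracy(pred, rec_neg, 1, paste0("L", 1:n)), -1)
  ## two experiments engineered to correlations 0.4 and 0.8 with pred
  make_corr <- function(rho, seed) {
    set.seed(seed)
    repeat {
      z <- stats::rnorm(n)
      x <- as.numeric(1:n)
      zr <- stats::resid(stats::lm(z ~ x))
      y <- rho * scale(x) + sqrt(1 - rho^2) * scale(zr)
      if (abs(stats::cor(x, y) - rho) < 1e-10) return(drop(y) + 10)
    }
  }
  rec2 <- as_phenotype_records(rbind(mk(make_corr(0.4, 1), "E1"),
                                     mk(make_corr(0.8, 2), "E2")))
  expect_equal(prediction_accuracy(pred, rec2, 1, paste0("L", 1:n)), 0.6,
               tolerance = 1e-9)
})

test_that("replicated plants are averaged before correlating", {
  pred <- stats::setNames(c(1, 2, 3, 4), paste0("L", 1:4))
  df <- data.frame(
    line_id = c("L1", "L1", "L2", "L3", "L4"),
    experiment_id = "E1",
    plant_id = c("p1a", "p1b", "p2", "p3", "p4"),
    day = 1, value = c(5, 7, 10, 14, 18))  # L1 mean 6 -> perfectly linear
  rec <- as_phenotype_records(df)
  expect_equal(prediction_accuracy(pred, rec, 1, paste0("L", 1:4)), 1,
               tolerance = 1e-12)
})

scenario_truth <- function() {
  fixture("scenario_truth", function() {
    cfg <- sim_config(n_lines = 90, n_markers = 300, n_rep_lines = 15,
                      seed = 31)
    suppressMessages(simulate_trajectories(cfg))
  })
}

test_that("scenario runs are reproducible and leak no test phenotypes", {
  truth <- scenario_truth()
  rec <- truth$records
  a1 <- run_scenario("A", rec, truth$grm, n_resamples = 1, base_seed = 3)
  a2 <- run_scenario("A", rec, truth$grm, n_resamples = 1, base_seed = 3)
  expect_identical(a1$accuracies, a2$accuracies)
  ## sentinel: corrupting test-line phenotypes must not change the fitted
  ## model or the predictions, only the evaluation
  folds <- two_fold_split(sort(unique(rec$line_id)), 3)
  te <- folds[[1]]$test_ids
  rec_corrupt <- rec
  rec_corrupt$value[rec_corrupt$line_id %in% te] <-
    rec_corrupt$value[rec_corrupt$line_id %in% te] * 1000
  rec_corrupt <- as_phenotype_records(rec_corrupt)
  train <- as_phenotype_records(
    rec[rec$line_id %in% folds[[1]]$train_ids, , drop = FALSE])
  train_c <- as_phenotype_records(
    rec_corrupt[rec_corrupt$line_id %in% folds[[1]]$train_ids, , drop = FALSE])
  p1 <- rrgrowth:::rr_predict_lines(train, truth$grm, rr_model_spec(),
                                    c(1, 20), 1:20)
  p2 <- rrgrowth:::rr_predict_lines(train_c, truth$grm, rr_model_spec(),
                                    c(1, 20), 1:20)
  expect_identical(p1$pred, p2$pred)
})

test_that("forecasting outside the declared domain is refused by name", {
  truth <- scenario_truth()
  train <- as_phenotype_records(
    truth$records[truth$records$day <= 10, , drop = FALSE])
  expect_error(
    rrgrowth:::rr_predict_lines(train, truth$grm, rr_model_spec(),
                                c(1, 10), 11:12),
    "outside the basis domain: 11, 12")
})

test_that("TP forecasting of unobserved days is refused", {
  truth <- scenario_truth()
  expect_error(run_scenario("B", truth$records, truth$grm, model = "TP"),
               "scenario A only")
})

test_that("forecasting known lines beats forecasting new lines (B > C)", {
  truth <- scenario_truth()
  b <- run_scenario("B", truth$records, truth$grm, n_resamples = 2,
                    base_seed = 11)
  cc <- run_scenario("C", truth$records, truth$grm, n_resamples = 2,
                     base_seed = 11)
  expect_gt(mean(b$mean_accuracy), mean(cc$mean_accuracy))
  ## forecast accuracy declines, on average, away from the training window
  first_half <- mean(b$mean_accuracy[1:5])
  second_half <- mean(b$mean_accuracy[6:10])
  expect_gte(first_half, second_half - 0.02)
})

test_that("cross-study forecasting (scenario D) evaluates on the second study's days", {
  cfg <- sim_config(n_lines = 60, n_markers = 200, seed = 55)
  two <- suppressMessages(simulate_two_studies(cfg, days2 = 15:24))
  d <- run_scenario("D", two$study1$records, two$study1$grm,
                    records2 = two$records2, n_resamples = 1, base_seed = 2)
  expect_equal(d$eval_days, as.numeric(15:24))
  expect_true(all(is.finite(d$mean_accuracy)))
  expect_gt(mean(d$mean_accuracy), 0.2)
})
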