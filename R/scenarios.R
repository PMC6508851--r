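#' Two-fold cross-validation split of lines
#'
#' Randomly halves the lines; with an odd count the leftover line joins the
#' training set of both folds (so a training set is never the smaller half).
#' Deterministic given `seed`.
#'
#' @param line_ids Character vector of line IDs (>= 4).
#' @param seed Integer seed.
#' @return List of two folds, each a list with `train_ids`, `test_ids`,
#'   `seed`.
#' @export
two_fold_split <- function(line_ids, seed) {
  stopifnot(length(line_ids) >= 4L)
  set.seed(seed)
  ids <- sample(line_ids)
  odd <- if (length(ids) %% 2L == 1L) ids[1L] else character(0)
  rest <- ids[(length(odd) + 1L):length(ids)]
  half <- length(rest) / 2L
  h1 <- rest[seq_len(half)]
  h2 <- rest[half + seq_len(half)]
  list(list(train_ids = sort(c(h1, odd)), test_ids = sort(h2), seed = seed),
       list(train_ids = sort(c(h2, odd)), test_ids = sort(h1), seed = seed))
}

#' Prediction accuracy at one day
#'
#' Pearson correlation between predicted gBLUPs and observed phenotypes for
#' the test lines, computed within each experiment (replicate plants of a
#' line within an experiment are averaged first) and then averaged over
#' experiments. Experiments with fewer than 3 observed test lines or zero
#' variance are skipped with a warning.
#'
#' @param gblups Named numeric vector of per-line predictions (names = line
#'   IDs).
#' @param records A `phenotype_records`.
#' @param day The evaluation day.
#' @param test_ids Line IDs of the test set.
#' @return Mean over experiments of the within-experiment correlations
#'   (`NA` if no experiment was usable).
#' @export
prediction_accuracy <- function(gblups, records, day, test_ids) {
  sub <- records[records$day == day & records$line_id %in% test_ids, ,
                 drop = FALSE]
  if (nrow(sub) == 0L) return(NA_real_)
  cors <- c()
  for (ex in unique(sub$experiment_id)) {
    se <- sub[sub$experiment_id == ex, , drop = FALSE]
    obs <- tapply(se$value, se$line_id, mean)
    pred <- gblups[names(obs)]
    ok <- !is.na(pred) & !is.na(obs)
    if (sum(ok) < 3L) {
      warning("experiment ", ex, " day ", day,
              ": fewer than 3 test lines; skipped")
      next
    }
    if (stats::sd(obs[ok]) == 0 || stats::sd(pred[ok]) == 0) {
      warning("experiment ", ex, " day ", day, ": zero variance; skipped")
      next
    }
    cors <- c(cors, stats::cor(pred[ok], obs[ok]))
  }
  if (length(cors) == 0L) NA_real_ else mean(cors)
}

## Fit an RR model on training records and return per-line predictions at
## the evaluation days (basis evaluated inside the declared domain).
rr_predict_lines <- function(train_records, grm, spec, domain, eval_days,
                             control = reml_control()) {
  out_of_domain <- eval_days[eval_days < domain[1] | eval_days > domain[2]]
  if (length(out_of_domain)) {
    stop("evaluation day(s) outside the basis domain: ",
         paste(out_of_domain, collapse = ", "),
         "; extend the domain to cover them")
  }
  fit_days <- sort(unique(train_records$day))
  grid_fit <- standardize_time(fit_days, domain)
  fit <- fit_rr_reml(train_records, grm, spec, grid_fit, control = control)
  basis_eval <- legendre_matrix(standardize_time(eval_days, domain),
                                spec$genetic_order)
  basis_eval$grid <- standardize_time(eval_days, domain)
  list(fit = fit,
       pred = predict_gblup_trajectory(fit$u_hat, basis_eval))
}

#' Run a genomic-prediction cross-validation scenario
#'
#' The four scenarios:
#' \describe{
#'   \item{A}{All days for the training lines predict all days for the test
#'     lines (two folds; the conventional whole-trajectory genomic
#'     prediction). `model = "TP"` instead fits an independent per-day
#'     gBLUP model on the training lines.}
#'   \item{B}{A random half of the lines, fitted on the early-day window
#'     (`day <= split_day`), predicts the *same* lines at the later days
#'     (single sampled half per resample; pure forecasting).}
#'   \item{C}{Training lines fitted on the early window predict the *test*
#'     lines at the later days (two folds; forecasting new lines).}
#'   \item{D}{Training lines fitted on the full first-study window predict
#'     the test lines at a second study's days (`records2`/`eval_days2`),
#'     with the basis standardized over a domain spanning both studies.}
#' }
#' Per resample and evaluation day, the accuracy is the fold average (A, C,
#' D) or the sampled half's value (B) of [prediction_accuracy()]. Resample
#' `i` uses seed `base_seed + i - 1`.
#'
#' @param scenario `"A"`, `"B"`, `"C"` or `"D"`.
#' @param records A `phenotype_records` (first study).
#' @param grm A `genomic_relationship`.
#' @param spec An [rr_model_spec()].
#' @param model `"RR"` or (scenario A only) `"TP"`.
#' @param n_resamples Number of random resampling rounds (default 20).
#' @param base_seed Integer seed of the first resample.
#' @param split_day Last training day for scenarios B/C (default the median
#'   day, i.e. first half trains).
#' @param records2,eval_days2 Second-study phenotypes and evaluation days
#'   (scenario D).
#' @param control REML solver settings.
#' @return A `scenario_result`: list with `scenario`, `model`, `accuracies`
#'   (n_resamples x days matrix), `mean_accuracy`, `sd_accuracy`, `seeds`,
#'   `eval_days`.
#' @export
run_scenario <- function(scenario = c("A", "B", "C", "D"), records, grm,
                         spec = rr_model_spec(), model = c("RR", "TP"),
                         n_resamples = 20L, base_seed = 1L,
                         split_day = NULL, records2 = NULL,
                         eval_days2 = NULL, control = reml_control()) {
  scenario <- match.arg(scenario)
  model <- match.arg(model)
  if (model == "TP" && scenario != "A") {
    stop("the per-day TP model cannot forecast unobserved days; ",
         "TP is available for scenario A only")
  }
  days <- day_set(records)
  if (scenario %in% c("B", "C")) {
    if (is.null(split_day)) split_day <- stats::median(days)
    train_days <- days[days <= split_day]
    eval_days <- days[days > split_day]
    if (length(train_days) == 0L || length(eval_days) == 0L) {
      stop("split_day must leave days on both sides")
    }
  } else if (scenario == "D") {
    if (is.null(records2)) stop("scenario D needs records2")
    if (is.null(eval_days2)) eval_days2 <- day_set(records2)
    eval_days <- eval_days2
  } else {
    eval_days <- days
  }
  domain <- if (scenario == "D") range(c(days, eval_days)) else range(days)

  line_ids <- sort(unique(records$line_id))
  seeds <- base_seed + seq_len(n_resamples) - 1L
  acc <- matrix(NA_real_, n_resamples, length(eval_days),
                dimnames = list(NULL, as.character(eval_days)))

  for (i in seq_len(n_resamples)) {
    if (scenario == "B") {
      set.seed(seeds[i])
      half <- sort(sample(line_ids, floor(length(line_ids) / 2)))
      train <- as_phenotype_records(
        records[records$line_id %in% half & records$day <= split_day, ,
                drop = FALSE])
      rp <- rr_predict_lines(train, grm, spec, domain, eval_days, control)
      acc[i, ] <- vapply(seq_along(eval_days), function(k) {
        prediction_accuracy(rp$pred[, k], records, eval_days[k], half)
      }, numeric(1))
      next
    }
    folds <- two_fold_split(line_ids, seeds[i])
    fold_acc <- matrix(NA_real_, 2L, length(eval_days))
    for (f in 1:2) {
      tr_ids <- folds[[f]]$train_ids
      te_ids <- folds[[f]]$test_ids
      if (scenario == "A" && model == "TP") {
        train <- as_phenotype_records(
          records[records$line_id %in% tr_ids, , drop = FALSE])
        for (k in seq_along(eval_days)) {
          tp <- fit_tp_gblup(train, grm, eval_days[k], control)
          fold_acc[f, k] <- prediction_accuracy(tp$gblup, records,
                                                eval_days[k], te_ids)
        }
      } else {
        train <- switch(scenario,
          A = records[records$line_id %in% tr_ids, , drop = FALSE],
          C = records[records$line_id %in% tr_ids &
                        records$day <= split_day, , drop = FALSE],
          D = records[records$line_id %in% tr_ids, , drop = FALSE])
        train <- as_phenotype_records(train)
        eval_records <- if (scenario == "D") records2 else records
        rp <- rr_predict_lines(train, grm, spec, domain, eval_days, control)
        fold_acc[f, ] <- vapply(seq_along(eval_days), function(k) {
          prediction_accuracy(rp$pred[, k], eval_records, eval_days[k],
                              te_ids)
        }, numeric(1))
      }
    }
    acc[i, ] <- colMeans(fold_acc)
  }
  structure(list(scenario = scenario, model = model, accuracies = acc,
                 n_resamples = n_resamples, seeds = seeds,
                 eval_days = eval_days,
                 mean_accuracy = colMeans(acc, na.rm = TRUE),
                 sd_accuracy = apply(acc, 2L, stats::sd, na.rm = TRUE)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario_result", x$scenario, "(", x$model, "):",
      x$n_resamples, "resamples,", length(x$eval_days), "days\n")
  cat("  mean accuracy:", round(mean(x$mean_accuracy, na.rm = TRUE), 3),
      " range:", round(range(x$mean_accuracy, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Summarize a scenario result as a per-day table
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return Data frame with `day`, `mean`, `sd` over resamples.
#' @export
summary.scenario_result <- function(object, ...) {
  data.frame(day = object$eval_days, mean = object$mean_accuracy,
             sd = object$sd_accuracy)
}
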