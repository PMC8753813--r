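#' Run the nine orthogonal-array screening experiments
#'
#' Trains `n_runs` independent models for each of the nine
#' hyperparameter combinations of the design, records the accuracy of
#' every run on both the training and the preliminary-test split, and
#' summarises each experiment x split group with [summarize_runs()].
#'
#' One master seed is expanded deterministically into one seed per
#' (experiment, run) cell, so two invocations with the same arguments
#' produce identical records.
#'
#' @param backend A classifier backend (see [train_model()]).
#' @param oa The orthogonal array, default [l9_oa()].
#' @param space The [factor_space()] of hyperparameter levels.
#' @param data A `"labeled_image_set"` with `train` and
#'   `preliminary_test` splits.
#' @param n_runs Independent runs per experiment, default 3.
#' @param seed Master seed.
#' @param m Accuracy target for the SNR, default 1.
#' @return An object of class `"oa_experiments"`: list with `runs` (long
#'   `data.frame`: `experiment_id, dataset, run, accuracy`), `records`
#'   (summary `data.frame` as from [summarize_run_table()]),
#'   `combinations`, `oa`, `space`, and `seed`.
#' @export
run_oa_experiments <- function(backend, oa = l9_oa(), space, data,
                               n_runs = 3L, seed = 1L, m = 1) {
  combos <- map_combinations(oa, space)
  n_exp <- nrow(combos)
  seeds <- matrix(derive_seeds(seed, n_exp * n_runs), n_exp, n_runs)
  rows <- vector("list", n_exp * n_runs)
  k <- 1L
  for (i in seq_len(n_exp)) {
    cmb <- combination(combos, combos$experiment_id[i])
    for (r in seq_len(n_runs)) {
      mod <- train_model(backend, cmb, data, seeds[i, r], run = r)
      rows[[k]] <- data.frame(
        experiment_id = combos$experiment_id[i],
        dataset = c("training", "preliminary_test"),
        run = r,
        accuracy = c(mod$accuracy_train, mod$accuracy_test),
        stringsAsFactors = FALSE
      )
      k <- k + 1L
    }
  }
  runs <- do.call(rbind, rows)
  runs <- runs[order(runs$experiment_id, runs$dataset, runs$run), ,
               drop = FALSE]
  rownames(runs) <- NULL
  structure(
    list(runs = runs, records = summarize_run_table(runs, m = m),
         combinations = combos, oa = oa, space = space,
         seed = as.integer(seed)),
    class = "oa_experiments"
  )
}

#' @export
print.oa_experiments <- function(x, digits = 4, ...) {
  cat("Orthogonal-array screening:", nrow(x$combinations),
      "experiments x", max(x$runs$run), "runs (seed", x$seed, ")\n")
  y <- x$records
  y[c("mean", "sd", "eta")] <- lapply(y[c("mean", "sd", "eta")],
                                      round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Confirmation runs at the selected best combination
#'
#' Trains `n_models` independent models with the winning hyperparameter
#' combination under distinct derived seeds, evaluates each on the
#' preliminary-test split, and assembles their per-image predictions
#' into the model x image vote matrix consumed by [majority_vote()] and
#' [ensemble_evaluate()].  Models are named by their preliminary-test
#' accuracy scaled by 10^4 (e.g. `model-8249(#1)`).
#'
#' @param backend A classifier backend.
#' @param combo The best hyperparameter combination (named list).
#' @param data A `"labeled_image_set"` with both splits.
#' @param n_models Number of independent confirmation models, default 9.
#' @param seed Master seed.
#' @return An object of class `"confirmation_runs"`: list with `models`
#'   (list of trained handles), `votes` (character matrix, rows =
#'   models, columns = preliminary-test images), `accuracies`
#'   (`data.frame` with train/test accuracy per model), `actual` (true
#'   labels of the test split), `record` (list with the `mean`, `sd`,
#'   and smaller-the-better SNR `eta` of the test accuracies; `eta` is
#'   `NA` with a warning when the mean accuracy is exactly 1), and
#'   `seed`.
#' @export
confirmation_runs <- function(backend, combo, data, n_models = 9L,
                              seed = 1L) {
  if (n_models < 1L) stop("'n_models' must be >= 1", call. = FALSE)
  test <- subset_split(data, "preliminary_test")
  if (length(test$images) == 0L) {
    stop("'data' has no preliminary_test split", call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_models)
  models <- vector("list", n_models)
  votes <- matrix(NA_character_, n_models, length(test$images),
                  dimnames = list(NULL, test$image_ids))
  acc <- data.frame(model = character(n_models),
                    accuracy_train = numeric(n_models),
                    accuracy_test = numeric(n_models),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_models)) {
    mod <- train_model(backend, combo, data, seeds[i], run = i)
    votes[i, ] <- predict(mod, test)
    acc_test <- mean(votes[i, ] == test$labels)
    mod$accuracy_test <- acc_test
    acc$model[i] <- sprintf("model-%04d(#%d)", round(1e4 * acc_test), i)
    acc$accuracy_train[i] <- mod$accuracy_train
    acc$accuracy_test[i] <- acc_test
    models[[i]] <- mod
  }
  rownames(votes) <- acc$model
  mean_acc <- mean(acc$accuracy_test)
  # a perfect confirmation score leaves the smaller-the-better SNR
  # undefined; report it as NA rather than failing the whole run
  eta <- if (mean_acc == 1) {
    warning("mean confirmation accuracy equals the target; ",
            "SNR reported as NA", call. = FALSE)
    NA_real_
  } else {
    snr_stb(acc$accuracy_test)
  }
  record <- list(mean = mean_acc,
                 sd = if (n_models > 1L) stats::sd(acc$accuracy_test)
                      else 0,
                 eta = eta)
  structure(
    list(models = models, votes = votes, accuracies = acc,
         actual = test$labels, record = record,
         seed = as.integer(seed)),
    class = "confirmation_runs"
  )
}

#' @export
print.confirmation_runs <- function(x, digits = 4, ...) {
  cat("Confirmation runs:", nrow(x$accuracies), "models (seed",
      x$seed, ")\n")
  y <- x$accuracies
  y[-1L] <- lapply(y[-1L], round, digits)
  print(y, row.names = FALSE)
  cat(sprintf("Test accuracy: mean %.4f, SD %.4f, eta %.4f dB\n",
              x$record$mean, x$record$sd, x$record$eta))
  invisible(x)
}
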