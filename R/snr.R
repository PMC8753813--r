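#' Smaller-the-better signal-to-noise ratio
#'
#' Computes the Taguchi smaller-the-better SNR in decibels,
#' \eqn{\eta = -10 \log_{10}((\bar y - m)^2)}, where \eqn{\bar y} is the
#' mean of the observed run accuracies and `m` is the accuracy target.
#' With `m = 1` (a 100\% accuracy target) the quantity being driven to
#' zero is the mean error rate, so a larger \eqn{\eta} means accuracy
#' closer to 1.
#'
#' @param y Numeric vector of run accuracies (fractions in `[0, 1]`).
#' @param m Target value, default 1.
#' @return The SNR in dB (a single number).
#' @examples
#' snr_stb(c(0.9, 0.9, 0.9))  # -10 * log10(0.01) = 20 dB
#' @export
snr_stb <- function(y, m = 1) {
  if (length(y) < 1L || !is.numeric(y)) {
    stop("'y' must be a non-empty numeric vector", call. = FALSE)
  }
  ybar <- mean(y)
  if (ybar == m) {
    stop("mean accuracy equals the target m = ", m,
         ": the smaller-the-better SNR is undefined (log of zero)",
         call. = FALSE)
  }
  -10 * log10((ybar - m)^2)
}

#' Summarise repeated runs of one screening experiment
#'
#' Collapses the independent training runs of one orthogonal-array
#' experiment (on one dataset split) into the three recorded statistics:
#' mean accuracy, sample standard deviation (n - 1 denominator; 0 when
#' n = 1), and the smaller-the-better SNR \eqn{\eta}.
#'
#' @param experiment_id Integer experiment number (1..9 for an L9 design).
#' @param dataset Label of the dataset split the accuracies were measured
#'   on, e.g. `"training"` or `"preliminary_test"`.
#' @param accuracies Numeric vector of per-run accuracies in `[0, 1]`.
#' @param m Accuracy target for the SNR, default 1.
#' @return An object of class `"experiment_record"`: a list with elements
#'   `experiment_id`, `dataset`, `accuracies`, `n`, `mean`, `sd`, `eta`,
#'   and `m`.
#' @examples
#' summarize_runs(1, "training", c(0.9777, 0.9796, 0.9792))
#' @export
summarize_runs <- function(experiment_id, dataset, accuracies, m = 1) {
  if (length(accuracies) < 1L || !is.numeric(accuracies)) {
    stop("'accuracies' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(accuracies < 0 | accuracies > 1)) {
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  }
  ybar <- mean(accuracies)
  if (ybar == m) {
    stop("experiment ", experiment_id, " (", dataset,
         "): mean accuracy equals the target m = ", m,
         ", SNR undefined", call. = FALSE)
  }
  structure(
    list(
      experiment_id = as.integer(experiment_id),
      dataset = as.character(dataset),
      accuracies = as.numeric(accuracies),
      n = length(accuracies),
      mean = ybar,
      sd = if (length(accuracies) > 1L) stats::sd(accuracies) else 0,
      eta = snr_stb(accuracies, m),
      m = m
    ),
    class = "experiment_record"
  )
}

#' @export
print.experiment_record <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Experiment %d [%s]: n = %d, mean = %s, SD = %s, eta = %s dB\n",
    x$experiment_id, x$dataset, x$n,
    format(round(x$mean, digits), nsmall = digits),
    format(round(x$sd, digits), nsmall = digits),
    format(round(x$eta, digits), nsmall = digits)
  ))
  invisible(x)
}

#' Summarise a long table of run accuracies
#'
#' Applies [summarize_runs()] to each `(experiment_id, dataset)` group of a
#' long run table, the CSV format used throughout the package
#' (`experiment_id, dataset, run, accuracy`).
#'
#' @param runs A `data.frame` with columns `experiment_id`, `dataset`, and
#'   `accuracy` (a `run` column is allowed and ignored).
#' @param m Accuracy target, default 1.
#' @return A `data.frame` with one row per group and columns
#'   `experiment_id`, `dataset`, `n`, `mean`, `sd`, `eta`.
#' @export
summarize_run_table <- function(runs, m = 1) {
  need <- c("experiment_id", "dataset", "accuracy")
  if (!all(need %in% names(runs))) {
    stop("'runs' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  grp <- split(runs, list(runs$dataset, runs$experiment_id), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    r <- summarize_runs(g$experiment_id[1L], g$dataset[1L], g$accuracy, m)
    data.frame(experiment_id = r$experiment_id, dataset = r$dataset,
               n = r$n, mean = r$mean, sd = r$sd, eta = r$eta,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$dataset, out$experiment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
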