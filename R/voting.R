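CLASS_LEVELS <- c("ALL", "Normal")

check_labels <- function(x, what) {
  x <- as.character(x)
  bad <- setdiff(unique(x), CLASS_LEVELS)
  if (length(bad) > 0L) {
    stop(what, " contains unknown class labels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Majority vote over a model-by-image prediction matrix
#'
#' Each image receives the class predicted by strictly more than half of
#' the member models.  With an odd number of models a tie is impossible;
#' with an even number a tie is broken toward the positive class `"ALL"`
#' (favouring sensitivity in a screening setting) with a warning.
#'
#' @param votes Character matrix of class labels (`"ALL"`/`"Normal"`),
#'   rows = models, columns = images.
#' @return Character vector of ensemble labels, one per image.
#' @examples
#' v <- rbind(c("ALL", "Normal"), c("ALL", "ALL"), c("Normal", "ALL"))
#' majority_vote(v)
#' @export
majority_vote <- function(votes) {
  if (!is.matrix(votes) || nrow(votes) < 1L || ncol(votes) < 1L) {
    stop("'votes' must be a non-empty model x image matrix", call. = FALSE)
  }
  storage.mode(votes) <- "character"
  check_labels(votes, "'votes'")
  n_all <- colSums(votes == "ALL")
  k <- nrow(votes)
  tie <- n_all * 2L == k
  if (any(tie)) {
    warning(sum(tie), " tied vote(s) broken toward 'ALL'", call. = FALSE)
  }
  ifelse(n_all * 2L >= k, "ALL", "Normal")
}

#' Confusion matrix for binary ALL/Normal classification
#'
#' Counts are laid out with predicted classes as rows and actual classes
#' as columns; the positive class is `"ALL"`, so `TP` = predicted ALL and
#' actually ALL, `FP` = predicted ALL but actually Normal, `FN` =
#' predicted Normal but actually ALL, `TN` = predicted and actually
#' Normal.
#'
#' @param predicted,actual Character vectors of class labels, equal
#'   length.
#' @return A 2 x 2 integer matrix of class `"confusion_matrix"`
#'   (rows `ALL`/`Normal` predicted, columns `ALL`/`Normal` actual).
#' @examples
#' confusion(c("ALL", "ALL", "Normal"), c("ALL", "Normal", "Normal"))
#' @export
confusion <- function(predicted, actual) {
  predicted <- check_labels(predicted, "'predicted'")
  actual <- check_labels(actual, "'actual'")
  if (length(predicted) != length(actual)) {
    stop("'predicted' and 'actual' must have equal length (",
         length(predicted), " vs ", length(actual), ")", call. = FALSE)
  }
  cm <- table(factor(predicted, CLASS_LEVELS),
              factor(actual, CLASS_LEVELS))
  cm <- matrix(as.integer(cm), 2L, 2L,
               dimnames = list(predicted = CLASS_LEVELS,
                               actual = CLASS_LEVELS))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Build a confusion matrix directly from its four counts
#'
#' @param tp,fp,fn,tn Non-negative counts (predicted x actual as in
#'   [confusion()]).
#' @return A `"confusion_matrix"`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  cm <- matrix(as.integer(c(tp, fn, fp, tn)), 2L, 2L,
               dimnames = list(predicted = CLASS_LEVELS,
                               actual = CLASS_LEVELS))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = actual)\n")
  print(unclass(x))
  invisible(x)
}

#' Classification metrics from a binary confusion matrix
#'
#' Computes the five standard performance measures with `"ALL"` as the
#' positive class: accuracy `(TP+TN)/N`, precision `TP/(TP+FP)` (positive
#' predictive value), recall `TP/(TP+FN)` (sensitivity), specificity
#' `TN/(FP+TN)` (true-negative rate), and
#' F1 `= 2 * precision * recall / (precision + recall)`.  A metric with a
#' zero denominator is reported as `NaN` with a warning.
#'
#' @param cm A `"confusion_matrix"` (from [confusion()] or
#'   [confusion_counts()]).
#' @return A named numeric vector of class `"metric_report"` with elements
#'   `accuracy`, `precision`, `recall`, `specificity`, `f1`.
#' @examples
#' classification_metrics(confusion_counts(1118, 177, 101, 471))
#' @export
classification_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    stop("'cm' must be a confusion_matrix", call. = FALSE)
  }
  tp <- cm["ALL", "ALL"]; fp <- cm["ALL", "Normal"]
  fn <- cm["Normal", "ALL"]; tn <- cm["Normal", "Normal"]
  n <- tp + fp + fn + tn
  if (n == 0L) stop("empty confusion matrix", call. = FALSE)
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  f1 <- if (is.nan(precision) || is.nan(recall) ||
            precision + recall == 0) {
    warning("F1 undefined (zero denominator)", call. = FALSE)
    NaN
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    c(accuracy = (tp + tn) / n,
      precision = precision,
      recall = recall,
      specificity = safe_ratio(tn, fp + tn, "specificity"),
      f1 = f1),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

#' Evaluate majority-vote ensembles of increasing size
#'
#' For each requested member count `k`, votes over the *first* `k` models
#' of the prediction matrix (models are assumed ordered as in the
#' confirmation runs) and computes the confusion matrix and metric report
#' against the true labels.
#'
#' @param votes Model x image character matrix of predictions.
#' @param actual True class labels, one per image.
#' @param member_counts Integer vector of ensemble sizes (odd values
#'   recommended; even sizes can tie and tie-break toward `"ALL"`).
#' @return A named list (one element per `k`, names `"ensemble-<k>"`),
#'   each a list with `k`, `confusion`, and `metrics`.
#' @export
ensemble_evaluate <- function(votes, actual,
                              member_counts = c(3L, 5L, 7L, 9L)) {
  if (any(member_counts < 1L) || any(member_counts > nrow(votes))) {
    stop("member counts must be between 1 and the number of models (",
         nrow(votes), ")", call. = FALSE)
  }
  out <- lapply(member_counts, function(k) {
    pred <- majority_vote(votes[seq_len(k), , drop = FALSE])
    cm <- confusion(pred, actual)
    list(k = as.integer(k), confusion = cm,
         metrics = classification_metrics(cm))
  })
  names(out) <- paste0("ensemble-", member_counts)
  out
}

#' Per-image error profile of a voting ensemble
#'
#' For every image the ensemble misclassifies, records the actual class
#' and how many of the individual member models also voted wrongly (the
#' misclassification multiplicity: at least a strict majority, up to all
#' members).  Buckets of the multiplicity, split by actual class, sum to
#' the ensemble's FN (actual ALL) and FP (actual Normal) counts.
#'
#' @param votes Model x image character matrix of predictions.
#' @param actual True class labels.
#' @param ensemble_pred Ensemble labels; computed by [majority_vote()]
#'   when omitted.
#' @return An object of class `"error_profile"`: a list with `errors`
#'   (`data.frame` of `image_id`, `actual`, `n_wrong`) and `buckets`
#'   (`data.frame` of `actual`, `n_wrong`, `n_images`).
#' @export
error_profile <- function(votes, actual, ensemble_pred = NULL) {
  if (is.null(ensemble_pred)) ensemble_pred <- majority_vote(votes)
  actual <- check_labels(actual, "'actual'")
  ensemble_pred <- check_labels(ensemble_pred, "'ensemble_pred'")
  if (ncol(votes) != length(actual) ||
      length(actual) != length(ensemble_pred)) {
    stop("votes, actual, and ensemble_pred dimensions disagree",
         call. = FALSE)
  }
  ids <- colnames(votes)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(votes)))
  n_wrong <- colSums(votes != matrix(actual, nrow(votes),
                                     ncol(votes), byrow = TRUE))
  miss <- which(ensemble_pred != actual)
  errors <- data.frame(image_id = ids[miss],
                       actual = actual[miss],
                       n_wrong = as.integer(n_wrong[miss]),
                       stringsAsFactors = FALSE)
  errors <- errors[order(errors$actual, errors$n_wrong,
                         errors$image_id), , drop = FALSE]
  rownames(errors) <- NULL
  if (nrow(errors) > 0L) {
    buckets <- as.data.frame(table(actual = errors$actual,
                                   n_wrong = errors$n_wrong),
                             stringsAsFactors = FALSE)
    names(buckets)[3L] <- "n_images"
    buckets$n_wrong <- as.integer(buckets$n_wrong)
    buckets <- buckets[buckets$n_images > 0L, , drop = FALSE]
    rownames(buckets) <- NULL
  } else {
    buckets <- data.frame(actual = character(0L),
                          n_wrong = integer(0L),
                          n_images = integer(0L))
  }
  structure(list(errors = errors, buckets = buckets),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat("Ensemble error profile:", nrow(x$errors),
      "misclassified image(s)\n")
  if (nrow(x$buckets) > 0L) print(x$buckets, row.names = FALSE)
  invisible(x)
}
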