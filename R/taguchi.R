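# E_fl matrix: mean SNR of the runs with factor f at level l.
level_means <- function(oa, etas) {
  E <- vapply(seq_len(ncol(oa)), function(f) {
    vapply(1:3, function(l) mean(etas[oa[, f] == l]), numeric(1L))
  }, numeric(3L))
  dimnames(E) <- list(level = as.character(1:3), factor = colnames(oa))
  E
}

#' Factor response table from orthogonal-array SNR values
#'
#' For each factor and each level, averages the SNR values \eqn{\eta_i} of
#' the experiments that ran the factor at that level
#' (\eqn{E_{fl}} = mean of the three \eqn{\eta_i} with factor \eqn{f} at
#' level \eqn{l} in an L9 design).  The factor "effect" is the range
#' \eqn{\max_l E_{fl} - \min_l E_{fl}}, and the best level is the one with
#' the largest \eqn{E_{fl}}.
#'
#' @param oa Orthogonal array from [l9_oa()].
#' @param etas Numeric vector of 9 finite SNR values, ordered by experiment.
#' @return An object of class `"response_table"`: a list with `E` (3 x 4
#'   matrix of level averages, rows = levels, columns = factors),
#'   `effect`, `maximum`, and `best_level` (all per-factor vectors).
#' @examples
#' rt <- response_table(l9_oa(), c(14.03, 13.85, 11.98, 9.14, 13.13,
#'                                 10.17, 14.03, 11.41, 13.13))
#' rt$best_level
#' @export
response_table <- function(oa, etas) {
  if (length(etas) != nrow(oa)) {
    stop("need exactly ", nrow(oa), " SNR values, got ", length(etas),
         call. = FALSE)
  }
  if (!is.numeric(etas) || !all(is.finite(etas))) {
    stop("all SNR values must be finite numbers", call. = FALSE)
  }
  E <- level_means(oa, etas)
  best <- apply(E, 2L, function(col) which(col == max(col))[1L])
  tied <- vapply(seq_len(ncol(E)), function(f) {
    sum(E[, f] == max(E[, f])) > 1L
  }, logical(1L))
  if (any(tied)) {
    warning("tie for best level of factor(s) ",
            paste(colnames(E)[tied], collapse = ", "),
            "; taking the lowest level index", call. = FALSE)
  }
  structure(
    list(E = E,
         effect = apply(E, 2L, max) - apply(E, 2L, min),
         maximum = apply(E, 2L, max),
         best_level = as.integer(best)),
    class = "response_table"
  )
}

#' @export
print.response_table <- function(x, digits = 4, ...) {
  cat("Response table (average SNR per factor level, dB)\n")
  tab <- rbind(round(x$E, digits),
               Effect = round(x$effect, digits),
               Maximum = round(x$maximum, digits),
               `Best level` = x$best_level)
  print(tab)
  invisible(x)
}

#' Pick the best hyperparameter combination from a response table
#'
#' Forms the predicted-best combination by taking, for every factor, the
#' level value with the highest average SNR.  Ties are broken toward the
#' lowest level index with a warning (they cannot arise from continuous
#' accuracy data).
#'
#' @param rt A [response_table()].
#' @param space The matching [factor_space()].
#' @return A named list of level values with attribute `levels`
#'   (the winning 1-based level indices).
#' @export
select_best_combination <- function(rt, space) {
  if (!inherits(rt, "response_table")) {
    stop("'rt' must be a response_table", call. = FALSE)
  }
  if (length(space$factors) != ncol(rt$E)) {
    stop("factor space does not match the response table", call. = FALSE)
  }
  vals <- lapply(seq_along(space$factors), function(f) {
    space$factors[[f]][rt$best_level[f]]
  })
  names(vals) <- names(space$factors)
  attr(vals, "levels") <- stats::setNames(rt$best_level,
                                          names(space$factors))
  vals
}

#' Taguchi ANOVA of orthogonal-array SNR values
#'
#' Decomposes the total sum of squares of the 9 SNR values,
#' \eqn{S_T = \sum_i (\eta_i - \bar\eta)^2}, into per-factor sums of
#' squares \eqn{SS_f = 3 \sum_l (E_{fl} - \bar\eta)^2} (2 df each for a
#' three-level factor).  Four three-level factors exhaust all 8 df of an
#' L9 design, so the residual error SS and df are both zero; the expected
#' sum of squares \eqn{SS_f - df_f V_{error}} then equals \eqn{SS_f}, and
#' the percentage contribution is \eqn{SS_f / S_T \times 100}.
#'
#' @inheritParams response_table
#' @return A `data.frame` of class `"taguchi_anova"` with one row per
#'   factor plus `Error` and `Total` rows, and columns `ss`, `df`,
#'   `variance`, `expected_ss`, `pct_contribution`.
#' @export
taguchi_anova <- function(oa, etas) {
  if (length(etas) != nrow(oa) || !all(is.finite(etas))) {
    stop("need ", nrow(oa), " finite SNR values", call. = FALSE)
  }
  E <- level_means(oa, etas)
  gm <- mean(etas)
  ss_f <- 3 * colSums((E - gm)^2)
  s_t <- sum((etas - gm)^2)
  df_f <- rep(2L, length(ss_f))
  ss_e <- s_t - sum(ss_f)
  df_e <- nrow(oa) - 1L - sum(df_f)
  v_e <- if (df_e > 0L) ss_e / df_e else 0
  exp_ss <- ss_f - df_f * v_e
  pct <- exp_ss / s_t * 100
  out <- data.frame(
    term = c(colnames(oa), "Error", "Total"),
    ss = c(ss_f, ss_e, s_t),
    df = c(df_f, df_e, nrow(oa) - 1L),
    variance = c(ss_f / df_f, if (df_e > 0L) v_e else NA_real_, NA_real_),
    expected_ss = c(exp_ss, NA_real_, NA_real_),
    pct_contribution = c(pct, 100 - sum(pct), 100),
    stringsAsFactors = FALSE
  )
  attr(out, "pooled_error") <- df_e > 0L
  class(out) <- c("taguchi_anova", "data.frame")
  out
}

#' @export
print.taguchi_anova <- function(x, digits = 4, ...) {
  cat("Taguchi ANOVA of SNR values\n")
  y <- x
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  if (!attr(x, "pooled_error")) {
    cat("Note: error df = 0 (factors exhaust all df);",
        "expected SS equals SS.\n")
  }
  invisible(x)
}

#' Fit a Taguchi orthogonal-array analysis
#'
#' The central model of the package: given the SNR values of the nine
#' L9(3^4) screening experiments (or a long run table from which they are
#' computed), fits the additive main-effects decomposition that underlies
#' the Taguchi method, producing the factor response table, the best-level
#' inference, and the ANOVA with percentage contributions.
#'
#' `x` may be (a) a numeric vector of 9 SNR values ordered by experiment,
#' (b) a long run table (`experiment_id, dataset, run, accuracy`) as read
#' by [read_runs_csv()], or (c) the summary `data.frame` produced by
#' [summarize_run_table()] or [run_oa_experiments()].  For (b) and (c) the
#' rows belonging to `dataset` are used.
#'
#' @param x SNR values or a run/summary table (see Details).
#' @param oa The orthogonal array, default [l9_oa()].
#' @param space Optional [factor_space()]; when supplied the best-level
#'   values and predicted-best combination are reported as concrete
#'   hyperparameter values.
#' @param dataset Which dataset split to analyse when `x` is a table;
#'   default `"preliminary_test"` (generalisation accuracy, not training
#'   accuracy, is the quality characteristic of interest).
#' @param m Accuracy target for the SNR, default 1.
#' @return An object of class `"taguchi"` with components `etas`,
#'   `grand_mean`, `response` (a [response_table()]), `anova`
#'   (a [taguchi_anova()]), `best_level`, `best_combination` (when `space`
#'   is given), `records` (per-experiment summaries when computed from
#'   runs), `oa`, `space`, and `call`.  Methods: `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `predict`, `plot`.
#' @examples
#' etas <- c(14.0346, 13.8487, 11.9754, 9.1385, 13.1253,
#'           10.1737, 14.0288, 11.4082, 13.1318)
#' fit <- taguchi(etas)
#' fit$best_level
#' round(residuals(fit), 3)
#' @export
taguchi <- function(x, oa = l9_oa(), space = NULL,
                    dataset = "preliminary_test", m = 1) {
  records <- NULL
  if (is.data.frame(x)) {
    if ("accuracy" %in% names(x)) {
      records <- summarize_run_table(x, m = m)
    } else if (all(c("experiment_id", "eta") %in% names(x))) {
      records <- x
    } else {
      stop("'x' must contain either run accuracies or per-experiment eta",
           call. = FALSE)
    }
    if ("dataset" %in% names(records)) {
      sel <- records[records$dataset == dataset, , drop = FALSE]
      if (nrow(sel) == 0L) {
        stop("no rows for dataset '", dataset, "'", call. = FALSE)
      }
    } else {
      sel <- records
    }
    sel <- sel[order(sel$experiment_id), , drop = FALSE]
    etas <- sel$eta
  } else {
    etas <- as.numeric(x)
  }
  rt <- response_table(oa, etas)
  fit <- structure(
    list(
      etas = etas,
      grand_mean = mean(etas),
      response = rt,
      anova = taguchi_anova(oa, etas),
      best_level = stats::setNames(rt$best_level, colnames(oa)),
      best_combination = if (!is.null(space)) {
        select_best_combination(rt, space)
      },
      records = records,
      dataset = if (is.data.frame(x)) dataset else NULL,
      oa = oa,
      space = space,
      m = m,
      call = match.call()
    ),
    class = "taguchi"
  )
  fit
}

#' @export
print.taguchi <- function(x, digits = 4, ...) {
  cat("Taguchi L9(3^4) orthogonal-array analysis\n")
  if (!is.null(x$dataset)) cat("Dataset split:", x$dataset, "\n")
  cat("Grand mean SNR:", round(x$grand_mean, digits), "dB\n\n")
  print(x$response, digits = digits)
  cat("\nBest level per factor:",
      paste(names(x$best_level), x$best_level, sep = "", collapse = ", "),
      "\n")
  if (!is.null(x$best_combination)) {
    bc <- x$best_combination
    cat("Best combination:",
        paste(names(bc), vapply(bc, format, character(1L)), sep = " = ",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.taguchi <- function(object, digits = 4, ...) {
  print(object, digits = digits)
  cat("\n")
  print(object$anova, digits = digits)
  invisible(object)
}

#' @export
coef.taguchi <- function(object, ...) object$response$E

# Additive main-effects prediction: eta_hat = grand mean + per-factor
# level deviations.  This is the standard Taguchi prediction equation.
predict_levels <- function(object, levels_mat) {
  gm <- object$grand_mean
  E <- object$response$E
  unname(apply(levels_mat, 1L, function(lv) {
    gm + sum(vapply(seq_along(lv),
                    function(f) E[lv[f], f] - gm, numeric(1L)))
  }))
}

#' Predict the SNR of arbitrary level combinations
#'
#' Uses the additive main-effects model implied by the response table:
#' \eqn{\hat\eta = \bar\eta + \sum_f (E_{f,l_f} - \bar\eta)}.
#'
#' @param object A fitted [taguchi()] object.
#' @param newdata A matrix or `data.frame` of 1-based level indices, one
#'   column per factor; if omitted, the predicted SNR of the best
#'   combination.
#' @param ... Unused.
#' @return Numeric vector of predicted SNR values (dB).
#' @export
predict.taguchi <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- matrix(object$best_level, nrow = 1L,
                      dimnames = list(NULL, names(object$best_level)))
  }
  lv <- as.matrix(newdata)
  if (ncol(lv) != ncol(object$response$E)) {
    stop("'newdata' must have one column per factor", call. = FALSE)
  }
  if (!all(lv %in% 1:3)) {
    stop("'newdata' must contain 1-based level indices in 1:3",
         call. = FALSE)
  }
  predict_levels(object, lv)
}

#' @export
fitted.taguchi <- function(object, ...) {
  predict_levels(object, unclass(object$oa))
}

#' @export
residuals.taguchi <- function(object, ...) {
  object$etas - fitted(object)
}

#' Main-effects plot of a Taguchi analysis
#'
#' One panel per factor showing the average SNR at each level, the
#' standard factor-effects display of a screening design.
#'
#' @param x A fitted [taguchi()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.taguchi <- function(x, ...) {
  E <- x$response$E
  nf <- ncol(E)
  old <- graphics::par(mfrow = c(1L, nf), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  ylim <- range(E)
  for (f in seq_len(nf)) {
    graphics::plot(1:3, E[, f], type = "b", pch = 19, ylim = ylim,
                   xaxt = "n", xlab = colnames(E)[f],
                   ylab = if (f == 1L) "Mean SNR (dB)" else "", ...)
    graphics::axis(1, at = 1:3)
    graphics::abline(h = x$grand_mean, lty = 3, col = "grey50")
  }
  invisible(x)
}
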