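#' The three-level L9(3^4) orthogonal array
#'
#' Returns the standard L9 orthogonal array: nine experiments covering four
#' three-level factors so that every pair of columns realises each of the
#' nine ordered level pairs exactly once.  This is the design used to screen
#' the four training hyperparameters (optimizer, mini-batch size, maximum
#' epochs, initial learning rate) with nine training experiments instead of
#' the full 3^4 = 81 grid.
#'
#' @return An integer matrix of class `"orthogonal_array"` with 9 rows
#'   (experiments) and 4 columns (factors `A`..`D`); entries are level
#'   indices in `1:3`.
#' @examples
#' oa <- l9_oa()
#' oa[1, ]  # experiment 1 runs every factor at level 1
#' validate_orthogonality(oa)
#' @export
l9_oa <- function() {
  oa <- matrix(
    c(1L, 1L, 1L, 1L,
      1L, 2L, 2L, 2L,
      1L, 3L, 3L, 3L,
      2L, 1L, 2L, 3L,
      2L, 2L, 3L, 1L,
      2L, 3L, 1L, 2L,
      3L, 1L, 3L, 2L,
      3L, 2L, 1L, 3L,
      3L, 3L, 2L, 1L),
    nrow = 9L, ncol = 4L, byrow = TRUE,
    dimnames = list(as.character(1:9), c("A", "B", "C", "D"))
  )
  class(oa) <- c("orthogonal_array", class(oa))
  oa
}

#' Check the orthogonality of a 9 x 4 three-level array
#'
#' Verifies both defining properties of an L9 design: each column contains
#' each level exactly three times (balance), and every ordered pair of
#' columns realises each of the nine ordered level pairs exactly once.
#'
#' @param oa A 9 x 4 matrix of level indices in `1:3`.
#' @return `TRUE` if the array is a valid L9 orthogonal array, `FALSE` if it
#'   is well-formed but not orthogonal.  A malformed input (wrong shape or
#'   levels outside `1:3`) is an error.
#' @examples
#' validate_orthogonality(l9_oa())
#' @export
validate_orthogonality <- function(oa) {
  if (!is.matrix(oa) || !is.numeric(oa)) {
    stop("'oa' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(oa) != 9L || ncol(oa) != 4L) {
    stop("'oa' must have 9 rows and 4 columns, got ",
         nrow(oa), " x ", ncol(oa), call. = FALSE)
  }
  if (!all(oa %in% 1:3)) {
    stop("all entries of 'oa' must be level indices in 1:3", call. = FALSE)
  }
  for (j in 1:4) {
    if (!all(tabulate(oa[, j], 3L) == 3L)) return(FALSE)
  }
  for (j in 1:3) {
    for (k in (j + 1):4) {
      pairs <- table(factor(oa[, j], 1:3), factor(oa[, k], 1:3))
      if (!all(pairs == 1L)) return(FALSE)
    }
  }
  TRUE
}

#' Define a factor space of hyperparameters and their levels
#'
#' A factor space lists the four factors of the screening design together
#' with exactly three candidate levels each.  Level values may be character
#' or numeric and need not be distinct within a factor: levels are treated
#' as distinct design levels even when their values coincide, so response
#' tables and the ANOVA keep them apart.
#'
#' @param ... Named arguments, one per factor, each a vector of exactly
#'   three level values; alternatively a single named list.
#' @return An object of class `"factor_space"`.
#' @examples
#' sp <- factor_space(
#'   Optimizer        = c("adam", "sgdm", "adam"),
#'   MiniBatchSize    = c(60, 65, 70),
#'   MaxEpochs        = c(8, 10, 12),
#'   InitialLearnRate = c(1e-4, 1e-5, 1e-6)
#' )
#' sp
#' @export
factor_space <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && is.null(names(args))) {
    args <- args[[1L]]
  }
  nm <- names(args)
  if (is.null(nm) || any(nm == "")) {
    stop("every factor must be named", call. = FALSE)
  }
  if (length(args) != 4L) {
    stop("an L9(3^4) factor space needs exactly 4 factors, got ",
         length(args), call. = FALSE)
  }
  for (i in seq_along(args)) {
    if (length(args[[i]]) != 3L) {
      stop(sprintf("factor '%s' must have exactly 3 levels, got %d",
                   nm[i], length(args[[i]])), call. = FALSE)
    }
  }
  structure(list(factors = args), class = "factor_space")
}

#' @export
print.factor_space <- function(x, ...) {
  cat("Factor space (", length(x$factors), " factors, 3 levels each)\n",
      sep = "")
  for (i in seq_along(x$factors)) {
    cat(sprintf("  %s: %s\n", names(x$factors)[i],
                paste(format(x$factors[[i]]), collapse = ", ")))
  }
  invisible(x)
}

#' Read a factor space from a YAML or JSON configuration file
#'
#' The file holds a list of `{name, levels: [3 values]}` entries (or a
#' simple `name: [3 values]` mapping).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [factor_space()] object.
#' @export
read_factor_space <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE)
  )
  # accept either a named mapping or a list of {name, levels} records
  if (!is.null(names(raw)) && !all(c("name", "levels") %in% names(raw[[1L]]))) {
    lv <- raw
  } else {
    lv <- stats::setNames(
      lapply(raw, function(r) unlist(r$levels, use.names = FALSE)),
      vapply(raw, function(r) as.character(r$name), character(1L))
    )
  }
  lv <- lapply(lv, function(v) {
    v <- unlist(v, use.names = FALSE)
    suppressWarnings(num <- as.numeric(v))
    if (!anyNA(num)) num else v
  })
  factor_space(lv)
}

#' Map orthogonal-array level indices onto concrete hyperparameter values
#'
#' Substitutes each factor's declared level values into the design array,
#' producing the nine concrete hyperparameter combinations to run.
#'
#' @param oa An orthogonal array from [l9_oa()].
#' @param space A [factor_space()] with one entry per design column.
#' @return A `data.frame` with columns `experiment_id` and one column per
#'   factor, 9 rows.  The level indices used are kept in the
#'   `"levels"` attribute (an integer matrix).
#' @examples
#' sp <- factor_space(Optimizer = c("adam", "sgdm", "adam"),
#'                    MiniBatchSize = c(60, 65, 70),
#'                    MaxEpochs = c(8, 10, 12),
#'                    InitialLearnRate = c(1e-4, 1e-5, 1e-6))
#' map_combinations(l9_oa(), sp)
#' @export
map_combinations <- function(oa, space) {
  if (!inherits(space, "factor_space")) {
    stop("'space' must be a factor_space object", call. = FALSE)
  }
  if (nrow(oa) != 9L || ncol(oa) != length(space$factors)) {
    stop("array shape does not match the factor space: ",
         ncol(oa), " columns vs ", length(space$factors), " factors",
         call. = FALSE)
  }
  cols <- lapply(seq_along(space$factors), function(f) {
    space$factors[[f]][oa[, f]]
  })
  names(cols) <- names(space$factors)
  out <- data.frame(experiment_id = 1:9, cols,
                    stringsAsFactors = FALSE, check.names = FALSE)
  lv <- unclass(oa)
  colnames(lv) <- names(space$factors)
  attr(out, "levels") <- lv
  out
}

#' Extract one hyperparameter combination from a combination table
#'
#' @param combos The `data.frame` returned by [map_combinations()].
#' @param experiment_id Which experiment row to extract.
#' @return A named list of hyperparameter values with attributes
#'   `experiment_id` and `levels` (the 1-based level indices).
#' @export
combination <- function(combos, experiment_id) {
  i <- match(experiment_id, combos$experiment_id)
  if (is.na(i)) stop("no experiment ", experiment_id, call. = FALSE)
  val <- as.list(combos[i, setdiff(names(combos), "experiment_id")])
  attr(val, "experiment_id") <- combos$experiment_id[i]
  lv <- attr(combos, "levels")
  if (!is.null(lv)) attr(val, "levels") <- lv[i, ]
  val
}
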