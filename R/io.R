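#' Read / write long run-accuracy tables
#'
#' The package's exchange format for screening runs: a CSV with columns
#' `experiment_id, dataset, run, accuracy`.
#'
#' @param path File path.
#' @return `read_runs_csv()` returns the `data.frame`.
#' @export
read_runs_csv <- function(path) {
  runs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "dataset", "run", "accuracy")
  if (!all(need %in% names(runs))) {
    stop(path, " must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  runs
}

#' @rdname read_runs_csv
#' @param runs A run table.
#' @export
write_runs_csv <- function(runs, path) {
  utils::write.csv(runs, path, row.names = FALSE)
  invisible(path)
}

#' Write a labeled image set as PNG folders plus a manifest
#'
#' Lays the images out as `<split>/<label>/<id>.png` under `dir` and
#' writes `manifest.csv` (`image_path, label, split`), the layout
#' consumed by [read_image_dataset()].
#'
#' @param data A `"labeled_image_set"`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_image_dataset <- function(data, dir) {
  stopifnot(inherits(data, "labeled_image_set"))
  paths <- character(length(data$images))
  for (i in seq_along(data$images)) {
    sub <- file.path(dir, data$split[i], data$labels[i])
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(sub, paste0(data$image_ids[i], ".png"))
    png::writePNG(data$images[[i]], paths[i])
  }
  manifest <- data.frame(
    image_path = sub(paste0("^", dir, "/?"), "", paths),
    label = data$labels, split = data$split,
    stringsAsFactors = FALSE
  )
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a labeled image set from a manifest
#'
#' @param dir Directory containing `manifest.csv` and the PNG layout
#'   written by [write_image_dataset()].
#' @return A `"labeled_image_set"`.
#' @export
read_image_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest at ", mpath, call. = FALSE)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  images <- lapply(manifest$image_path, function(p) {
    f <- file.path(dir, p)
    if (!file.exists(f)) stop("missing image file: ", f, call. = FALSE)
    png::readPNG(f)
  })
  ids <- sub("\\.png$", "", basename(manifest$image_path))
  labeled_image_set(images, ids, manifest$label, manifest$split)
}

#' Write / read a vote matrix as CSV
#'
#' Rows are models, columns are image ids.
#'
#' @param votes Character model x image matrix.
#' @param path File path.
#' @export
write_votes_csv <- function(votes, path) {
  df <- data.frame(model = rownames(votes), votes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_votes_csv
#' @export
read_votes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  votes <- as.matrix(df[, -1L, drop = FALSE])
  rownames(votes) <- df[[1L]]
  votes
}

#' Taguchi analysis of a run-accuracy table, with file outputs
#'
#' The analysis entry point behind the command line: reads a long run
#' table (path or `data.frame`), fits [taguchi()] on the chosen split,
#' and optionally writes the per-experiment summary, response table,
#' ANOVA, and best combination as CSV files shaped like the package's
#' printed reports.
#'
#' @param runs Path to a runs CSV or a run `data.frame`.
#' @param space The [factor_space()]; factor names label the outputs.
#' @param dataset Split to analyse, default `"preliminary_test"`.
#' @param out_dir Optional output directory for the CSV reports.
#' @param m SNR target, default 1.
#' @return The fitted `"taguchi"` object (invisibly when `out_dir` is
#'   given).
#' @export
analyze_runs <- function(runs, space, dataset = "preliminary_test",
                         out_dir = NULL, m = 1) {
  if (is.character(runs)) runs <- read_runs_csv(runs)
  fit <- taguchi(runs, space = space, dataset = dataset, m = m)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fit$records,
                     file.path(out_dir, "experiment_summary.csv"),
                     row.names = FALSE)
    E <- fit$response$E
    colnames(E) <- names(space$factors)
    rtab <- rbind(E, Effect = fit$response$effect,
                  Maximum = fit$response$maximum,
                  `Best level` = fit$response$best_level)
    utils::write.csv(data.frame(level = rownames(rtab), rtab,
                                check.names = FALSE),
                     file.path(out_dir, "response_table.csv"),
                     row.names = FALSE)
    av <- fit$anova
    av$term[seq_along(space$factors)] <- names(space$factors)
    utils::write.csv(av, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    bc <- fit$best_combination
    utils::write.csv(
      data.frame(factor = names(bc),
                 best_level = attr(bc, "levels"),
                 best_value = vapply(bc, format, character(1L)),
                 stringsAsFactors = FALSE),
      file.path(out_dir, "best_combination.csv"), row.names = FALSE)
    return(invisible(fit))
  }
  fit
}

#' Read a pipeline run configuration
#'
#' A single YAML (or JSON) file resolving everything [run_pipeline()]
#' needs; missing keys fall back to the defaults documented there.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE)
  )
}

default_factor_space <- function() {
  factor_space(
    Optimizer        = c("adam", "sgdm", "adam"),
    MiniBatchSize    = c(60, 65, 70),
    MaxEpochs        = c(8, 10, 12),
    InitialLearnRate = c(1e-4, 1e-5, 1e-6)
  )
}

#' Run the whole screening-and-ensemble pipeline
#'
#' Executes design construction, the nine orthogonal-array screening
#' experiments, the Taguchi analysis with best-combination inference,
#' the confirmation runs, majority-vote ensembles of increasing size,
#' and the per-image error report; writes every artifact to
#' `out_dir` and a `summary.json` with the per-model and per-ensemble
#' metric reports.
#'
#' @param config A named list (or the path to a YAML/JSON file read via
#'   [read_run_config()]) with elements: `backend`
#'   (`"surrogate"`/`"tiny_cnn"`, or a backend object), `factors`
#'   (a [factor_space()], a path, or omitted for the default four
#'   training hyperparameters), `data` (a `"labeled_image_set"`, a
#'   dataset directory for [read_image_dataset()], or omitted to
#'   generate synthetic cells), `synthetic` (arguments to
#'   [synthetic_cells()]), `n_runs`, `n_confirmation_models`,
#'   `ensemble_sizes`, `seed`, and `out_dir`.
#' @return A list with the fitted `"taguchi"` object, the
#'   `"oa_experiments"`, the `"confirmation_runs"`, the ensemble
#'   evaluations, the `"error_profile"`, and the summary written to
#'   disk.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("oaensemble-run-")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  space <- config$factors %||% default_factor_space()
  if (is.character(space)) space <- read_factor_space(space)
  if (!inherits(space, "factor_space")) space <- factor_space(space)

  backend <- config$backend %||% "surrogate"
  if (is.character(backend)) {
    backend <- switch(backend,
      surrogate = {
        # mild default main effects so the surrogate pipeline has signal
        eff <- list(c(0.04, 0, 0.03), c(0, 0.02, -0.01),
                    c(-0.01, 0, 0.02), c(0.05, 0.01, -0.04))
        surrogate_backend(effects = eff)
      },
      tiny_cnn = tiny_cnn_backend(),
      stop("unknown backend '", backend, "'", call. = FALSE))
  }

  data <- config$data
  if (is.null(data)) {
    syn <- config$synthetic %||% list()
    syn$seed <- syn$seed %||% (seed + 1L)
    data <- do.call(synthetic_cells, syn)
  } else if (is.character(data)) {
    data <- read_image_dataset(data)
  }
  if (inherits(backend, "tiny_cnn_backend")) {
    data <- preprocess_images(data, rep(backend$input_size, 2L))
  }

  combos <- map_combinations(l9_oa(), space)
  utils::write.csv(combos, file.path(out_dir, "combinations.csv"),
                   row.names = FALSE)

  ox <- run_oa_experiments(backend, l9_oa(), space, data,
                           n_runs = as.integer(config$n_runs %||% 3L),
                           seed = seed)
  write_runs_csv(ox$runs, file.path(out_dir, "runs.csv"))
  fit <- analyze_runs(ox$runs, space, out_dir = out_dir)

  best <- fit$best_combination
  conf <- confirmation_runs(
    backend, best, data,
    n_models = as.integer(config$n_confirmation_models %||% 9L),
    seed = seed + 1L)
  utils::write.csv(conf$accuracies,
                   file.path(out_dir, "confirmation_accuracies.csv"),
                   row.names = FALSE)
  write_votes_csv(conf$votes, file.path(out_dir, "votes.csv"))

  sizes <- as.integer(config$ensemble_sizes %||%
                        seq(3L, nrow(conf$votes), by = 2L))
  ens <- ensemble_evaluate(conf$votes, conf$actual, sizes)
  prof <- error_profile(conf$votes, conf$actual,
                        majority_vote(conf$votes))
  utils::write.csv(prof$errors, file.path(out_dir, "error_profile.csv"),
                   row.names = FALSE)

  model_metrics <- lapply(seq_len(nrow(conf$votes)), function(i) {
    cm <- confusion(conf$votes[i, ], conf$actual)
    as.list(unclass(classification_metrics(cm)))
  })
  names(model_metrics) <- conf$accuracies$model
  summary <- list(
    seed = seed,
    best_combination = lapply(best, identity),
    best_levels = as.list(attr(best, "levels")),
    confirmation = list(mean = conf$record$mean, sd = conf$record$sd,
                        eta = conf$record$eta),
    models = model_metrics,
    ensembles = lapply(ens, function(e) {
      c(list(k = e$k), as.list(unclass(e$metrics)))
    })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(list(seed = seed, n_runs = config$n_runs %||% 3L,
                        backend = class(backend)[1L],
                        ensemble_sizes = sizes),
                   file.path(out_dir, "config_resolved.yaml"))

  invisible(list(fit = fit, experiments = ox, confirmation = conf,
                 ensembles = ens, error_profile = prof,
                 summary = summary, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paths to the bundled example tables
#'
#' The package ships three small CSV fixtures from a published L9
#' hyperparameter screen of a fine-tuned residual-network classifier on
#' the C-NMC leukemia image dataset: `"screening_runs"` (the 54 run
#' accuracies of the nine screening experiments on both splits),
#' `"confirmation_accuracies"` (train/test accuracy of the nine
#' confirmation models), and `"confusion_matrices"` (the confusion
#' matrices of the nine individual models and the 3/5/7/9-member voting
#' ensembles on the 1,867-image preliminary test set), plus
#' `"factors"` (the YAML factor space of the screen).
#'
#' @param name One of `"screening_runs"`, `"confirmation_accuracies"`,
#'   `"confusion_matrices"`, `"factors"`.
#' @return The file path.
#' @examples
#' head(read_runs_csv(example_table("screening_runs")))
#' @export
example_table <- function(name = c("screening_runs",
                                   "confirmation_accuracies",
                                   "confusion_matrices", "factors")) {
  name <- match.arg(name)
  file <- paste0(name, if (name == "factors") ".yaml" else ".csv")
  path <- system.file("extdata", file, package = "oaensemble",
                      mustWork = TRUE)
  path
}
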