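#' Bundle a cohort with its feature sources
#'
#' An experiment consumes a cohort plus one or more named feature sources:
#' numeric matrices with one row per recording (rownames = recording ids).
#' The batch-encoding source (`baef`) can be added automatically.
#'
#' @param cohort A [build_cohort()] object.
#' @param sources Named list of numeric matrices; each must cover every
#'   recording of the cohort.
#' @param add_baef Add the two-level batch-encoding design matrix as source
#'   `"baef"`.
#' @return Object of class `experiment_data`.
#' @export
experiment_data <- function(cohort, sources, add_baef = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(sources) == 0 && !add_baef) stop("no feature sources given")
  if (length(sources) > 0 && is.null(names(sources))) stop("sources must be named")
  ids <- cohort$recordings$recording_id
  sources <- lapply(sources, function(x) {
    x <- as.matrix(x)
    if (is.null(rownames(x))) {
      if (nrow(x) != length(ids)) stop("unnamed source rows must match recording count")
      rownames(x) <- ids
    }
    missing <- setdiff(ids, rownames(x))
    if (length(missing) > 0) {
      stop("source lacks recordings: ", paste(utils::head(missing, 3), collapse = ", "))
    }
    x[ids, , drop = FALSE]
  })
  if (add_baef) sources$baef <- batch_design(cohort)
  structure(list(cohort = cohort, sources = sources), class = "experiment_data")
}

#' Convert a synthetic dataset to experiment data
#'
#' @param dataset A [generate_dataset()] result.
#' @param source_name Name for the feature source (default `"synthetic"`).
#' @param add_baef Also attach the batch-encoding source.
#' @return An [experiment_data()] object.
#' @export
as_experiment_data <- function(dataset, source_name = "synthetic", add_baef = FALSE) {
  stopifnot(inherits(dataset, "synth_dataset"))
  sources <- stats::setNames(list(dataset$features), source_name)
  experiment_data(dataset$cohort, sources, add_baef = add_baef)
}

#' Configuration of a classification experiment
#'
#' @param scheme Cross-validation scheme: `"recording_kfold"`,
#'   `"subject_kfold"` or `"leave_one_site_out"`.
#' @param k Folds for the k-fold schemes.
#' @param p Prototypes per source (default 40, capped at the training-set
#'   size per fold).
#' @param distances Named list mapping source name to distance
#'   specification (`"euclidean"`, `"correlation"`, or a function); unnamed
#'   sources fall back to `default_distance`.
#' @param default_distance Distance for sources not listed in `distances`.
#' @param split_seed,fft_seed Seeds for the fold split and the prototype
#'   selection.
#' @param classifier A [classifier_spec()].
#' @param bf_M,bf_seed,bf_method Monte Carlo iterations, seed and method for
#'   [log_bayes_factor()].
#' @param prototypes `"per_fold"` selects prototypes from each fold's
#'   training portion only (no test leakage; the default); `"global"`
#'   selects once from the full dataset before splitting, reproducing the
#'   leakage-prone alternative for comparison.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(scheme = c("recording_kfold", "subject_kfold",
                                         "leave_one_site_out"),
                              k = 10L, p = 40L,
                              distances = list(), default_distance = "euclidean",
                              split_seed = 1L, fft_seed = 1L,
                              classifier = classifier_spec(),
                              bf_M = 1000L, bf_seed = 1L, bf_method = "auto",
                              prototypes = c("per_fold", "global")) {
  structure(
    list(
      scheme = match.arg(scheme), k = as.integer(k), p = as.integer(p),
      distances = distances, default_distance = default_distance,
      split_seed = as.integer(split_seed), fft_seed = as.integer(fft_seed),
      classifier = classifier,
      bf_M = as.integer(bf_M), bf_seed = as.integer(bf_seed),
      bf_method = bf_method,
      prototypes = match.arg(prototypes)
    ),
    class = "experiment_config"
  )
}

source_distance <- function(config, source) {
  if (!is.null(config$distances[[source]])) config$distances[[source]]
  else config$default_distance
}

build_plan <- function(cohort, config) {
  switch(config$scheme,
    recording_kfold = recording_kfold(cohort, k = config$k, seed = config$split_seed),
    subject_kfold = subject_kfold(cohort, k = config$k, seed = config$split_seed),
    leave_one_site_out = leave_one_site_out(cohort, seed = config$split_seed)
  )
}

#' Run a classification experiment on one or several sources
#'
#' For each cross-validation fold: prototypes are selected (by default from
#' the training portion only), train and test recordings are projected into
#' the dissimilarity space of each requested source, the per-source
#' projections are concatenated in the declared order, the tree ensemble is
#' fitted on the training projection and evaluated on the test projection.
#' Fold confusion matrices are summed and the aggregate matrix is scored by
#' accuracy and by the Bayesian test of independence.
#'
#' @param data An [experiment_data()] bundle.
#' @param sources Character vector of source names (one for a single-source
#'   run, several for a multi-source run; concatenation order = the order
#'   given). `run_single_source()` and `run_multi_source()` are thin
#'   wrappers enforcing arity.
#' @param config An [experiment_config()].
#' @param label Row label for the report (defaults to the source names
#'   joined with `+`).
#' @return A one-row `result_row` tibble with columns `data`, `log_b10`,
#'   `pa` (aggregate trace/m), `pa_fold_mean` (mean of per-fold
#'   accuracies), `tp`, `tn`, `fp`, `fn`, and attribute `details` (fold
#'   matrices, split plan, prototype audit, Bayes-factor result, config).
#' @export
run_experiment <- function(data, sources, config = experiment_config(),
                           label = NULL) {
  stopifnot(inherits(data, "experiment_data"))
  missing <- setdiff(sources, names(data$sources))
  if (length(missing) > 0) stop("unknown source(s): ", paste(missing, collapse = ", "))
  if (is.null(label)) label <- paste(sources, collapse = "+")
  cohort <- data$cohort
  plan <- build_plan(cohort, config)
  labels_of <- stats::setNames(cohort$recordings$class_label,
                               cohort$recordings$recording_id)

  global_protos <- NULL
  if (config$prototypes == "global") {
    global_protos <- lapply(sources, function(src) {
      x <- data$sources[[src]]
      fft_select(x, min(config$p, nrow(x)),
                 distance = source_distance(config, src), seed = config$fft_seed)
    })
  }

  fold_results <- lapply(seq_len(nrow(plan)), function(i) {
    train_ids <- plan$train[[i]]
    test_ids <- plan$test[[i]]
    proto_ids <- vector("list", length(sources))
    names(proto_ids) <- sources # duplicates allowed; indexed by position
    proj_train <- vector("list", length(sources))
    proj_test <- vector("list", length(sources))
    for (si in seq_along(sources)) {
      src <- sources[si]
      x <- data$sources[[src]]
      if (config$prototypes == "global") {
        ps <- global_protos[[si]]
        proto_ids[[si]] <- rownames(x)[ps$indices]
      } else {
        xtr <- x[train_ids, , drop = FALSE]
        ps <- fft_select(xtr, min(config$p, length(train_ids)),
                         distance = source_distance(config, src),
                         seed = config$fft_seed + i)
        proto_ids[[si]] <- train_ids[ps$indices]
      }
      proj_train[[si]] <- project(x[train_ids, , drop = FALSE], ps)
      proj_test[[si]] <- project(x[test_ids, , drop = FALSE], ps)
    }
    ftr <- do.call(cbind, unname(proj_train))
    fte <- do.call(cbind, unname(proj_test))
    spec <- config$classifier
    spec$seed <- spec$seed + i # independent tree randomization per fold
    model <- train_classifier(ftr, labels_of[train_ids], spec)
    pred <- predict_classifier(model, fte)
    list(
      confusion = confusion_from_predictions(labels_of[test_ids], pred,
                                             n_classes = cohort$n_classes),
      prototype_ids = proto_ids,
      train_ids = train_ids,
      test_ids = test_ids,
      feature_dim = ncol(ftr)
    )
  })

  total <- sum_confusions(lapply(fold_results, `[[`, "confusion"))
  bf <- log_bayes_factor(total, M = config$bf_M, seed = config$bf_seed,
                         method = config$bf_method)
  pa_folds <- vapply(fold_results, function(f) accuracy(f$confusion), numeric(1))
  row <- tibble::tibble(
    data = label,
    log_b10 = bf$log_b10,
    pa = accuracy(total),
    pa_fold_mean = mean(pa_folds),
    tp = total[2, 2], tn = total[1, 1], fp = total[1, 2], fn = total[2, 1]
  )
  attr(row, "details") <- list(
    sources = sources,
    feature_dim = vapply(fold_results, `[[`, numeric(1), "feature_dim"),
    confusion = total,
    fold_confusions = lapply(fold_results, `[[`, "confusion"),
    fold_prototypes = lapply(fold_results, `[[`, "prototype_ids"),
    plan = plan,
    bayes_factor = bf,
    config = config
  )
  class(row) <- c("result_row", class(row))
  row
}

#' @rdname run_experiment
#' @export
run_single_source <- function(data, source, config = experiment_config(),
                              label = NULL) {
  stopifnot(length(source) == 1)
  run_experiment(data, source, config, label = label)
}

#' @rdname run_experiment
#' @export
run_multi_source <- function(data, sources, config = experiment_config(),
                             label = NULL) {
  if (length(sources) < 2) stop("multi-source runs need >= 2 sources")
  run_experiment(data, sources, config, label = label)
}

#' Write an experiment report
#'
#' Writes the standard results layout -- one row per data source with
#' columns `Data`, `log(B10)`, `PA`, `TP`, `TN`, `FP`, `FN` -- as TSV, plus
#' a JSON sidecar carrying everything needed to re-derive each cell: the
#' scheme, seeds, per-fold confusion matrices and configuration.
#'
#' @param rows A `result_row` or a list of them.
#' @param path Output TSV path; the sidecar goes to `<path>.json`.
#' @param digits Decimal places for `log(B10)` and `PA` in the TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, digits = 2) {
  if (inherits(rows, "result_row")) rows <- list(rows)
  if (length(rows) == 0) stop("no result rows")
  tab <- data.frame(
    Data = vapply(rows, function(r) r$data, character(1)),
    `log(B10)` = vapply(rows, function(r) round(r$log_b10, digits), numeric(1)),
    PA = vapply(rows, function(r) round(r$pa, digits), numeric(1)),
    TP = vapply(rows, function(r) as.integer(r$tp), integer(1)),
    TN = vapply(rows, function(r) as.integer(r$tn), integer(1)),
    FP = vapply(rows, function(r) as.integer(r$fp), integer(1)),
    FN = vapply(rows, function(r) as.integer(r$fn), integer(1)),
    check.names = FALSE
  )
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write report to ", path, ": ", conditionMessage(e)))
  sidecar <- lapply(rows, function(r) {
    d <- attr(r, "details")
    list(
      data = r$data,
      sources = d$sources,
      log_b10 = r$log_b10,
      pa = r$pa,
      pa_fold_mean = r$pa_fold_mean,
      confusion = unclass(d$confusion),
      fold_confusions = lapply(d$fold_confusions, unclass),
      scheme = attr(d$plan, "scheme"),
      k = attr(d$plan, "k"),
      split_seed = attr(d$plan, "seed"),
      fft_seed = d$config$fft_seed,
      prototypes = d$config$prototypes,
      p = d$config$p,
      classifier = unclass(d$config$classifier),
      bayes_factor = list(
        log_b10 = d$bayes_factor$log_b10, t_star = d$bayes_factor$t_star,
        M = d$bayes_factor$M, seed = d$bayes_factor$seed,
        method = d$bayes_factor$method
      )
    )
  })
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Plot a set of result rows
#'
#' Bar chart of the log Bayes factor per data source, the conventional
#' strong-evidence reference `log B10 = 3` marked.
#'
#' @param rows A `result_row` or list of them.
#' @return A ggplot object.
#' @export
plot_results <- function(rows) {
  if (inherits(rows, "result_row")) rows <- list(rows)
  tab <- dplyr::bind_rows(lapply(rows, function(r) r[, c("data", "log_b10")]))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$data, y = .data$log_b10)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 3, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "log B10")
}
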