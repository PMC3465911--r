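#' Specification of the randomized-tree ensemble classifier
#'
#' The classification stage is an ensemble of extremely randomized trees:
#' fully grown trees where candidate split points are drawn at random, with
#' every tree trained on the whole sample (no bootstrap). The family is
#' insensitive to monotone feature rescaling and fits both linear and
#' non-linear structure. Backed by \pkg{ranger} with
#' `splitrule = "extratrees"`.
#'
#' @param num_trees Number of trees (default 501; an odd count rules out
#'   majority-vote ties in two-class problems, keeping prediction exactly
#'   deterministic).
#' @param mtry Features tried per split; `NULL` = `sqrt(p)` default.
#' @param num_random_splits Random cut-points drawn per candidate feature
#'   (1 = classical extremely randomized trees).
#' @param seed Integer seed; a fixed seed makes training and prediction
#'   reproducible bit-for-bit (training runs single-threaded).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(num_trees = 501L, mtry = NULL,
                            num_random_splits = 1L, seed = 1L) {
  structure(
    list(
      algorithm = "extremely_randomized_trees",
      num_trees = as.integer(num_trees),
      mtry = if (is.null(mtry)) NULL else as.integer(mtry),
      num_random_splits = as.integer(num_random_splits),
      seed = as.integer(seed)
    ),
    class = "classifier_spec"
  )
}

#' Train the tree-ensemble classifier
#'
#' @param features Numeric matrix, one row per example.
#' @param labels Integer class labels (>= 2 distinct values present).
#' @param spec A [classifier_spec()].
#' @return Object of class `sitewise_model` wrapping the fitted ensemble
#'   and the training label set.
#' @export
train_classifier <- function(features, labels, spec = classifier_spec()) {
  features <- as.matrix(features)
  if (nrow(features) == 0) stop("empty feature matrix")
  if (nrow(features) != length(labels)) stop("rows(features) != length(labels)")
  if (nrow(features) < 2) stop("need at least two training examples")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("training set contains a single class; cannot fit a discriminative model")
  }
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(features)))
  fit <- ranger::ranger(
    x = df,
    y = factor(labels),
    num.trees = spec$num_trees,
    mtry = spec$mtry,
    splitrule = "extratrees",
    num.random.splits = spec$num_random_splits,
    replace = FALSE,
    sample.fraction = 1,
    seed = spec$seed,
    num.threads = 1,
    verbose = FALSE
  )
  structure(
    list(fit = fit, n_features = ncol(features), labels = sort(unique(labels)),
         spec = spec),
    class = "sitewise_model"
  )
}

#' Predict class labels with a trained ensemble
#'
#' @param model A [train_classifier()] fit.
#' @param features Numeric matrix with the training feature dimension.
#' @return Integer label vector, one per row, values from the training
#'   label set.
#' @export
predict_classifier <- function(model, features) {
  stopifnot(inherits(model, "sitewise_model"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    stop("feature dimension mismatch: model expects ", model$n_features,
         ", got ", ncol(features))
  }
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(features)))
  pred <- stats::predict(model$fit, data = df, num.threads = 1)
  as.integer(as.character(pred$predictions))
}
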