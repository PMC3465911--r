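#' Confusion matrix from predicted and true labels
#'
#' Counts (true class, predicted class) pairs over a test set into a c-by-c
#' matrix with true labels on the rows and predicted labels on the columns.
#'
#' @param truth,estimate Equal-length integer label vectors with values in
#'   `0..n_classes-1`.
#' @param n_classes Number of classes (default 2).
#' @return Object of class `confusion_matrix`: integer matrix with
#'   attributes `m` (total count) and `n_classes`.
#' @export
confusion_from_predictions <- function(truth, estimate, n_classes = 2L) {
  if (length(truth) != length(estimate)) stop("label vectors differ in length")
  if (length(truth) == 0) stop("empty label sequences")
  truth <- as.integer(truth)
  estimate <- as.integer(estimate)
  if (anyNA(truth) || anyNA(estimate)) stop("labels must not contain NA")
  if (any(truth < 0L | truth >= n_classes) || any(estimate < 0L | estimate >= n_classes)) {
    stop("labels must lie in 0..", n_classes - 1L)
  }
  lv <- 0:(n_classes - 1L)
  y <- table(factor(truth, levels = lv), factor(estimate, levels = lv))
  y <- matrix(as.integer(y), n_classes, n_classes,
              dimnames = list(true = lv, predicted = lv))
  new_confusion(y)
}

new_confusion <- function(y) {
  structure(y, m = sum(y), n_classes = nrow(y),
            class = c("confusion_matrix", "matrix", "array"))
}

#' Confusion matrix from binary-classification cell counts
#'
#' Convenience constructor from the TP/TN/FP/FN convention for two classes
#' with class 1 the positive (patient) class: `y = [[TN, FP], [FN, TP]]`,
#' rows true, columns predicted.
#'
#' @param tp,tn,fp,fn Non-negative integer cell counts.
#' @return A 2x2 `confusion_matrix`.
#' @export
confusion_from_counts <- function(tp, tn, fp, fn) {
  cells <- c(tn, fn, fp, tp)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  y <- matrix(as.integer(cells), 2, 2, dimnames = list(true = 0:1, predicted = 0:1))
  new_confusion(y)
}

#' Sum confusion matrices over folds
#'
#' Elementwise sum of per-fold confusion matrices; the aggregate test-set
#' size is the sum of the fold sizes.
#'
#' @param matrices List of `confusion_matrix` objects with equal class
#'   count.
#' @return A `confusion_matrix`.
#' @export
sum_confusions <- function(matrices) {
  if (length(matrices) == 0) stop("no matrices to sum")
  cc <- vapply(matrices, nrow, integer(1))
  if (length(unique(cc)) != 1) stop("matrices have mixed class counts")
  new_confusion(Reduce(`+`, lapply(matrices, unclass)))
}

#' Prediction accuracy and error rate of a confusion matrix
#'
#' `accuracy = trace(y) / m`; `error_rate = 1 - accuracy`. With unbalanced
#' classes these can be misleading on their own -- the motivation for the
#' independence test below.
#'
#' @param y A `confusion_matrix`.
#' @return A number in \[0, 1\].
#' @export
accuracy <- function(y) {
  m <- sum(y)
  if (m < 1) stop("empty confusion matrix")
  sum(diag(unclass(y))) / m
}

#' @rdname accuracy
#' @export
error_rate <- function(y) 1 - accuracy(y)

# Shared log-space constant of the intrinsic-prior Bayes factor at training
# size t for a square c x c table y:
#   Gamma(t + c^2) / Gamma(t + m + c^2) * Gamma(m + c)^2 / Gamma(t + c)^2
#     / (prod_i r_i(y)! prod_j c_j(y)!)
bf_log_const <- function(y, t) {
  cc <- nrow(y)
  m <- sum(y)
  lgamma(t + cc^2) - lgamma(t + m + cc^2) +
    2 * lgamma(m + cc) - 2 * lgamma(t + cc) -
    sum(lgamma(rowSums(y) + 1)) - sum(lgamma(colSums(y) + 1))
}

#' Log Bayes factor of dependence at a fixed training size t
#'
#' Evaluates `log B10(y, t)`, the intrinsic-prior Bayes factor of the
#' dependence hypothesis H1 against independence H0 for a confusion matrix
#' `y` under the multinomial sampling model, at intrinsic training-sample
#' size `t`. The intrinsic prior mixes Dirichlet posteriors over training
#' tables of size `t` weighted by their null marginal, which concentrates
#' the H1 prior around H0 as `t` grows.
#'
#' Two evaluation routes are provided:
#'
#' * `method = "mc"`: the Monte Carlo importance-sampling estimator --
#'   `M` draws `x_k ~ Multinomial(t, theta_hat)` with
#'   `theta_hat_ij = (y_ij + 1) / (m + c^2)`, every factorial evaluated via
#'   `lgamma` and the average taken with a log-sum-exp, so nothing
#'   overflows. Deterministic given `seed`.
#' * `method = "exact"`: full enumeration of all training tables (2x2 only;
#'   compiled, log-space). This is the converged limit of the Monte Carlo
#'   estimator and carries no sampling error.
#'
#' @param y A `confusion_matrix`.
#' @param t Integer training-sample size, `0 <= t <= m`.
#' @param M Monte Carlo iterations (>= 1).
#' @param seed Seed for the Monte Carlo draws.
#' @param method `"mc"` or `"exact"`.
#' @return `log B10(y, t)` (natural log). For `method = "mc"` the result
#'   carries attributes `se_log` (delta-method standard error on the log
#'   scale) and `M`.
#' @export
log_bayes_factor_at_t <- function(y, t, M = 1000L, seed = 1L,
                                  method = c("mc", "exact")) {
  method <- match.arg(method)
  m <- sum(y)
  if (t < 0 || t > m) stop("t must lie in 0..m")
  if (method == "exact") {
    if (nrow(y) != 2) stop("exact enumeration is available for 2x2 matrices only")
    return(bf_log_const(y, t) + bf_exact_log_sum(unclass(y), as.integer(t)))
  }
  if (M < 1) stop("M must be >= 1")
  with_seed(seed, bf_mc_at_t(y, t, M))
}

# Monte Carlo core (uses the current RNG stream; callers seed it).
bf_mc_at_t <- function(y, t, M) {
  cc <- nrow(y)
  c2 <- cc^2
  m <- sum(y)
  const <- bf_log_const(y, t)
  if (t == 0) { # single term: the empty training table
    out <- const + sum(lgamma(unclass(y) + 1))
    attr(out, "se_log") <- 0
    attr(out, "M") <- as.integer(M)
    return(out)
  }
  theta <- as.vector((unclass(y) + 1) / (m + c2))
  x <- stats::rmultinom(M, t, theta) # c2 x M, cells in column-major order
  row_of <- rep(seq_len(cc), times = cc)
  col_of <- rep(seq_len(cc), each = cc)
  # log weights: row/col factorials of x, Dirichlet ratio, importance correction
  rsum <- rowsum(x, group = row_of)            # cc x M row sums
  csum <- rowsum(x, group = col_of)            # cc x M col sums
  s <- colSums(lgamma(rsum + 1)) + colSums(lgamma(csum + 1)) +
    colSums(lgamma(x + as.vector(unclass(y)) + 1) - lgamma(x + 1) - x * log(theta))
  mx <- max(s)
  w <- exp(s - mx)
  est <- mean(w)
  se_rel <- stats::sd(w) / sqrt(M) / est # relative SE => SE of the log
  out <- const + mx + log(est)
  attr(out, "se_log") <- se_rel
  attr(out, "M") <- as.integer(M)
  out
}

#' Bayes factor of dependence, minimized over the training size
#'
#' The reported evidence is the conservative minimum of `log B10(y, t)` over
#' the intrinsic training-sample size `t` in `{0..m}`. For small test sets
#' the scan is exhaustive; for larger ones a geometric coarse grid is
#' followed by local refinement around the coarse minimizer down to step 1,
#' and the minimum is checked to be locally stable.
#'
#' `log B10 >> 0` is strong evidence that predicted and true labels are
#' dependent, i.e. that the classifier learned the discrimination;
#' `log B10 <= 0` means the confusion matrix is compatible with
#' independence.
#'
#' @param y A `confusion_matrix`.
#' @param M Monte Carlo iterations per t (ignored by the exact route).
#' @param seed Seed for the Monte Carlo draws.
#' @param t_grid Optional integer vector of t values to scan instead of the
#'   default policy.
#' @param method `"auto"` (exact for 2x2 tables up to m = 2000, Monte Carlo
#'   otherwise), `"exact"`, or `"mc"`.
#' @param exhaustive_max Largest m for which the default scan is the full
#'   `0..m` range.
#' @return Object of class `bayes_factor_result`: list with `log_b10`,
#'   `t_star`, `curve` (tibble of scanned `t` and `log_b10`), `m`,
#'   `n_classes`, `M`, `seed`, `method`.
#' @export
log_bayes_factor <- function(y, M = 1000L, seed = 1L, t_grid = NULL,
                             method = c("auto", "exact", "mc"),
                             exhaustive_max = 200L) {
  method <- match.arg(method)
  m <- sum(y)
  if (m < 1) stop("empty confusion matrix")
  if (method == "auto") {
    method <- if (nrow(y) == 2 && m <= 2000) "exact" else "mc"
  }
  eval_t <- function(t) {
    if (method == "exact") {
      log_bayes_factor_at_t(y, t, method = "exact")
    } else {
      # one reproducible stream per (seed, t)
      as.numeric(log_bayes_factor_at_t(y, t, M = M, seed = seed + t, method = "mc"))
    }
  }
  if (is.null(t_grid)) {
    if (m <= exhaustive_max) {
      t_grid <- 0:m
    } else {
      t_grid <- unique(c(0L, as.integer(round(exp(seq(0, log(m), length.out = 25)))), m))
    }
  } else {
    t_grid <- sort(unique(as.integer(t_grid)))
    if (any(t_grid < 0) || any(t_grid > m)) stop("t_grid must lie within 0..m")
  }
  vals <- vapply(t_grid, eval_t, numeric(1))
  scanned_t <- t_grid
  scanned_v <- vals
  # local refinement between the grid neighbours of the coarse minimizer
  repeat {
    i <- which.min(scanned_v)
    lo <- if (i > 1) scanned_t[i - 1L] else scanned_t[i]
    hi <- if (i < length(scanned_t)) scanned_t[i + 1L] else scanned_t[i]
    gap <- max(scanned_t[i] - lo, hi - scanned_t[i])
    if (gap <= 1L) break
    extra <- setdiff(unique(as.integer(round(seq(lo, hi, length.out = 9)))), scanned_t)
    if (length(extra) == 0) break
    vv <- vapply(extra, eval_t, numeric(1))
    scanned_t <- c(scanned_t, extra)
    scanned_v <- c(scanned_v, vv)
    ord <- order(scanned_t)
    scanned_t <- scanned_t[ord]
    scanned_v <- scanned_v[ord]
  }
  i <- which.min(scanned_v)
  structure(
    list(
      log_b10 = scanned_v[i],
      t_star = scanned_t[i],
      curve = tibble::tibble(t = scanned_t, log_b10 = scanned_v),
      m = m,
      n_classes = nrow(y),
      M = as.integer(M),
      seed = as.integer(seed),
      method = method
    ),
    class = "bayes_factor_result"
  )
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf(
    "<bayes_factor_result> log B10 = %.3f at t* = %d (m = %d, method = %s)\n",
    x$log_b10, x$t_star, x$m, x$method
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-t evidence curve of a Bayes factor result
#'
#' @param x A `bayes_factor_result`.
#' @param ... Unused.
#' @return Tibble with columns `t`, `log_b10`, `minimum` (logical).
#' @export
tidy.bayes_factor_result <- function(x, ...) {
  dplyr::mutate(x$curve, minimum = .data$t == x$t_star)
}

#' One-row summary of a Bayes factor result
#'
#' @param x A `bayes_factor_result`.
#' @param ... Unused.
#' @return One-row tibble: `log_b10`, `t_star`, `m`, `n_classes`, `method`,
#'   `M`, `seed`.
#' @export
glance.bayes_factor_result <- function(x, ...) {
  tibble::tibble(
    log_b10 = x$log_b10, t_star = x$t_star, m = x$m,
    n_classes = x$n_classes, method = x$method, M = x$M, seed = x$seed
  )
}

#' Plot the per-t evidence curve
#'
#' @param object A `bayes_factor_result`.
#' @param ... Unused.
#' @return A ggplot object of `log B10(y, t)` against `t`, the reported
#'   minimum marked.
#' @export
autoplot.bayes_factor_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$t, y = .data$log_b10)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = object$curve[object$curve$t == object$t_star, ],
      colour = "red", size = 2
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "intrinsic training size t", y = "log B10(y, t)")
}

#' Posterior odds of dependence
#'
#' Updates prior odds `P(H1)/P(H0)` by the Bayes factor:
#' `posterior odds = prior odds * B10`.
#'
#' @param result A `bayes_factor_result` (or a bare log Bayes factor).
#' @param prior_odds Positive prior odds of H1 against H0 (default 1).
#' @return Object of class `hypothesis_odds`: list with `prior_odds`,
#'   `log_b10`, `posterior_odds`.
#' @export
posterior_odds <- function(result, prior_odds = 1) {
  if (prior_odds <= 0) stop("prior_odds must be > 0")
  lb <- if (inherits(result, "bayes_factor_result")) result$log_b10 else as.numeric(result)
  structure(
    list(prior_odds = prior_odds, log_b10 = lb,
         posterior_odds = prior_odds * exp(lb)),
    class = "hypothesis_odds"
  )
}

#' @export
print.hypothesis_odds <- function(x, ...) {
  cat(sprintf("<hypothesis_odds> prior %.3g -> posterior %.4g (log B10 = %.3f)\n",
              x$prior_odds, x$posterior_odds, x$log_b10))
  invisible(x)
}
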