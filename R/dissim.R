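#' Correlation distance between two vectors
#'
#' `d(a, b) = 1 - r(a, b)` with `r` the Pearson correlation coefficient;
#' bounded in \[0, 2\], zero iff the vectors are perfectly positively
#' correlated. Not a metric (no triangle inequality), which the
#' dissimilarity representation explicitly tolerates.
#'
#' @param a,b Numeric vectors of equal length >= 2, neither constant.
#' @return A single non-negative number.
#' @export
correlation_distance <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need vectors of length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation distance undefined for constant vectors")
  }
  1 - stats::cor(a, b)
}

#' Euclidean distance between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return `||a - b||_2`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  sqrt(sum((a - b)^2))
}

# Resolve a distance specification to list(name, fun). Accepts "correlation",
# "euclidean", or a symmetric function(a, b) -> scalar.
resolve_distance <- function(distance) {
  if (is.function(distance)) {
    return(list(name = "custom", fun = distance))
  }
  distance <- match.arg(distance, c("euclidean", "correlation"))
  fun <- switch(distance,
    euclidean = euclidean_distance,
    correlation = correlation_distance
  )
  list(name = distance, fun = fun)
}

# Cross-distance matrix between rows of x and rows of y (vectorized for the
# two built-in distances, rowwise loop otherwise).
dist_cross <- function(x, y, distance) {
  d <- resolve_distance(distance)
  if (d$name == "euclidean") {
    x2 <- rowSums(x^2)
    y2 <- rowSums(y^2)
    sq <- outer(x2, y2, "+") - 2 * tcrossprod(x, y)
    return(sqrt(pmax(sq, 0)))
  }
  if (d$name == "correlation") {
    return(1 - stats::cor(t(x), t(y)))
  }
  out <- matrix(0, nrow(x), nrow(y))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(y))) out[i, j] <- d$fun(x[i, ], y[j, ])
  }
  out
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Farthest-first-traversal prototype selection
#'
#' Selects `p` prototype objects from the rows of `x`. The first prototype
#' is drawn uniformly at random (seeded); each further prototype is the
#' not-yet-selected object maximizing the aggregated distance to all
#' previously selected prototypes. The default aggregation is the *sum* of
#' distances; `criterion = "maxmin"` switches to the classical
#' farthest-first rule (maximize the minimum distance). Ties are broken by
#' the lowest row index, so selection is deterministic given (data order,
#' seed).
#'
#' @param x Numeric matrix, one object per row.
#' @param p Number of prototypes, `1 <= p <= nrow(x)`.
#' @param distance `"euclidean"`, `"correlation"`, or a function.
#' @param seed Integer seed for the initial draw.
#' @param criterion `"sum"` (default) or `"maxmin"`.
#' @param first Optional row index of the first prototype, overriding the
#'   random draw (useful for worked examples and audits).
#' @return Object of class `prototype_set`: list with `indices` (row indices
#'   of `x` in selection order), `prototypes` (their rows), `distance`,
#'   `criterion`, `seed`, `p`.
#' @export
fft_select <- function(x, p, distance = "euclidean", seed = 1L,
                       criterion = c("sum", "maxmin"), first = NULL) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) stop("empty dataset")
  if (p < 1 || p > n) stop("p must lie in 1..nrow(x)")
  dname <- resolve_distance(distance)$name
  if (is.null(first)) {
    first <- with_seed(seed, sample.int(n, 1))
  } else {
    first <- as.integer(first)
    if (first < 1 || first > n) stop("first must index a row of x")
  }
  selected <- first
  if (p > 1) {
    # distances from every object to each selected prototype, grown columnwise
    dmat <- dist_cross(x, x[first, , drop = FALSE], distance)
    for (step in 2:p) {
      score <- if (criterion == "sum") rowSums(dmat) else apply(dmat, 1, min)
      score[selected] <- -Inf
      nxt <- which.max(score) # which.max returns the first (lowest) index on ties
      selected <- c(selected, nxt)
      if (step < p) {
        dmat <- cbind(dmat, dist_cross(x, x[nxt, , drop = FALSE], distance))
      }
    }
  }
  structure(
    list(
      indices = selected,
      prototypes = x[selected, , drop = FALSE],
      distance = if (is.function(distance)) distance else dname,
      criterion = criterion,
      seed = as.integer(seed),
      p = as.integer(p)
    ),
    class = "prototype_set"
  )
}

#' @export
print.prototype_set <- function(x, ...) {
  dn <- if (is.function(x$distance)) "custom" else x$distance
  cat(sprintf("<prototype_set> p=%d, distance=%s, criterion=%s, seed=%d\n",
              x$p, dn, x$criterion, x$seed))
  invisible(x)
}

#' Dissimilarity projection
#'
#' Maps each object (row of `x`) to its vector of distances from the
#' prototypes: component i of the projection of X is `d(X, prototype_i)`.
#' The output dimension equals the number of prototypes for every input.
#'
#' @param x Numeric matrix of objects (rows), same native space as the
#'   prototypes.
#' @param prototypes A [fft_select()] `prototype_set` (or any list with
#'   `prototypes` and `distance`).
#' @return Numeric matrix, `nrow(x)` by `p`.
#' @export
project <- function(x, prototypes) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(prototypes$prototypes)) {
    stop("object dimension does not match prototype dimension")
  }
  out <- dist_cross(x, prototypes$prototypes, prototypes$distance)
  colnames(out) <- paste0("proto", seq_len(ncol(out)))
  out
}

#' Distance between two objects in the projected space
#'
#' The Euclidean distance between the dissimilarity projections of two
#' objects. A true metric on the projected vectors even when the native
#' distance is not.
#'
#' @param a,b Numeric vectors (single objects in native space).
#' @param prototypes A `prototype_set`.
#' @return A single non-negative number.
#' @export
projected_distance <- function(a, b, prototypes) {
  pa <- project(matrix(a, nrow = 1), prototypes)
  pb <- project(matrix(b, nrow = 1), prototypes)
  euclidean_distance(as.numeric(pa), as.numeric(pb))
}

#' Quality of a dissimilarity projection
#'
#' Pearson correlation `r` between the native distances `d(X, X')` and the
#' projected Euclidean distances over object pairs. Values near 1 mean the
#' projection preserves the relative distances well.
#'
#' @param x Numeric matrix of objects (>= 3 rows).
#' @param prototypes A `prototype_set`.
#' @param max_pairs Cap on the number of pairs; beyond it a seeded uniform
#'   subsample of pairs is used.
#' @param seed Seed for the pair subsample (only used past the cap).
#' @return Object of class `projection_quality`: list with `r` and
#'   `n_pairs`.
#' @export
projection_quality <- function(x, prototypes, max_pairs = 50000L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 objects (3 pairs) to measure quality")
  pairs <- utils::combn(n, 2)
  if (ncol(pairs) > max_pairs) {
    keep <- with_seed(seed, sample.int(ncol(pairs), max_pairs))
    pairs <- pairs[, keep, drop = FALSE]
  }
  dn <- dist_cross(x, x, prototypes$distance)
  proj <- project(x, prototypes)
  dp <- dist_cross(proj, proj, "euclidean")
  dvec <- dn[cbind(pairs[1, ], pairs[2, ])]
  pvec <- dp[cbind(pairs[1, ], pairs[2, ])]
  if (stats::sd(dvec) == 0 || stats::sd(pvec) == 0) {
    stop("distance set is constant over the sampled pairs; r undefined")
  }
  structure(
    list(r = stats::cor(dvec, pvec), n_pairs = ncol(pairs)),
    class = "projection_quality"
  )
}

#' @export
print.projection_quality <- function(x, ...) {
  cat(sprintf("<projection_quality> r=%.4f over %d pairs\n", x$r, x$n_pairs))
  invisible(x)
}

#' Choose the number of prototypes from a quality curve
#'
#' Evaluates the projection quality `r` at each candidate prototype count
#' and returns the smallest count reaching `threshold`; if none does, the
#' count maximizing `r`. The full (p, r) curve is kept for inspection.
#'
#' @param x Numeric matrix of objects.
#' @param distance Distance specification as in [fft_select()].
#' @param p_grid Increasing candidate prototype counts, max <= `nrow(x)`.
#' @param threshold Minimum acceptable `r` (default 0.85).
#' @param seed Seed passed to [fft_select()] and to the pair subsample.
#' @param criterion FFT criterion, see [fft_select()].
#' @return Object of class `prototype_selection`: list with `p` (chosen
#'   count) and `curve` (tibble with columns `p`, `r`).
#' @export
select_num_prototypes <- function(x, distance = "euclidean", p_grid = c(5, 10, 20, 40),
                                  threshold = 0.85, seed = 1L,
                                  criterion = c("sum", "maxmin")) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  if (length(p_grid) == 0) stop("empty prototype grid")
  if (is.unsorted(p_grid)) stop("p_grid must be sorted ascending")
  if (max(p_grid) > nrow(x)) stop("largest p exceeds the dataset size")
  rs <- vapply(p_grid, function(p) {
    ps <- fft_select(x, p, distance = distance, seed = seed, criterion = criterion)
    projection_quality(x, ps, seed = seed)$r
  }, numeric(1))
  hit <- which(rs >= threshold)
  p_chosen <- if (length(hit) > 0) p_grid[hit[1]] else p_grid[which.max(rs)]
  structure(
    list(p = as.integer(p_chosen), curve = tibble::tibble(p = as.integer(p_grid), r = rs)),
    class = "prototype_selection"
  )
}

#' @export
print.prototype_selection <- function(x, ...) {
  cat(sprintf("<prototype_selection> p=%d\n", x$p))
  print(x$curve)
  invisible(x)
}

#' Plot a prototype-count quality curve
#'
#' @param object A [select_num_prototypes()] result.
#' @param ... Unused.
#' @return A ggplot object: `r` against the candidate prototype count.
#' @export
autoplot.prototype_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$p, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$p, linetype = "dashed") +
    ggplot2::labs(x = "number of prototypes", y = "distance correlation r")
}

#' Persist a projected dataset with its provenance
#'
#' Writes the projected matrix as TSV (rows = recordings) and a JSON sidecar
#' recording the prototype indices, distance, criterion and seed, so a
#' projection can be audited and replayed.
#'
#' @param proj Projected matrix from [project()].
#' @param prototypes The `prototype_set` that produced it.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_projection <- function(proj, prototypes, path) {
  utils::write.table(proj, path, sep = "\t", quote = FALSE, col.names = NA)
  meta <- list(
    prototype_indices = prototypes$indices,
    distance = if (is.function(prototypes$distance)) "custom" else prototypes$distance,
    criterion = prototypes$criterion,
    seed = prototypes$seed,
    p = prototypes$p
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
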