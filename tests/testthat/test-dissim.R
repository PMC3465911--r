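test_that("correlation distance matches the explicit Pearson formula", {
  expect_equal(correlation_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(correlation_distance(c(1, 2, 3), c(3, 2, 1)), 2)
  a <- c(1, 2, 3)
  b <- c(1, 2, 4)
  r <- mean((a - mean(a)) * (b - mean(b))) /
    (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  expect_equal(correlation_distance(a, b), 1 - r, tolerance = 1e-12)
  expect_error(correlation_distance(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(correlation_distance(1:3, 1:4), "length mismatch")
})

test_that("euclidean distance matches a loop oracle", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(5)
  a <- rnorm(17)
  b <- rnorm(17)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(euclidean_distance(a, b), sqrt(acc), tolerance = 1e-12)
})

test_that("fft_select follows the summed-distance rule with lowest-index ties", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  ps <- fft_select(x, 3, first = 1)
  expect_equal(ps$indices, c(1, 3, 2)) # 0 -> 10 (sum 10 > 1) -> 1
  x2 <- matrix(c(0, 4, 5, 10), ncol = 1)
  ps2 <- fft_select(x2, 2, first = 3) # from 5: d = 5, 1, 0, 5 -> tie 0 vs 10
  expect_equal(ps2$indices[2], 1) # lowest dataset index wins
})

test_that("fft_select equals a brute-force argmax oracle for both criteria", {
  set.seed(21)
  x <- matrix(rnorm(24), ncol = 2)
  dmat <- as.matrix(dist(x))
  for (crit in c("sum", "maxmin")) {
    ps <- fft_select(x, 5, seed = 9, criterion = crit)
    sel <- ps$indices[1]
    for (step in 2:5) {
      agg <- if (crit == "sum") {
        rowSums(dmat[, sel, drop = FALSE])
      } else {
        apply(dmat[, sel, drop = FALSE], 1, min)
      }
      agg[sel] <- -Inf
      sel <- c(sel, which.max(agg))
    }
    expect_equal(ps$indices, unname(sel))
  }
  # reproducibility and argument checks
  expect_identical(fft_select(x, 4, seed = 3)$indices,
                   fft_select(x, 4, seed = 3)$indices)
  expect_error(fft_select(x, 13), "p must lie")
  expect_error(fft_select(x[0, , drop = FALSE], 1), "empty")
})

test_that("projection maps an object to its prototype distances", {
  x <- matrix(c(0, 10), ncol = 1)
  ps <- fft_select(x, 2, first = 1)
  expect_equal(as.numeric(project(matrix(4), ps)), c(4, 6))
  # first component vanishes on the first prototype itself
  expect_equal(unname(project(x, ps)[1, 1]), 0)
  ps1 <- fft_select(x, 1, first = 2)
  expect_equal(dim(project(matrix(c(1, 2, 3)), ps1)), c(3, 1))
  expect_equal(projected_distance(4, 7, ps), sqrt(18))
  expect_equal(projected_distance(4, 4, ps), 0)
  # definitional identity against euclidean_distance on the projections
  set.seed(2)
  xs <- matrix(rnorm(10), ncol = 2)
  ps2 <- fft_select(xs, 3, seed = 1)
  expect_equal(
    projected_distance(xs[1, ], xs[2, ], ps2),
    euclidean_distance(project(xs[1, , drop = FALSE], ps2),
                       project(xs[2, , drop = FALSE], ps2))
  )
})

test_that("projection quality is 1 on the collinear construction and matches a loop oracle", {
  x <- matrix(0:4, ncol = 1)
  ps <- fft_select(x, 1, first = 1) # prototype 0: projection is isometric
  q <- projection_quality(x, ps)
  expect_equal(q$r, 1, tolerance = 1e-12)
  expect_equal(q$n_pairs, 10)
  # the second FFT prototype is the far endpoint; both coordinates are then
  # affine in x, so the projection stays a (scaled) isometry and r stays 1
  expect_equal(projection_quality(x, fft_select(x, 2, first = 1))$r, 1,
               tolerance = 1e-12)
  # interior prototypes bend the embedding: r may dip but stays high
  for (p in 3:4) {
    expect_gte(projection_quality(x, fft_select(x, p, first = 1))$r, 0.98)
  }
  expect_error(projection_quality(x[1:2, , drop = FALSE], ps), "at least 3")
  set.seed(31)
  xs <- matrix(rnorm(20), ncol = 2)
  ps2 <- fft_select(xs, 2, seed = 4)
  proj <- project(xs, ps2)
  dn <- c()
  dp <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    dn <- c(dn, sqrt(sum((xs[i, ] - xs[j, ])^2)))
    dp <- c(dp, sqrt(sum((proj[i, ] - proj[j, ])^2)))
  }
  expect_equal(projection_quality(xs, ps2)$r, cor(dn, dp), tolerance = 1e-12)
})

test_that("select_num_prototypes picks the smallest passing count with argmax fallback", {
  x <- matrix(0:9, ncol = 1)
  sel <- select_num_prototypes(x, p_grid = c(1, 2, 4), seed = 1)
  expect_equal(sel$p, 1) # collinear: r = 1 already at p = 1
  sel2 <- select_num_prototypes(x, p_grid = c(1, 2, 4), threshold = 1.01, seed = 1)
  expect_equal(sel2$p, sel2$curve$p[which.max(sel2$curve$r)])
  set.seed(77)
  xs <- matrix(rnorm(100), ncol = 2)
  grid <- c(5, 10, 20, 40)
  sel3 <- select_num_prototypes(xs, p_grid = grid, seed = 6)
  rs <- vapply(grid, function(p) {
    projection_quality(xs, fft_select(xs, p, seed = 6), seed = 6)$r
  }, numeric(1))
  hit <- which(rs >= 0.85)
  expect_equal(sel3$p, if (length(hit)) grid[hit[1]] else grid[which.max(rs)])
  expect_equal(sel3$curve$r, rs, tolerance = 1e-12)
  expect_error(select_num_prototypes(xs, p_grid = integer(0)), "empty")
})

test_that("projections persist with a replayable JSON sidecar", {
  set.seed(8)
  xs <- matrix(rnorm(20), ncol = 2)
  ps <- fft_select(xs, 3, seed = 5)
  proj <- project(xs, ps)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_projection(proj, ps, path)
  back <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1))
  expect_equal(unname(back), unname(proj), tolerance = 1e-8)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$prototype_indices, ps$indices)
  expect_equal(meta$seed, 5)
})
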