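test_that("linear initialization is deterministic and spans the leading principal plane", {
  set.seed(1)
  # data stretched along two known orthogonal directions
  n <- 200
  scores <- cbind(rnorm(n, sd = 4), rnorm(n, sd = 1))
  B <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  X <- scores %*% B + matrix(rnorm(4 * n, sd = 0.01), n)

  g1 <- initialize_map(X, 4, 4, method = "linear")
  g2 <- initialize_map(X, 4, 4, method = "linear")
  expect_identical(g1$prototypes, g2$prototypes)

  # corner prototypes are ordered along the dominant eigendirections
  eg <- eigen(cov(X), symmetric = TRUE)   # independent eigen oracle
  e1 <- eg$vectors[, 1L]
  proj <- as.vector(g1$prototypes %*% e1)
  by_row <- matrix(proj, nrow = 4, byrow = TRUE)
  # scores along e1 vary across lattice rows, monotonically
  row_means <- rowMeans(by_row)
  expect_true(all(diff(row_means) > 0) || all(diff(row_means) < 0))
  expect_gt(diff(range(proj)), 2 * sqrt(eg$values[1L]) * 0.9)
})

test_that("random initialization stays in the data range; constant data falls back", {
  X <- matrix(runif(60), 20, 3)
  g <- initialize_map(X, 4, 4, method = "random", seed = 5)
  for (j in 1:3) {
    expect_true(all(g$prototypes[, j] >= min(X[, j]) - 1e-12))
    expect_true(all(g$prototypes[, j] <= max(X[, j]) + 1e-12))
  }
  Xc <- matrix(1, 10, 3)
  expect_warning(gc_ <- initialize_map(Xc, 2, 2, method = "linear", seed = 1),
                 "degenerate")
  expect_true(all(gc_$prototypes == 1))
})

test_that("best-matching unit agrees with exhaustive search and breaks ties low", {
  set.seed(2)
  X <- matrix(runif(100 * 6), 100, 6)
  g <- initialize_map(X, 4, 4, method = "random", seed = 3)
  for (i in sample(100, 20)) {
    o <- oracle_bmu(g$prototypes, X[i, ])
    b <- find_bmu(g, X[i, ])
    expect_equal(b$unit, o$unit)
    expect_equal(b$distance, o$distance, tolerance = 1e-12)
  }
  # exact prototype match
  b <- find_bmu(g, g$prototypes[5, ])
  expect_equal(b$unit, 5L)
  expect_equal(b$distance, 0)
  # all units equidistant -> lowest index
  ge <- g
  ge$prototypes <- matrix(0, 16, 6)
  expect_equal(find_bmu(ge, rep(1, 6))$unit, 1L)
  expect_error(find_bmu(g, rep(0, 3)), "mismatch")
})

test_that("batch update limits: single unit gives the data mean, tiny sigma the centroid step", {
  set.seed(3)
  X <- matrix(rnorm(50 * 4), 50, 4)
  g1 <- initialize_map(X, 1, 2, method = "random", seed = 1)
  g1$prototypes <- g1$prototypes[1, , drop = FALSE]
  g1$rows <- 1L; g1$cols <- 1L
  g1$unit_coords <- g1$unit_coords[1, , drop = FALSE]
  res <- train_phase(g1, X, som_phase(1, 1, 1, "rough"))
  expect_equal(as.vector(res$grid$prototypes), colMeans(X), tolerance = 1e-12)

  # sigma -> 0: each occupied unit moves to the centroid of its points
  g <- initialize_map(X, 2, 2, method = "random", seed = 2)
  bmu <- find_bmu(g, X)$unit
  if (length(unique(bmu)) == 4L) {
    res <- train_phase(g, X, som_phase(1, 1e-3, 1e-3, "fine"))
    for (u in 1:4) {
      centroid <- colMeans(X[bmu == u, , drop = FALSE])
      expect_equal(as.vector(res$grid$prototypes[u, ]), centroid,
                   tolerance = 1e-6)
    }
  }
  expect_error(train_phase(g, X[0, , drop = FALSE],
                           som_phase(1, 1, 1, "rough")), "empty")
})

test_that("training runs the full 34-epoch schedule deterministically and refines the map", {
  ad <- sample_archetype_data(150, flip = 0.03, seed = 4)
  f1 <- som_train(ad$X, seed = 4)
  f2 <- som_train(ad$X, seed = 4)
  expect_length(f1$qe_trace, 34L)
  expect_identical(f1$grid$prototypes, f2$grid$prototypes)
  # fine phase never leaves the map worse than the rough phase
  expect_lte(f1$qe_trace[34], f1$qe_trace[7])

  # two well-separated binary archetypes are captured by prototypes
  arch <- rbind(rep(0, 10), rep(1, 10))
  set.seed(5)
  z <- rep(1:2, each = 60)
  Xa <- arch[z, ]
  flip <- matrix(runif(1200) < 0.02, 120)
  Xa[flip] <- 1 - Xa[flip]
  fa <- som_train(Xa, seed = 5)
  d_to_arch <- apply(arch, 1, function(a) {
    min(sqrt(rowSums(sweep(fa$grid$prototypes, 2, a)^2)))
  })
  expect_true(all(d_to_arch < 0.25))
})

test_that("every prototype remains a convex combination of the data", {
  set.seed(6)
  X <- matrix(runif(80 * 5), 80, 5)
  g <- initialize_map(X, 3, 3, method = "random", seed = 6)
  for (ph in som_schedule()) {
    res <- train_phase(g, X, ph)
    g <- res$grid
    # batch weights are Gaussian (non-negative) and normalized to sum 1,
    # so prototypes must lie inside the per-feature data range
    for (j in 1:5) {
      expect_true(all(g$prototypes[, j] >= min(X[, j]) - 1e-9))
      expect_true(all(g$prototypes[, j] <= max(X[, j]) + 1e-9))
    }
  }
})

test_that("a huge constant neighborhood collapses all prototypes to the data mean", {
  set.seed(7)
  X <- matrix(rnorm(60 * 3), 60, 3)
  g <- initialize_map(X, 4, 4, method = "random", seed = 7)
  res <- train_phase(g, X, som_phase(50, 1e5, 1e5, "rough"))
  mu <- colMeans(X)
  expect_true(all(abs(sweep(res$grid$prototypes, 2, mu)) < 1e-6))
})

test_that("quantization and topographic errors match brute-force recomputation", {
  set.seed(8)
  X <- matrix(runif(40 * 4), 40, 4)
  g <- initialize_map(X, 4, 4, method = "random", seed = 8)
  qe_brute <- mean(vapply(seq_len(40), function(i) {
    oracle_bmu(g$prototypes, X[i, ])$distance
  }, 0))
  expect_equal(quantization_error(g, X), qe_brute, tolerance = 1e-12)

  # data equal to prototypes -> zero error
  expect_equal(quantization_error(g, g$prototypes), 0)
  # single unit at the midpoint of two symmetric 1-D points
  gmid <- g
  gmid$prototypes <- matrix(0, 1, 1)
  gmid$rows <- 1L; gmid$cols <- 1L
  gmid$unit_coords <- gmid$unit_coords[1, , drop = FALSE]
  expect_equal(quantization_error(gmid, matrix(c(-1, 1), 2, 1)), 1.0)

  te_brute <- mean(vapply(seq_len(40), function(i) {
    d <- sqrt(rowSums(sweep(g$prototypes, 2, X[i, ])^2))
    ord <- order(d)
    c1 <- g$unit_coords[ord[1], ]; c2 <- g$unit_coords[ord[2], ]
    as.numeric(sqrt(sum((c1 - c2)^2)) != 1)
  }, 0))
  expect_equal(topographic_error(g, X), te_brute)

  # on a 1x2 grid every unit pair is adjacent
  g12 <- initialize_map(X[, 1, drop = FALSE], 1, 2, method = "random", seed = 1)
  expect_equal(topographic_error(g12, X[, 1, drop = FALSE]), 0)
})

test_that("component planes round-trip prototype values with per-feature scaling", {
  ad <- sample_archetype_data(100, seed = 9)
  colnames(ad$X) <- paste0("m", 1:10)
  fit <- som_train(ad$X, seed = 9)
  planes <- component_planes(fit)
  expect_length(planes, 10L)
  for (j in 1:10) {
    expect_equal(as.vector(t(planes[[j]])), fit$grid$prototypes[, j])
    expect_equal(attr(planes[[j]], "range"), range(fit$grid$prototypes[, j]))
  }
  # constant feature -> constant plane; duplicated feature -> identical plane
  Xc <- cbind(ad$X, cst = 0.5, dup = ad$X[, 1])
  fitc <- som_train(Xc, seed = 9)
  pc <- component_planes(fitc)
  expect_true(all(abs(pc$cst - 0.5) < 1e-12))
  expect_equal(pc$dup, pc$m1, tolerance = 1e-12)
})

test_that("trained maps serialize to JSON and back", {
  ad <- sample_archetype_data(60, seed = 10)
  fit <- som_train(ad$X, seed = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_som(fit, f)
  back <- read_som(f)
  expect_equal(back$grid$prototypes, fit$grid$prototypes, tolerance = 1e-12)
  expect_equal(back$qe_trace, fit$qe_trace, tolerance = 1e-12)
  expect_equal(find_bmu(back$grid, ad$X[1, ])$unit,
               find_bmu(fit$grid, ad$X[1, ])$unit)
})
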