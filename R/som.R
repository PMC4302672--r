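#' @title Kohonen self-organizing map: batch training core
#' @name som_core
#' @description
#' A rectangular lattice of prototype vectors ("virtual patients") trained
#' by the batch Kohonen rule: each epoch presents the whole dataset, maps
#' every patient to its best-matching unit (BMU), and replaces each
#' prototype by the Gaussian-neighborhood-weighted mean of the data. Two
#' consecutive phases are used: a rough phase with a wide neighborhood
#' that orders the map globally, then a fine phase with a narrow
#' neighborhood that tunes prototypes locally.
NULL

# row-major lattice coordinates for units 1..rows*cols
.lattice_coords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

# units x units Euclidean lattice distances
.lattice_dist <- function(coords) {
  as.matrix(stats::dist(coords))
}

new_som_grid <- function(prototypes, rows, cols, feature_names) {
  stopifnot(nrow(prototypes) == rows * cols)
  dimnames(prototypes) <- list(NULL, feature_names)
  structure(
    list(rows = rows, cols = cols,
         prototypes = prototypes,
         unit_coords = .lattice_coords(rows, cols)),
    class = "som_grid"
  )
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %dx%d rectangular lattice, %d features\n",
              x$rows, x$cols, ncol(x$prototypes)))
  invisible(x)
}

#' Initialize a self-organizing map
#'
#' `linear` initialization (the default) spans the plane of the two
#' leading principal directions of the data: prototypes are laid out on a
#' regular grid `mean +/- sqrt(lambda_i) * e_i`, which is deterministic
#' (eigenvector signs are fixed so the largest-magnitude loading is
#' positive). `random` initialization samples each prototype coordinate
#' uniformly within the per-feature data range under `seed`.
#'
#' @param X numeric matrix or `feature_matrix` (patients x features).
#' @param rows,cols lattice dimensions; default 4x4.
#' @param method `"linear"` or `"random"`.
#' @param seed RNG seed, used by `method = "random"` only.
#' @return A `som_grid`.
#' @export
initialize_map <- function(X, rows = 4L, cols = 4L,
                           method = c("linear", "random"), seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 data rows")
  if (rows * cols < 2L) stop("need at least 2 map units")
  if (method == "linear") {
    cv <- stats::cov(X)
    if (all(abs(cv) < .Machine$double.eps)) {
      warning("degenerate data (zero variance); falling back to random init")
      method <- "random"
    } else {
      eg <- eigen(cv, symmetric = TRUE)
      fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
      e1 <- fix_sign(eg$vectors[, 1L])
      l1 <- max(eg$values[1L], 0)
      if (ncol(X) >= 2L && eg$values[2L] > 1e-12) {
        e2 <- fix_sign(eg$vectors[, 2L])
        l2 <- eg$values[2L]
      } else {
        e2 <- rep(0, ncol(X)); l2 <- 0
      }
      ctr <- colMeans(X)
      coords <- .lattice_coords(rows, cols)
      u <- if (rows > 1L) 2 * (coords[, "row"] - 1) / (rows - 1) - 1 else
        rep(0, rows * cols)
      v <- if (cols > 1L) 2 * (coords[, "col"] - 1) / (cols - 1) - 1 else
        rep(0, rows * cols)
      P <- matrix(ctr, nrow = rows * cols, ncol = ncol(X), byrow = TRUE) +
        outer(u * sqrt(l1), e1) + outer(v * sqrt(l2), e2)
      return(new_som_grid(P, rows, cols, colnames(X)))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  P <- sapply(seq_len(ncol(X)), function(j) {
    stats::runif(rows * cols, lo[j], hi[j])
  })
  P <- matrix(P, nrow = rows * cols)
  new_som_grid(P, rows, cols, colnames(X))
}

# squared Euclidean distances, data rows x units; no sqrt for argmin use
.cross_dist2 <- function(X, P) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(P))) +
    outer(rep(1, nrow(X)), rowSums(P^2)) - 2 * X %*% t(P)
  pmax(d2, 0)
}

# BMU index for every data row; ties broken toward the lowest unit index
.bmu_all <- function(grid, X) {
  d2 <- .cross_dist2(as.matrix(X), grid$prototypes)
  idx <- max.col(-d2, ties.method = "first")
  list(unit = idx, dist = sqrt(d2[cbind(seq_len(nrow(d2)), idx)]), d2 = d2)
}

#' Best-matching unit
#'
#' Returns the map unit whose prototype is nearest (Euclidean) to `x`,
#' breaking ties toward the lowest unit index.
#'
#' @param grid a `som_grid`.
#' @param x numeric feature vector (or matrix of rows to match).
#' @return For a vector, `list(unit, distance)`; for a matrix, a
#'   data.frame with one row per input row.
#' @export
find_bmu <- function(grid, x) {
  if (is.null(dim(x))) {
    if (length(x) != ncol(grid$prototypes)) {
      stop("dimensionality mismatch: x has ", length(x), " entries, map has ",
           ncol(grid$prototypes), " features")
    }
    b <- .bmu_all(grid, matrix(x, nrow = 1L))
    return(list(unit = b$unit[1L], distance = b$dist[1L]))
  }
  b <- .bmu_all(grid, x)
  data.frame(unit = b$unit, distance = b$dist)
}

#' Training phase descriptor
#'
#' @param n_epochs number of whole-dataset presentations (>= 1).
#' @param sigma_start,sigma_end Gaussian neighborhood radii in lattice
#'   units; sigma decreases linearly from start to end across the phase.
#' @param name phase label, conventionally `"rough"` or `"fine"`.
#' @return A `som_phase` list.
#' @export
som_phase <- function(n_epochs, sigma_start, sigma_end,
                      name = c("rough", "fine")) {
  name <- if (is.character(name)) name[1L] else as.character(name)
  stopifnot(n_epochs >= 1L, sigma_start >= sigma_end, sigma_end > 0)
  structure(list(n_epochs = as.integer(n_epochs),
                 sigma_start = sigma_start, sigma_end = sigma_end,
                 name = name),
            class = "som_phase")
}

#' Default two-phase training schedule
#'
#' Seven rough epochs (sigma 2 -> 1) followed by 27 fine epochs
#' (sigma 1 -> 0.25), i.e. 34 whole-dataset presentations in total.
#'
#' @return List of two `som_phase` objects.
#' @export
som_schedule <- function() {
  list(som_phase(7L, 2, 1, "rough"), som_phase(27L, 1, 0.25, "fine"))
}

#' Run one training phase
#'
#' Batch mode (default): per epoch, all patients are assigned to BMUs and
#' each prototype is replaced by the neighborhood-weighted mean of the
#' data with Gaussian kernel `h(u, c) = exp(-d_lattice(u, c)^2 / (2
#' sigma^2))`. Units receiving negligible total weight keep their current
#' prototype. Online mode (for comparison) applies the sequential Kohonen
#' update per presented patient with a linearly decaying learning rate.
#'
#' @param grid a `som_grid`.
#' @param X data matrix.
#' @param phase a [som_phase()].
#' @param mode `"batch"` (deterministic) or `"online"`.
#' @param alpha_start,alpha_end online-mode learning-rate range.
#' @return List with the updated `grid` and `qe_trace`, the quantization
#'   error after each epoch.
#' @export
train_phase <- function(grid, X, phase, mode = c("batch", "online"),
                        alpha_start = 0.5, alpha_end = 0.05) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty data")
  L2 <- .lattice_dist(grid$unit_coords)^2
  E <- phase$n_epochs
  qe <- numeric(E)
  for (e in seq_len(E)) {
    sigma <- if (E == 1L) phase$sigma_end else
      phase$sigma_start + (phase$sigma_end - phase$sigma_start) * (e - 1) / (E - 1)
    H <- exp(-L2 / (2 * sigma^2))
    if (mode == "batch") {
      bmu <- .bmu_all(grid, X)$unit
      W <- H[, bmu, drop = FALSE]            # units x patients
      denom <- rowSums(W)
      num <- W %*% X
      keep <- denom < 1e-12
      Pnew <- num / ifelse(denom < 1e-12, 1, denom)
      if (any(keep)) Pnew[keep, ] <- grid$prototypes[keep, ]
      dimnames(Pnew) <- dimnames(grid$prototypes)
      grid$prototypes <- Pnew
    } else {
      alpha <- alpha_start + (alpha_end - alpha_start) * (e - 1) / max(1L, E - 1L)
      for (i in seq_len(nrow(X))) {
        b <- .bmu_all(grid, X[i, , drop = FALSE])$unit
        h <- H[, b]
        grid$prototypes <- grid$prototypes +
          alpha * h * (matrix(X[i, ], nrow = nrow(grid$prototypes),
                              ncol = ncol(X), byrow = TRUE) - grid$prototypes)
      }
    }
    qe[e] <- quantization_error(grid, X)
  }
  list(grid = grid, qe_trace = qe)
}

#' Train a self-organizing map
#'
#' Initializes the map and runs the full two-phase schedule.
#'
#' @inheritParams initialize_map
#' @param schedule list of [som_phase()] objects; default [som_schedule()]
#'   (7 rough + 27 fine epochs).
#' @param mode `"batch"` or `"online"`; see [train_phase()].
#' @return A `som_fit`: list with `grid`, `qe_trace` (one entry per
#'   epoch), `topographic_error`, `schedule`, `init`, `seed`.
#' @examples
#' coh <- simulate_cohort(n = 104, seed = 7)
#' fit <- som_train(encode_features(coh), seed = 7)
#' length(fit$qe_trace)  # 34
#' @export
som_train <- function(X, rows = 4L, cols = 4L, schedule = som_schedule(),
                      method = c("linear", "random"), seed = NULL,
                      mode = c("batch", "online")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  X <- as.matrix(X)
  grid <- initialize_map(X, rows, cols, method = method, seed = seed)
  qe <- numeric(0)
  for (ph in schedule) {
    res <- train_phase(grid, X, ph, mode = mode)
    grid <- res$grid
    qe <- c(qe, res$qe_trace)
  }
  structure(
    list(grid = grid, qe_trace = qe,
         topographic_error = topographic_error(grid, X),
         schedule = schedule, init = method, seed = seed),
    class = "som_fit"
  )
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf(paste0("som_fit: %dx%d map, %d features, %d epochs\n",
                     "  final quantization error %.4f, topographic error %.4f\n"),
              x$grid$rows, x$grid$cols, ncol(x$grid$prototypes),
              length(x$qe_trace), utils::tail(x$qe_trace, 1L),
              x$topographic_error))
  invisible(x)
}

#' Quantization error
#'
#' Mean Euclidean distance from each data row to its best-matching unit;
#' zero iff every row coincides with some prototype.
#'
#' @param grid a `som_grid` (or `som_fit`).
#' @param X data matrix.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(grid, X) {
  if (inherits(grid, "som_fit")) grid <- grid$grid
  mean(.bmu_all(grid, as.matrix(X))$dist)
}

#' Topographic error
#'
#' Fraction of data rows whose best and second-best matching units are not
#' direct lattice neighbors (Euclidean lattice distance 1). A measure of
#' how well the map preserves topology; 0 is perfect.
#'
#' @inheritParams quantization_error
#' @return Value in \[0, 1\].
#' @export
topographic_error <- function(grid, X) {
  if (inherits(grid, "som_fit")) grid <- grid$grid
  if (nrow(grid$prototypes) < 2L) stop("need at least 2 units")
  d2 <- .cross_dist2(as.matrix(X), grid$prototypes)
  best <- max.col(-d2, ties.method = "first")
  d2[cbind(seq_len(nrow(d2)), best)] <- Inf
  second <- max.col(-d2, ties.method = "first")
  L <- .lattice_dist(grid$unit_coords)
  mean(abs(L[cbind(best, second)] - 1) > 1e-9)
}

#' Component planes
#'
#' One rows x cols matrix per input feature holding that feature's
#' prototype values across the lattice — the standard visualization of
#' feature-region associations. Per-feature min/max are attached so each
#' plane can be color-scaled independently.
#'
#' @param grid a `som_grid` (or `som_fit`).
#' @return Named list of matrices, each with a `range` attribute
#'   `c(min, max)`.
#' @export
component_planes <- function(grid) {
  if (inherits(grid, "som_fit")) grid <- grid$grid
  feats <- colnames(grid$prototypes)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(grid$prototypes)))
  planes <- lapply(seq_along(feats), function(j) {
    m <- matrix(grid$prototypes[, j], nrow = grid$rows, ncol = grid$cols,
                byrow = TRUE)
    attr(m, "range") <- range(grid$prototypes[, j])
    m
  })
  stats::setNames(planes, feats)
}

#' Serialize a trained map to JSON
#'
#' Writes dimensions, feature names, the prototype matrix, the schedule
#' and the seed as a plain-text JSON document; [read_som()] restores it.
#'
#' @param fit a `som_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_som <- function(fit, path) {
  doc <- list(
    rows = fit$grid$rows, cols = fit$grid$cols,
    feature_names = colnames(fit$grid$prototypes),
    prototypes = unclass(fit$grid$prototypes),
    qe_trace = fit$qe_trace,
    topographic_error = fit$topographic_error,
    schedule = lapply(fit$schedule, unclass),
    init = fit$init, seed = fit$seed
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a trained map written by [write_som()]
#'
#' @param path JSON file produced by [write_som()].
#' @return A `som_fit`.
#' @export
read_som <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- matrix(unlist(doc$prototypes), nrow = doc$rows * doc$cols)
  grid <- new_som_grid(P, doc$rows, doc$cols, doc$feature_names)
  schedule <- lapply(seq_len(nrow(doc$schedule)), function(i) {
    som_phase(doc$schedule$n_epochs[i], doc$schedule$sigma_start[i],
              doc$schedule$sigma_end[i], doc$schedule$name[i])
  })
  structure(list(grid = grid, qe_trace = doc$qe_trace,
                 topographic_error = doc$topographic_error,
                 schedule = schedule, init = doc$init, seed = doc$seed),
            class = "som_fit")
}
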