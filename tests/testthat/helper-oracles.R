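# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# exhaustive nearest-prototype scan
oracle_bmu <- function(P, x) {
  d <- apply(P, 1L, function(p) sqrt(sum((p - x)^2)))
  list(unit = which.min(d), distance = min(d))
}

# naive agglomerative clustering by the Lance-Williams recursion.
# method "ward": start from squared Euclidean distances,
#   d(k, ij) = ((n_i+n_k) d_ki + (n_j+n_k) d_kj - n_k d_ij) / (n_i+n_j+n_k)
# method "average": start from `metric` distances,
#   d(k, ij) = (n_i d_ki + n_j d_kj) / (n_i + n_j)
# Returns merge heights and the member sets after each merge.
oracle_lance_williams <- function(X, method = c("ward", "average"),
                                  metric = "euclidean") {
  method <- match.arg(method)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X, method = metric))
  if (method == "ward") D <- D^2
  diag(D) <- Inf
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  partitions <- list()
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(Inf, NA, NA)
    for (a in idx) for (b in idx) {
      if (a < b && D[a, b] < best[1L]) best <- c(D[a, b], a, b)
    }
    i <- best[2L]; j <- best[3L]
    heights <- c(heights, best[1L])
    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- if (method == "ward") {
        ((sizes[i] + sizes[k]) * D[k, i] + (sizes[j] + sizes[k]) * D[k, j] -
           sizes[k] * D[i, j]) / (sizes[i] + sizes[j] + sizes[k])
      } else {
        (sizes[i] * D[k, i] + sizes[j] * D[k, j]) / (sizes[i] + sizes[j])
      }
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    D[j, ] <- D[, j] <- Inf
    partitions[[length(partitions) + 1L]] <-
      lapply(which(active), function(a) sort(members[[a]]))
  }
  list(heights = heights, partitions = partitions)
}

# partition of 1..n after each hclust merge, as sorted member sets
hclust_partitions <- function(hc, n) {
  lapply(seq_len(n - 1L), function(k) {
    cl <- stats::cutree(hc, k = n - k)
    unname(lapply(split(seq_len(n), cl), sort))
  })
}

# set-of-sets equality ignoring order
same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, function(s) paste(s, collapse = ","), ""))
  identical(key(a), key(b))
}

# hand product-limit estimator by direct counting
oracle_km <- function(times, events) {
  tt <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(times >= tt[i])
    d <- sum(times == tt[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = tt, survival = surv)
}

# two-group log-rank by the hypergeometric observed-minus-expected sum
oracle_logrank2 <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  tt <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in tt) {
    at1 <- sum(times >= t & g == 1L)
    at2 <- sum(times >= t & g == 2L)
    d1 <- sum(times == t & events == 1 & g == 1L)
    d <- sum(times == t & events == 1)
    N <- at1 + at2
    O <- O + d1
    E <- E + d * at1 / N
    if (N > 1) V <- V + d * (at1 / N) * (at2 / N) * (N - d) / (N - 1)
  }
  (O - E)^2 / V
}

# exact permutation p for a binary variable over 2 equal groups of 4:
# enumerate all placements of the group-1 members
oracle_exact_perm_p <- function(presence, labels) {
  n <- length(presence)
  g1 <- sum(labels == sort(unique(labels))[1L])
  chi <- function(lab) {
    counts <- rbind(
      c(sum(presence[lab] == 1), sum(presence[lab] == 0)),
      c(sum(presence[-lab] == 1), sum(presence[-lab] == 0)))
    e <- outer(rowSums(counts), colSums(counts)) / n
    ok <- e > 0
    sum((counts[ok] - e[ok])^2 / e[ok])
  }
  obs <- chi(which(labels == sort(unique(labels))[1L]))
  combos <- utils::combn(n, g1)
  stats <- apply(combos, 2L, chi)
  mean(stats >= obs - 1e-12)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# four binary archetype profiles with pairwise Hamming distance >= 6 of 10
separated_archetypes <- function() {
  rbind(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
        c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0),
        c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
        c(1, 1, 1, 1, 0, 0, 1, 1, 1, 1))
}

# sample a planted-archetype binary matrix with given flip noise
sample_archetype_data <- function(n, flip = 0.05, seed = 1) {
  set.seed(seed)
  A <- separated_archetypes()
  z <- sample(seq_len(nrow(A)), n, replace = TRUE)
  X <- A[z, , drop = FALSE]
  fl <- matrix(stats::runif(length(X)) < flip, nrow(X))
  X[fl] <- 1 - X[fl]
  list(X = X, z = z)
}
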