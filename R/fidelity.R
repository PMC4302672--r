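#' Phi fidelity coefficient
#'
#' Association between membership of one target group and presence of a
#' binary feature, the coefficient used in fidelity analysis of group
#' diagnostics: `phi = (n * n_p - n_t * N_p) / sqrt(n_t * N_p * (n - n_t)
#' * (n - N_p))` where `n` is the total count, `n_t` the target-group
#' size, `N_p` the overall number of presences and `n_p` the presences in
#' the target group. Equals the Pearson correlation of the two binary
#' indicators.
#'
#' With `equalize = TRUE` the observed within-group frequencies are first
#' re-expressed on hypothetical equal group sizes `n / k`, removing the
#' influence of unequal group sizes.
#'
#' @param presence binary 0/1 vector.
#' @param labels group labels, same length.
#' @param target the group whose fidelity is measured.
#' @param equalize equalize group sizes before computing phi.
#' @return phi in \[-1, 1\], or `NA` (with a warning) when a margin is
#'   degenerate (feature always or never present).
#' @examples
#' phi_fidelity(c(1, 1, 0, 0), c("a", "a", "b", "b"), "a")  # 1
#' @export
phi_fidelity <- function(presence, labels, target, equalize = FALSE) {
  stopifnot(length(presence) == length(labels))
  if (!all(presence %in% c(0, 1))) stop("presence must be 0/1")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 groups")
  if (!target %in% labels) stop("target group not found: ", target)
  n <- length(presence)
  if (equalize) {
    groups <- sort(unique(labels))
    k <- length(groups)
    freq <- vapply(groups, function(g) mean(presence[labels == g]), 0)
    n_t <- n / k
    n_p <- freq[[target]] * n_t
    N_p <- sum(freq) * n_t
  } else {
    n_t <- sum(labels == target)
    N_p <- sum(presence)
    n_p <- sum(presence[labels == target])
  }
  denom2 <- n_t * N_p * (n - n_t) * (n - N_p)
  if (denom2 <= 0) {
    warning("degenerate margin: phi undefined")
    return(NA_real_)
  }
  (n * n_p - n_t * N_p) / sqrt(denom2)
}

# chi-square statistic of a groups x levels contingency table given as a
# counts matrix (rows = groups); returns 0 for degenerate margins
.table_chisq <- function(counts) {
  n <- sum(counts)
  e <- outer(rowSums(counts), colSums(counts)) / n
  ok <- e > 0
  sum((counts[ok] - e[ok])^2 / e[ok])
}

#' Monte Carlo randomization test for group differences in a binary (or
#' categorical) variable
#'
#' The omnibus statistic is the Pearson chi-square of the groups x levels
#' contingency table; its null distribution is generated by randomly
#' permuting group labels. The p-value uses the add-one estimator
#' `p = (1 + #permuted >= observed) / (1 + n_permutations)`, which never
#' returns 0. For binary variables the per-group phi fidelity coefficient
#' is reported with its own one-sided permutation p (how often a permuted
#' phi reaches the observed one), supporting "significantly highest in
#' subcluster S" annotations.
#'
#' @inheritParams phi_fidelity
#' @param presence binary 0/1 vector, or a factor/character vector with
#'   >= 2 levels.
#' @param n_permutations number of label permutations (>= 999).
#' @param seed RNG seed for the permutations.
#' @param equalize passed to [phi_fidelity()].
#' @return A `fidelity_result`: list with the observed contingency
#'   `table` (groups x levels), `statistic`, `p_value`, per-group `phi`
#'   and `phi_p` (binary variables only), `n_permutations`, `seed`.
#' @examples
#' r <- mc_randomization_test(rep(c(1, 0), c(4, 4)),
#'                            rep(c("a", "b"), each = 4),
#'                            n_permutations = 999, seed = 1)
#' r$p_value
#' @export
mc_randomization_test <- function(presence, labels, n_permutations = 9999L,
                                  seed = NULL, equalize = FALSE) {
  if (n_permutations < 999L) stop("n_permutations must be >= 999")
  labels <- as.character(labels)
  stopifnot(length(presence) == length(labels))
  groups <- sort(unique(labels))
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  gi <- match(labels, groups)
  n <- length(presence)

  binary <- all(presence %in% c(0, 1))
  fl <- if (binary) factor(presence, levels = c(1, 0)) else factor(presence)
  lv <- levels(fl)
  li <- as.integer(fl)
  counts <- matrix(0L, nrow = k, ncol = length(lv),
                   dimnames = list(groups, if (binary) c("present", "absent")
                                   else lv))
  for (j in seq_along(lv)) {
    counts[, j] <- tabulate(gi[li == j], nbins = k)
  }

  degenerate <- any(colSums(counts) %in% c(0L, n))
  obs <- .table_chisq(counts)

  phi <- phi_p <- NULL
  if (binary) {
    phi <- vapply(groups, function(g) {
      if (degenerate) NA_real_ else
        phi_fidelity(presence, labels, g, equalize = equalize)
    }, 0)
  }

  if (degenerate) {
    warning("degenerate margins: variable constant across cohort; p = 1")
    return(structure(list(table = counts, statistic = obs, p_value = 1,
                          phi = phi, phi_p = NULL,
                          n_permutations = as.integer(n_permutations),
                          seed = seed),
                     class = "fidelity_result"))
  }

  if (!is.null(seed)) set.seed(seed)
  sizes <- tabulate(gi, nbins = k)
  n_ge <- 0L
  phi_obs <- phi
  phi_ge <- if (binary) integer(k) else NULL
  pres01 <- if (binary) as.integer(presence == 1) else NULL
  N_p <- if (binary) sum(pres01) else NULL
  tol <- 1e-12
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    cperm <- matrix(0L, nrow = k, ncol = length(lv))
    lp <- li[perm]
    for (j in seq_along(lv)) cperm[, j] <- tabulate(gi[lp == j], nbins = k)
    if (.table_chisq(cperm) >= obs - tol) n_ge <- n_ge + 1L
    if (binary) {
      # phi per group from permuted presence counts; margins are fixed
      n_p <- cperm[, 1L]
      ph <- (n * n_p - sizes * N_p) /
        sqrt(sizes * N_p * (n - sizes) * (n - N_p))
      phi_ge <- phi_ge + as.integer(ph >= phi_obs - tol)
    }
  }
  if (binary) {
    phi_p <- stats::setNames((1 + phi_ge) / (1 + n_permutations), groups)
  }
  structure(list(table = counts, statistic = obs,
                 p_value = (1 + n_ge) / (1 + n_permutations),
                 phi = phi, phi_p = phi_p,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "fidelity_result")
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat(sprintf("Monte Carlo randomization test: chi-square = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  print(x$table)
  if (!is.null(x$phi)) {
    cat("phi fidelity per group:\n")
    print(round(x$phi, 3))
  }
  invisible(x)
}

#' Expand a printed contingency table into observation vectors
#'
#' Convenience for re-analysing published group x presence tables: given
#' per-group presence counts and group sizes, reconstructs the
#' patient-level `presence` and `labels` vectors (their order is
#' irrelevant to any permutation statistic).
#'
#' @param present per-group counts of feature presence.
#' @param sizes per-group totals, same length.
#' @param groups group names; defaults to `names(present)` or G1, G2, ...
#' @return `list(presence, labels)`.
#' @examples
#' tab <- expand_binary_table(c(1, 1, 9, 28), c(24, 28, 24, 28))
#' table(tab$labels, tab$presence)
#' @export
expand_binary_table <- function(present, sizes, groups = NULL) {
  stopifnot(length(present) == length(sizes), all(present <= sizes))
  if (is.null(groups)) {
    groups <- names(present)
    if (is.null(groups)) groups <- paste0("G", seq_along(present))
  }
  presence <- unlist(lapply(seq_along(sizes), function(i) {
    rep(c(1L, 0L), c(present[i], sizes[i] - present[i]))
  }))
  labels <- rep(groups, sizes)
  list(presence = presence, labels = labels)
}
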