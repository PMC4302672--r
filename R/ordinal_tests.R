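#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected mid-rank Kruskal-Wallis H with a chi-square reference
#' distribution on groups - 1 degrees of freedom (thin wrapper around
#' [stats::kruskal.test()] returning the pieces downstream reports need).
#'
#' @param values numeric/ordinal observations.
#' @param labels group labels.
#' @return List with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, labels) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  groups <- unique(labels)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p_value = 1,
                n = length(values)))
  }
  kt <- stats::kruskal.test(values, factor(labels))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(values))
}

#' Dunn post hoc test
#'
#' Pairwise mean-rank comparisons following a Kruskal-Wallis test, with
#' the tie-corrected pooled variance
#' `V = (N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)` where
#' `T = sum(t^3 - t)` over tied value groups. Two-sided p-values from the
#' normal reference, optionally Bonferroni-adjusted across the pairs.
#'
#' @inheritParams kruskal_wallis
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, labels, adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  groups <- sort(unique(labels))
  sizes <- vapply(groups, function(g) sum(labels == g), 0L)
  if (any(sizes == 0L)) {
    warning("excluding empty group(s)")
    groups <- groups[sizes > 0L]
  }
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  N <- length(values)
  r <- rank(values)
  mean_rank <- vapply(groups, function(g) mean(r[labels == g]), 0)
  n_g <- vapply(groups, function(g) sum(labels == g), 0L)
  ties <- table(values)
  T_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2L)
  res <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    v <- unname((N * (N + 1) / 12 - T_corr) * (1 / n_g[i] + 1 / n_g[j]))
    z <- if (v > 0) unname(mean_rank[i] - mean_rank[j]) / sqrt(v) else 0
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(
    group1 = groups[pairs[1L, ]],
    group2 = groups[pairs[2L, ]],
    z = res["z", ],
    p_raw = res["p", ],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$p_adjusted <- if (adjustment == "bonferroni") {
    pmin(1, out$p_raw * nrow(out))
  } else out$p_raw
  out
}

# conventional significance tier for a p-value
.p_label <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "<0.001" else if (p < 0.01) "<0.01" else
    if (p < 0.05) "<0.05" else "ns"
}
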