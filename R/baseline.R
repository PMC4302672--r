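#' Direct hierarchical clustering of patients
#'
#' The comparison arm to the map-based partition: agglomerative
#' clustering of the patient rows themselves, by default with city-block
#' (Manhattan) distance and average (UPGMA) linkage. On 0/1 data the
#' city-block distance between two patients equals their Hamming count of
#' differing markers.
#'
#' @param X encoded `feature_matrix` (or numeric matrix) of patients.
#' @param k number of groups to cut the tree into (default 4, matching
#'   the number of map subclusters).
#' @param metric distance metric for [stats::dist()].
#' @param linkage linkage method for [stats::hclust()].
#' @return A `baseline_partition`: list with the `hclust` record,
#'   per-patient `labels` (`C1`...`Ck`, numbered by decreasing size),
#'   `k`, `metric`, `linkage`.
#' @export
hcluster_patients <- function(X, k = 4L, metric = "manhattan",
                              linkage = "average") {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 patients")
  hc <- stats::hclust(stats::dist(X, method = metric), method = linkage)
  cl <- stats::cutree(hc, k = k)
  size <- tabulate(cl, nbins = k)
  first <- vapply(seq_len(k), function(s) which(cl == s)[1L], 0L)
  ord <- order(-size, first)
  labels <- paste0("C", match(cl, ord))
  names(labels) <- rownames(X)
  structure(list(hclust = hc, labels = labels, k = as.integer(k),
                 metric = metric, linkage = linkage),
            class = "baseline_partition")
}

#' @export
print.baseline_partition <- function(x, ...) {
  cat(sprintf("baseline_partition: %s distance, %s linkage, k = %d\n",
              x$metric, x$linkage, x$k))
  print(table(x$labels))
  invisible(x)
}

#' Head-to-head survival stratification of two partitions
#'
#' Runs the k-group log-rank test on the progression endpoint once per
#' partition and reports the two results side by side. A partition with a
#' single group is reported as not testable rather than raising.
#'
#' @param cohort validated cohort.
#' @param som_labels per-patient labels from the map partition (a
#'   `map_partition` or character vector).
#' @param baseline_labels per-patient labels from the direct clustering
#'   (a `baseline_partition` or character vector).
#' @return data.frame with one row per partition: `partition`,
#'   `n_groups`, `statistic`, `df`, `p_value` (NA when not testable).
#' @export
compare_stratification <- function(cohort, som_labels, baseline_labels) {
  as_labels <- function(x) {
    if (inherits(x, "map_partition")) x$patient_subcluster
    else if (inherits(x, "baseline_partition")) x$labels
    else as.character(x)
  }
  lab <- list(som = as_labels(som_labels),
              baseline = as_labels(baseline_labels))
  rows <- lapply(names(lab), function(nm) {
    l <- lab[[nm]]
    if (length(l) != nrow(cohort)) stop(nm, " labels do not cover the cohort")
    ng <- length(unique(l))
    if (ng < 2L) {
      return(data.frame(partition = nm, n_groups = ng, statistic = NA_real_,
                        df = NA_integer_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    lr <- logrank_test(cohort$t_progression, cohort$progression_event, l)
    data.frame(partition = nm, n_groups = ng, statistic = lr$statistic,
               df = lr$df, p_value = lr$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
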