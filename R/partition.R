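#' Ward clustering of map prototypes
#'
#' Agglomerates the trained map's prototype vectors ("virtual patients")
#' with Ward's minimum-variance criterion. The default uses the classical
#' squared-Euclidean Ward objective (`hclust` method `ward.D` on squared
#' distances); `squared = FALSE` switches to `ward.D2` on unsquared
#' Euclidean distances.
#'
#' @param grid a `som_grid` or `som_fit`.
#' @param squared use the squared-Euclidean Ward objective (default TRUE).
#' @return A `som_linkage`: the `hclust` merge record plus the prototype
#'   matrix it was computed from.
#' @export
cluster_prototypes <- function(grid, squared = TRUE) {
  if (inherits(grid, "som_fit")) grid <- grid$grid
  P <- grid$prototypes
  if (nrow(P) < 2L) stop("need at least 2 units to cluster")
  d <- stats::dist(P)
  hc <- if (squared) stats::hclust(d^2, method = "ward.D") else
    stats::hclust(d, method = "ward.D2")
  if (is.unsorted(hc$height)) {
    stop("defect: non-monotone merge heights from Ward linkage")
  }
  structure(list(hclust = hc, prototypes = P, grid = grid,
                 squared = squared),
            class = "som_linkage")
}

#' Two-level cut of the prototype dendrogram
#'
#' Cuts the Ward tree at k = 2 (main clusters X and Y) and k = 4
#' (subclusters), with the k = 4 groups nested inside the k = 2 groups by
#' construction. Labels are canonicalized: X is the main cluster whose
#' units have the higher mean prototype value on the UroVysion feature
#' (falling back to the first feature if absent), and subclusters within
#' each cluster are numbered by decreasing unit count, ties broken toward
#' the lowest unit index.
#'
#' @param linkage a `som_linkage` from [cluster_prototypes()].
#' @return A `map_partition` with per-unit `unit_cluster` and
#'   `unit_subcluster` labels (patient labels are added by
#'   [assign_patients()]).
#' @export
cut_two_level <- function(linkage) {
  hc <- linkage$hclust
  n_units <- nrow(linkage$prototypes)
  if (n_units < 4L) stop("k = 4 cut impossible with fewer than 4 units")
  k2 <- stats::cutree(hc, k = 2L)
  k4 <- stats::cutree(hc, k = 4L)

  feats <- colnames(linkage$prototypes)
  anchor <- if ("urovysion_pos" %in% feats) "urovysion_pos" else 1L
  m1 <- mean(linkage$prototypes[k2 == 1L, anchor])
  m2 <- mean(linkage$prototypes[k2 == 2L, anchor])
  x_id <- if (m1 >= m2) 1L else 2L
  unit_cluster <- ifelse(k2 == x_id, "X", "Y")

  unit_subcluster <- character(n_units)
  for (cl in c("X", "Y")) {
    in_cl <- unit_cluster == cl
    subs <- unique(k4[in_cl])
    size <- vapply(subs, function(s) sum(k4 == s), 0L)
    first <- vapply(subs, function(s) which(k4 == s)[1L], 0L)
    ord <- order(-size, first)
    for (i in seq_along(ord)) {
      unit_subcluster[k4 == subs[ord[i]]] <- paste0(cl, i)
    }
  }
  structure(
    list(unit_cluster = unit_cluster,
         unit_subcluster = unit_subcluster,
         linkage = linkage,
         patient_cluster = NULL, patient_subcluster = NULL,
         patient_unit = NULL, empty_units = NULL),
    class = "map_partition"
  )
}

#' Assign patients to subclusters through their best-matching units
#'
#' Each patient inherits the cluster/subcluster label of its BMU. Units to
#' which no patient maps are recorded in `empty_units` and kept in unit
#' tables with n = 0 (unoccupied neurons are a normal outcome on small
#' cohorts).
#'
#' @param grid a `som_grid` or `som_fit`.
#' @param partition a `map_partition` from [cut_two_level()].
#' @param X the encoded `feature_matrix` of the cohort.
#' @return The `map_partition` completed with `patient_unit`,
#'   `patient_cluster`, `patient_subcluster` and `empty_units`.
#' @export
assign_patients <- function(grid, partition, X) {
  if (inherits(grid, "som_fit")) grid <- grid$grid
  if (is.null(partition$unit_subcluster)) stop("unit labels missing")
  bmu <- .bmu_all(grid, as.matrix(X))$unit
  partition$patient_unit <- bmu
  partition$patient_cluster <- partition$unit_cluster[bmu]
  partition$patient_subcluster <- partition$unit_subcluster[bmu]
  names(partition$patient_subcluster) <- rownames(X)
  partition$empty_units <-
    setdiff(seq_len(nrow(grid$prototypes)), unique(bmu))
  partition
}

#' @export
print.map_partition <- function(x, ...) {
  cat("map_partition:", length(x$unit_cluster), "units in",
      length(unique(x$unit_subcluster)), "subclusters\n")
  if (!is.null(x$patient_subcluster)) {
    print(table(subcluster = x$patient_subcluster))
  }
  invisible(x)
}

#' Tabular export of a map partition
#'
#' @param partition a completed `map_partition`.
#' @return List of two data.frames: `units` (row, col, cluster,
#'   subcluster, n_patients — empty units included with 0) and `patients`
#'   (id, bmu, cluster, subcluster).
#' @export
partition_tables <- function(partition) {
  grid <- partition$linkage$grid
  n_per_unit <- tabulate(partition$patient_unit,
                         nbins = length(partition$unit_cluster))
  units <- data.frame(
    unit = seq_along(partition$unit_cluster),
    row = grid$unit_coords[, "row"],
    col = grid$unit_coords[, "col"],
    cluster = partition$unit_cluster,
    subcluster = partition$unit_subcluster,
    n_patients = n_per_unit,
    stringsAsFactors = FALSE
  )
  patients <- NULL
  if (!is.null(partition$patient_subcluster)) {
    ids <- names(partition$patient_subcluster)
    if (is.null(ids)) ids <- as.character(seq_along(partition$patient_subcluster))
    patients <- data.frame(
      patient_id = ids,
      bmu = partition$patient_unit,
      cluster = partition$patient_cluster,
      subcluster = partition$patient_subcluster,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  list(units = units, patients = patients)
}
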