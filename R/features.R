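#' Default feature set for map training
#'
#' The ten genetic variables used as map inputs by default: the nine
#' binary tumor/viral markers plus the binary CDKN2A A148T genotype. The
#' three-level CYP1B1 and TP53 codon-72 polymorphisms can be added via the
#' `features` argument of [encode_features()]; they enter as equally
#' spaced ordinal scalars so each variable still occupies one input
#' neuron.
#'
#' @return Character vector of length 10.
#' @export
som_features <- function() {
  c(cohort_fields()$markers, "cdkn2a_a148t")
}

# encoding registry: number of levels for each encodable feature
.feature_levels <- function() {
  fl <- cohort_fields()
  c(stats::setNames(rep(2L, length(fl$markers)), fl$markers),
    .genotype_levels)
}

#' Encode cohort features for map training
#'
#' Builds the numeric patient x feature matrix presented to the map's
#' input neurons. Binary markers map to \{0, 1\}; k-level ordinal codes map
#' to equally spaced values in \[0, 1\] (`code / (k - 1)`), so all features
#' share the \[0, 1\] scale and contribute comparably to Euclidean
#' distances.
#'
#' @param cohort validated cohort.
#' @param features ordered character vector of feature names; defaults to
#'   [som_features()].
#' @return A `feature_matrix`: numeric matrix (rows = patients, in cohort
#'   order) with attributes `encoding` (`"binary"`/`"ordinal"` per
#'   feature) and `n_levels` (levels per feature).
#' @examples
#' coh <- simulate_cohort(n = 10, seed = 1)
#' X <- encode_features(coh)
#' dim(X)  # 10 patients x 10 features
#' @export
encode_features <- function(cohort, features = som_features()) {
  levels_map <- .feature_levels()
  unknown <- setdiff(features, names(levels_map))
  if (length(unknown) > 0L) {
    stop("configuration error: unknown feature(s): ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(features, names(cohort))
  if (length(absent) > 0L) {
    stop("feature(s) absent from cohort: ", paste(absent, collapse = ", "))
  }
  k <- levels_map[features]
  X <- vapply(seq_along(features), function(j) {
    cohort[[features[j]]] / (k[j] - 1L)
  }, numeric(nrow(cohort)))
  X <- matrix(X, nrow = nrow(cohort),
              dimnames = list(cohort$patient_id, features))
  structure(X,
            class = c("feature_matrix", "matrix", "array"),
            encoding = ifelse(k == 2L, "binary", "ordinal")[seq_along(k)] |>
              stats::setNames(features),
            n_levels = stats::setNames(as.integer(k), features))
}

#' Decode a feature matrix back to integer codes
#'
#' Inverse of [encode_features()]: maps each scaled value back to its
#' ordinal code, exact on values produced by the encoder.
#'
#' @param X a `feature_matrix`.
#' @return Integer matrix of codes with the same dimnames.
#' @export
decode_features <- function(X) {
  k <- attr(X, "n_levels")
  if (is.null(k)) stop("not a feature_matrix: missing n_levels attribute")
  out <- vapply(seq_len(ncol(X)), function(j) {
    as.integer(round(X[, j] * (k[j] - 1L)))
  }, integer(nrow(X)))
  matrix(out, nrow = nrow(X), dimnames = dimnames(X))
}
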