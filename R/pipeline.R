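#' Subtype a cohort with the map pipeline
#'
#' The core analysis chain in one call: encode features, train the
#' self-organizing map, Ward-cluster its prototypes, cut the two-level
#' partition and assign every patient to a subcluster via its
#' best-matching unit.
#'
#' @param cohort validated cohort.
#' @param features feature names to present to the map; default
#'   [som_features()].
#' @param rows,cols map dimensions.
#' @param schedule training schedule; default [som_schedule()].
#' @param method map initialization, `"linear"` (deterministic) or
#'   `"random"`.
#' @param seed training seed (used by random init).
#' @return List with `X` (feature matrix), `fit` (`som_fit`), `linkage`
#'   (`som_linkage`) and `partition` (completed `map_partition`).
#' @examples
#' coh <- simulate_cohort(n = 104, seed = 11)
#' st <- subtype_cohort(coh, seed = 11)
#' table(st$partition$patient_subcluster)
#' @export
subtype_cohort <- function(cohort, features = som_features(),
                           rows = 4L, cols = 4L, schedule = som_schedule(),
                           method = c("linear", "random"), seed = NULL) {
  X <- encode_features(cohort, features)
  fit <- som_train(X, rows = rows, cols = cols, schedule = schedule,
                   method = method, seed = seed)
  linkage <- cluster_prototypes(fit)
  partition <- assign_patients(fit, cut_two_level(linkage), X)
  list(X = X, fit = fit, linkage = linkage, partition = partition)
}

#' Pipeline configuration
#'
#' Resolves every option and seed to an explicit value so a run is fully
#' reproducible from its manifest.
#'
#' @param input path to a cohort CSV/TSV, or `NULL` to simulate.
#' @param schema optional column-mapping for [load_cohort()].
#' @param n synthetic cohort size when `input` is `NULL`.
#' @param features map input features.
#' @param rows,cols map dimensions.
#' @param schedule training schedule.
#' @param n_permutations randomization-test permutations.
#' @param baseline_k groups for the direct-clustering comparison arm.
#' @param seed_train,seed_permutation,seed_generation the three named
#'   seeds feeding map training, randomization tests and cohort
#'   simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, schema = NULL, n = 104L,
                            features = som_features(), rows = 4L, cols = 4L,
                            schedule = som_schedule(),
                            n_permutations = 9999L, baseline_k = 4L,
                            seed_train = 1L, seed_permutation = 2L,
                            seed_generation = 3L) {
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input)
  }
  structure(list(input = input, schema = schema, n = as.integer(n),
                 features = features, rows = as.integer(rows),
                 cols = as.integer(cols), schedule = schedule,
                 n_permutations = as.integer(n_permutations),
                 baseline_k = as.integer(baseline_k),
                 seed_train = as.integer(seed_train),
                 seed_permutation = as.integer(seed_permutation),
                 seed_generation = as.integer(seed_generation)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline and write its artifact set
#'
#' load/simulate -> encode -> train -> cluster prototypes -> assign ->
#' subcluster statistics -> survival comparisons, writing every table as
#' CSV/JSON under `out_dir` plus a `manifest.json` recording inputs,
#' seeds and output files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
    p
  }

  stage <- "load"
  manifest <- tryCatch({
    if (is.null(config$input)) {
      cohort <- simulate_cohort(n = config$n, seed = config$seed_generation)
      emit(cbind(cohort, true_subtype = attr(cohort, "true_subtype")),
           "cohort.csv")
    } else {
      cohort <- load_cohort(config$input, schema = config$schema)
    }
    emit(summarize_cohort(cohort), "cohort_summary.csv")
    emit(derive_composite_flags(cohort), "composite_flags.csv")

    stage <- "train"
    st <- subtype_cohort(cohort, features = config$features,
                         rows = config$rows, cols = config$cols,
                         schedule = config$schedule, seed = config$seed_train)
    write_som(st$fit, file.path(out_dir, "som.json"))
    paths[["som.json"]] <- file.path(out_dir, "som.json")
    planes <- component_planes(st$fit)
    plane_df <- do.call(rbind, lapply(names(planes), function(f) {
      m <- planes[[f]]
      data.frame(feature = f,
                 row = rep(seq_len(nrow(m)), times = ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
    }))
    emit(plane_df, "component_planes.csv")

    stage <- "partition"
    tabs <- partition_tables(st$partition)
    emit(tabs$units, "units.csv")
    emit(tabs$patients, "patients.csv")

    stage <- "subcluster_stats"
    rep <- subcluster_report(cohort, st$partition,
                             n_permutations = config$n_permutations,
                             seed = config$seed_permutation)
    emit(rep$table, "subcluster_report.csv")

    stage <- "survival"
    screen <- univariable_screen(cohort)
    emit(screen, "univariable_screen.csv")
    base <- hcluster_patients(st$X, k = config$baseline_k)
    emit(compare_stratification(cohort, st$partition, base),
         "stratification.csv")
    km <- lapply(split(seq_len(nrow(cohort)), st$partition$patient_subcluster),
                 function(i) km_estimate(cohort$t_progression[i],
                                         cohort$progression_event[i]))
    km_df <- do.call(rbind, lapply(names(km), function(g) {
      cbind(subcluster = g, as.data.frame(km[[g]]))
    }))
    emit(km_df, "km_progression.csv")

    list(
      package = "somtype",
      version = as.character(utils::packageVersion("somtype")),
      input = if (is.null(config$input)) "synthetic" else config$input,
      n_patients = nrow(cohort),
      n_features = length(config$features),
      map = c(config$rows, config$cols),
      n_epochs = length(st$fit$qe_trace),
      qe_trace = st$fit$qe_trace,
      topographic_error = st$fit$topographic_error,
      subcluster_sizes = as.list(table(st$partition$patient_subcluster)),
      empty_units = st$partition$empty_units,
      n_permutations = config$n_permutations,
      seeds = list(train = config$seed_train,
                   permutation = config$seed_permutation,
                   generation = config$seed_generation),
      outputs = names(paths)
    )
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
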