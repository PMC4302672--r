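#' @title Cohort schema
#' @description Canonical column names of a patient cohort table.
#'
#' A cohort is a plain `data.frame`, one row per patient, with binary
#' marker columns coded 0/1, ordinal genotype columns coded as small
#' integers, clinical covariates and censored time-to-event outcomes.
#'
#' @return Named list of character vectors grouping the canonical fields:
#'   `markers` (binary 0/1), `genotypes` (ordinal codes), `clinical`,
#'   `outcomes`, and `id`.
#' @examples
#' cohort_fields()$markers
#' @export
cohort_fields <- function() {
  list(
    id = "patient_id",
    markers = c("chek2_mut", "fgfr3_mut", "tp53_mut", "tp53_expr_altered",
                "loh9", "loh13", "loh17", "urovysion_pos", "hpv_pos"),
    genotypes = c("cdkn2a_a148t", "cyp1b1", "tp53_codon72"),
    clinical = c("grade", "stage", "diameter_gt2cm", "multiplicity_gt1",
                 "smoker_ever", "occupational_exposure", "age", "sex"),
    outcomes = c("t_progression", "progression_event",
                 "t_recurrence", "recurrence_event")
  )
}

# number of levels per ordinal genotype (codes 0..levels-1)
.genotype_levels <- c(cdkn2a_a148t = 2L, cyp1b1 = 3L, tp53_codon72 = 3L)

.stage_levels <- c("Ta", "T1", "T2-T4")

.all_fields <- function() unlist(cohort_fields(), use.names = FALSE)

#' Validate a cohort data frame
#'
#' Checks the invariants every downstream step assumes: all canonical
#' columns present, binary fields in \{0, 1\}, ordinal codes within range,
#' grade in 1..3, stage one of Ta/T1/T2-T4, event times strictly positive,
#' and (in strict mode) no missing values anywhere.
#'
#' @param cohort data.frame with the columns of [cohort_fields()].
#' @param on_missing `"error"` (default) rejects rows with missing values;
#'   `"drop"` removes them with a warning.
#' @return The validated cohort (invisibly unchanged apart from dropped
#'   rows), with `stage` and `sex` as character.
#' @export
validate_cohort <- function(cohort, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("empty cohort")
  missing_cols <- setdiff(.all_fields(), names(cohort))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cohort$stage <- as.character(cohort$stage)
  cohort$sex <- as.character(cohort$sex)
  cohort$patient_id <- as.character(cohort$patient_id)

  na_rows <- which(rowSums(is.na(cohort[, .all_fields(), drop = FALSE])) > 0L)
  if (length(na_rows) > 0L) {
    if (on_missing == "error") {
      stop("validation error: missing values in row(s) ",
           paste(utils::head(na_rows, 5L), collapse = ", "))
    }
    warning("dropping ", length(na_rows), " row(s) with missing values")
    cohort <- cohort[-na_rows, , drop = FALSE]
    if (nrow(cohort) == 0L) stop("empty cohort after dropping incomplete rows")
  }

  fl <- cohort_fields()
  check_range <- function(field, ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0L) {
      stop(sprintf("validation error: row %d, field '%s': %s",
                   bad[1L], field, what))
    }
  }
  for (f in c(fl$markers, "diameter_gt2cm", "multiplicity_gt1",
              "smoker_ever", "occupational_exposure",
              "progression_event", "recurrence_event")) {
    check_range(f, cohort[[f]] %in% c(0, 1), "must be 0 or 1")
  }
  for (g in fl$genotypes) {
    check_range(g, cohort[[g]] %in% seq(0L, .genotype_levels[[g]] - 1L),
                sprintf("code outside 0..%d", .genotype_levels[[g]] - 1L))
  }
  check_range("grade", cohort$grade %in% 1:3, "must be 1, 2 or 3")
  check_range("stage", cohort$stage %in% .stage_levels,
              paste("must be one of", paste(.stage_levels, collapse = "/")))
  check_range("sex", cohort$sex %in% c("M", "F"), "must be M or F")
  check_range("age", is.finite(cohort$age) & cohort$age > 0,
              "must be positive")
  for (tcol in c("t_progression", "t_recurrence")) {
    check_range(tcol, is.finite(cohort[[tcol]]) & cohort[[tcol]] > 0,
                "event time must be strictly positive")
  }
  if (anyDuplicated(cohort$patient_id)) {
    stop("validation error: duplicated patient_id")
  }
  rownames(cohort) <- NULL
  cohort
}

#' Load a patient cohort from a delimited text file
#'
#' Reads a CSV/TSV with a header row, optionally renames columns through a
#' schema mapping, and validates the result (see [validate_cohort()]).
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param schema optional named character vector mapping canonical field
#'   names to the column names used in the file,
#'   e.g. `c(fgfr3_mut = "FGFR3")`. Unmapped canonical fields are expected
#'   under their own names. A schema may also be a path to a plain-text
#'   `key = value` file.
#' @param sep field separator override.
#' @inheritParams validate_cohort
#' @return A validated cohort data.frame.
#' @seealso [write_cohort()]
#' @export
load_cohort <- function(path, schema = NULL, sep = NULL,
                        on_missing = c("error", "drop")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(schema) && length(schema) == 1L && is.null(names(schema)) &&
      file.exists(schema)) {
    schema <- read_schema_file(schema)
  }
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      stop("schema error: schema must be a fully named character vector")
    }
    unknown <- setdiff(names(schema), .all_fields())
    if (length(unknown) > 0L) {
      stop("schema error: unknown canonical field(s): ",
           paste(unknown, collapse = ", "))
    }
    absent <- setdiff(unname(schema), names(df))
    if (length(absent) > 0L) {
      stop("schema error: mapped column(s) not in file: ",
           paste(absent, collapse = ", "))
    }
    idx <- match(unname(schema), names(df))
    names(df)[idx] <- names(schema)
  }
  validate_cohort(df, on_missing = on_missing)
}

# plain-text "canonical_field = column name" schema files
read_schema_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("schema error: malformed line: ", lines[bad][1L])
  stats::setNames(vapply(kv, function(x) trimws(x[2L]), ""),
                  vapply(kv, function(x) trimws(x[1L]), ""))
}

#' Write a cohort back to delimited text
#'
#' Inverse of [load_cohort()]: the written file reloads to an identical
#' cohort (round-trip identity).
#'
#' @param cohort validated cohort data.frame.
#' @param path output path; delimiter inferred as in [load_cohort()].
#' @param sep field separator override.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  cols <- intersect(c(.all_fields(), setdiff(names(cohort), .all_fields())),
                    names(cohort))
  utils::write.table(cohort[, cols, drop = FALSE], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Composite mutation and LOH flags
#'
#' Per-patient aggregates used in the cohort narrative: whether any of the
#' CHEK2/FGFR3/TP53 point mutations is present, how many are, and the same
#' for loss of heterozygosity at chromosomes 9, 13 and 17.
#'
#' @param cohort validated cohort.
#' @return data.frame with `patient_id`, `any_mutation`, `n_mutations`,
#'   `any_loh`, `n_loh`.
#' @examples
#' coh <- simulate_cohort(n = 20, seed = 1)
#' colSums(derive_composite_flags(coh)[, -1])
#' @export
derive_composite_flags <- function(cohort) {
  mut <- c("chek2_mut", "fgfr3_mut", "tp53_mut")
  loh <- c("loh9", "loh13", "loh17")
  missing_cols <- setdiff(c(mut, loh), names(cohort))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  n_mut <- rowSums(cohort[, mut, drop = FALSE])
  n_loh <- rowSums(cohort[, loh, drop = FALSE])
  data.frame(
    patient_id = as.character(cohort$patient_id),
    any_mutation = as.integer(n_mut > 0),
    n_mutations = as.integer(n_mut),
    any_loh = as.integer(n_loh > 0),
    n_loh = as.integer(n_loh),
    stringsAsFactors = FALSE
  )
}

#' Marginal summary of a cohort
#'
#' Tabulates every marker, genotype and categorical clinical variable by
#' level with counts and percentages (recomputed from counts, one decimal),
#' and appends overall recurrence and progression event rates.
#'
#' @param cohort validated cohort.
#' @return data.frame with columns `variable`, `level`, `count`, `percent`.
#' @examples
#' coh <- simulate_cohort(n = 104, seed = 1)
#' head(summarize_cohort(coh))
#' @export
summarize_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) stop("empty cohort")
  n <- nrow(cohort)
  fl <- cohort_fields()
  vars <- c(fl$markers, fl$genotypes, "grade", "stage", "diameter_gt2cm",
            "multiplicity_gt1", "smoker_ever", "occupational_exposure", "sex")
  rows <- lapply(vars, function(v) {
    tab <- table(cohort[[v]])
    data.frame(variable = v, level = names(tab),
               count = as.integer(tab),
               percent = round(100 * as.integer(tab) / n, 1L),
               stringsAsFactors = FALSE)
  })
  ev <- data.frame(
    variable = c("recurrence_event", "progression_event"),
    level = "1",
    count = c(sum(cohort$recurrence_event), sum(cohort$progression_event)),
    stringsAsFactors = FALSE
  )
  ev$percent <- round(100 * ev$count / n, 1L)
  out <- rbind(do.call(rbind, rows), ev)
  rownames(out) <- NULL
  out
}
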