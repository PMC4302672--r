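#' Subcluster characterization report
#'
#' The central descriptive output: for every marker, genotype and clinical
#' variable, per-subcluster counts with percentages (always recomputed
#' from counts) and a significance test routed by measurement level —
#' binary/categorical variables to the Monte Carlo randomization test
#' ([mc_randomization_test()]), graded/ordinal variables (grade, stage,
#' tumor multiplicity, diameter class) to Kruskal-Wallis with Dunn post
#' hoc.
#'
#' @param cohort validated cohort.
#' @param partition completed `map_partition` (or any vector of
#'   per-patient group labels).
#' @param n_permutations permutations for the randomization tests.
#' @param seed RNG seed for the randomization tests.
#' @param collapse_cyp1b1 report CYP1B1 as two levels (T/T homozygotes vs
#'   G-allele carriers) instead of its three genotype codes.
#' @return List with `table` (data.frame: variable, level, one
#'   `count (percent)` column per subcluster, `p_value`, `p_label`,
#'   `test`) and `details` (raw test objects per variable, including
#'   per-subcluster phi and Dunn pairs).
#' @examples
#' \donttest{
#' coh <- simulate_cohort(n = 104, seed = 3)
#' part <- subtype_cohort(coh, seed = 3)$partition
#' rep <- subcluster_report(coh, part, n_permutations = 999, seed = 3)
#' head(rep$table)
#' }
#' @export
subcluster_report <- function(cohort, partition, n_permutations = 9999L,
                              seed = NULL, collapse_cyp1b1 = TRUE) {
  labels <- if (inherits(partition, "map_partition")) {
    partition$patient_subcluster
  } else as.character(partition)
  if (length(labels) != nrow(cohort)) {
    stop("labels do not cover the cohort")
  }
  groups <- sort(unique(labels))

  binary_vars <- c("smoker_ever", "occupational_exposure",
                   "recurrence_event", "hpv_pos", "chek2_mut", "fgfr3_mut",
                   "tp53_mut", "tp53_expr_altered", "loh9", "loh13",
                   "loh17", "urovysion_pos", "cdkn2a_a148t")
  ordinal_vars <- c("grade", "stage", "multiplicity_gt1", "diameter_gt2cm")

  get_var <- function(v) {
    if (v == "stage") {
      # ordered for ranking: Ta < T1 < T2-T4
      as.integer(factor(cohort$stage, levels = .stage_levels))
    } else cohort[[v]]
  }

  details <- list()
  rows <- list()
  add_rows <- function(variable, values, p, test) {
    lev <- sort(unique(values), decreasing = TRUE)
    for (l in lev) {
      cells <- vapply(groups, function(g) {
        cnt <- sum(values == l & labels == g)
        sz <- sum(labels == g)
        sprintf("%d (%.1f)", cnt, 100 * cnt / sz)
      }, "")
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, level = as.character(l),
        t(cells), p_value = p, p_label = .p_label(p), test = test,
        stringsAsFactors = FALSE, check.names = FALSE
      )
      p <- NA_real_; test <- ""   # print p once per variable block
    }
  }

  for (v in binary_vars) {
    vals <- get_var(v)
    res <- tryCatch(
      mc_randomization_test(vals, labels, n_permutations = n_permutations,
                            seed = seed),
      warning = function(w) {
        suppressWarnings(
          mc_randomization_test(vals, labels,
                                n_permutations = n_permutations, seed = seed))
      })
    details[[v]] <- res
    add_rows(v, vals, res$p_value, "randomization")
  }
  if (collapse_cyp1b1) {
    vals <- as.integer(cohort$cyp1b1 == 2L)   # T/T vs G carriers
    res <- suppressWarnings(
      mc_randomization_test(vals, labels, n_permutations = n_permutations,
                            seed = seed))
    details[["cyp1b1_tt"]] <- res
    add_rows("cyp1b1_tt", vals, res$p_value, "randomization")
  } else {
    vals <- cohort$cyp1b1
    res <- suppressWarnings(
      mc_randomization_test(factor(vals), labels,
                            n_permutations = n_permutations, seed = seed))
    details[["cyp1b1"]] <- res
    add_rows("cyp1b1", vals, res$p_value, "randomization")
  }
  vals <- cohort$tp53_codon72
  res <- suppressWarnings(
    mc_randomization_test(factor(vals), labels,
                          n_permutations = n_permutations, seed = seed))
  details[["tp53_codon72"]] <- res
  add_rows("tp53_codon72", vals, res$p_value, "randomization")

  for (v in ordinal_vars) {
    vals <- get_var(v)
    kw <- kruskal_wallis(vals, labels)
    dn <- if (kw$H > 0) dunn_posthoc(vals, labels) else NULL
    details[[v]] <- list(kruskal_wallis = kw, dunn = dn)
    add_rows(v, vals, kw$p_value, "kruskal-wallis")
  }

  tab <- do.call(rbind, rows)
  names(tab)[3:(2 + length(groups))] <- groups
  rownames(tab) <- NULL
  list(table = tab, details = details,
       n_permutations = as.integer(n_permutations), seed = seed)
}
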