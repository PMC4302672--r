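#' Archetype specification for the cohort simulator
#'
#' One molecular archetype: its mixing proportion and the per-variable
#' sampling distributions used for patients drawn from it. Markers are
#' sampled as independent Bernoulli draws given the archetype (the
#' simulator's key simplification: no within-archetype marker
#' correlation).
#'
#' @param name archetype label.
#' @param proportion mixing proportion in \[0, 1\].
#' @param markers named Bernoulli probabilities for the nine binary
#'   markers plus `cdkn2a_a148t`.
#' @param cyp1b1,tp53_codon72 length-3 probability vectors over genotype
#'   codes 0, 1, 2.
#' @param grade length-3 probability vector over grades 1-3.
#' @param stage length-3 probability vector over Ta, T1, T2-T4.
#' @param diameter_gt2cm,multiplicity_gt1,smoker_ever,occupational_exposure,female
#'   Bernoulli probabilities for the clinical binaries.
#' @param age_mean,age_sd normal age distribution (years), truncated to
#'   \[30, 95\].
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(name, proportion, markers, cyp1b1, tp53_codon72,
                           grade, stage, diameter_gt2cm, multiplicity_gt1,
                           smoker_ever, occupational_exposure, female,
                           age_mean, age_sd = 11) {
  spec <- list(name = name, proportion = proportion, markers = markers,
               cyp1b1 = cyp1b1, tp53_codon72 = tp53_codon72, grade = grade,
               stage = stage, diameter_gt2cm = diameter_gt2cm,
               multiplicity_gt1 = multiplicity_gt1,
               smoker_ever = smoker_ever,
               occupational_exposure = occupational_exposure,
               female = female, age_mean = age_mean, age_sd = age_sd)
  class(spec) <- "archetype_spec"
  .validate_archetype(spec)
  spec
}

.validate_archetype <- function(spec) {
  need <- c(cohort_fields()$markers, "cdkn2a_a148t")
  missing_m <- setdiff(need, names(spec$markers))
  if (length(missing_m) > 0L) {
    stop("archetype '", spec$name, "': missing marker probabilities: ",
         paste(missing_m, collapse = ", "))
  }
  probs <- c(spec$markers, spec$cyp1b1, spec$tp53_codon72, spec$grade,
             spec$stage, spec$diameter_gt2cm, spec$multiplicity_gt1,
             spec$smoker_ever, spec$occupational_exposure, spec$female)
  if (any(probs < 0 | probs > 1)) {
    stop("archetype '", spec$name, "': probability outside [0, 1]")
  }
  for (f in c("cyp1b1", "tp53_codon72", "grade", "stage")) {
    if (length(spec[[f]]) != 3L || abs(sum(spec[[f]]) - 1) > 1e-8) {
      stop("archetype '", spec$name, "': ", f,
           " must be 3 probabilities summing to 1")
    }
  }
  if (spec$proportion < 0 || spec$proportion > 1) {
    stop("archetype '", spec$name, "': proportion outside [0, 1]")
  }
  invisible(spec)
}

# convenience: counts over a group size -> probability
.fr <- function(count, size) count / size

#' Default archetype panel
#'
#' Four molecular archetypes whose mixing proportions (24/104, 28/104,
#' 24/104, 28/104) and per-variable frequencies reproduce the observed
#' subcluster profiles of the reference cohort: an aggressive
#' UroVysion-positive/TP53-driven pair (X1, X2 — X2 additionally LOH-rich
#' with altered TP53 expression) and a lower-risk pair (Y1 —
#' UroVysion-negative, moderate FGFR3; Y2 — FGFR3-mutant in every
#' patient, mostly UroVysion-positive). CYP1B1 genotypes not fixed by the
#' subcluster T/T frequency are split between G/G and G/T in the cohort's
#' overall 44:46 ratio.
#'
#' @return List of four `archetype_spec` objects.
#' @export
default_archetypes <- function() {
  cy <- function(tt) {
    g <- (1 - tt) * c(44, 46) / 90
    c(g[1L], g[2L], tt)
  }
  mk <- function(chek2, fgfr3, tp53, expr, l9, l13, l17, uro, hpv, cdkn2a,
                 size) {
    c(chek2_mut = chek2, fgfr3_mut = fgfr3, tp53_mut = tp53,
      tp53_expr_altered = expr, loh9 = l9, loh13 = l13, loh17 = l17,
      urovysion_pos = uro, hpv_pos = hpv, cdkn2a_a148t = cdkn2a) / size
  }
  g23 <- function(g1, size) {
    p1 <- g1 / size
    c(p1, 0.7 * (1 - p1), 0.3 * (1 - p1))
  }
  list(
    archetype_spec("X1", 24 / 104,
                   markers = mk(2, 1, 5, 1, 1, 1, 2, 24, 4, 5, 24),
                   cyp1b1 = cy(5 / 24), tp53_codon72 = c(16, 7, 1) / 24,
                   grade = g23(10, 24), stage = c(16, 3, 5) / 24,
                   diameter_gt2cm = 14 / 24, multiplicity_gt1 = 6 / 24,
                   smoker_ever = 24 / 24, occupational_exposure = 9 / 24,
                   female = 2 / 24, age_mean = 64),
    archetype_spec("X2", 28 / 104,
                   markers = mk(1, 1, 5, 16, 17, 3, 8, 26, 4, 1, 28),
                   cyp1b1 = cy(3 / 28), tp53_codon72 = c(15, 12, 1) / 28,
                   grade = g23(13, 28), stage = c(15, 8, 5) / 28,
                   diameter_gt2cm = 21 / 28, multiplicity_gt1 = 10 / 28,
                   smoker_ever = 26 / 28, occupational_exposure = 9 / 28,
                   female = 4 / 28, age_mean = 75.5),
    archetype_spec("Y1", 24 / 104,
                   markers = mk(1, 9, 0, 1, 7, 2, 0, 0, 3, 1, 24),
                   cyp1b1 = cy(1 / 24), tp53_codon72 = c(13, 9, 2) / 24,
                   grade = g23(19, 24), stage = c(19, 5, 0) / 24,
                   diameter_gt2cm = 5 / 24, multiplicity_gt1 = 7 / 24,
                   smoker_ever = 22 / 24, occupational_exposure = 9 / 24,
                   female = 5 / 24, age_mean = 70.5),
    archetype_spec("Y2", 28 / 104,
                   markers = mk(3, 28, 5, 11, 8, 0, 2, 24, 3, 0, 28),
                   cyp1b1 = cy(5 / 28), tp53_codon72 = c(11, 13, 4) / 28,
                   grade = g23(18, 28), stage = c(20, 5, 3) / 28,
                   diameter_gt2cm = 10 / 28, multiplicity_gt1 = 7 / 28,
                   smoker_ever = 27 / 28, occupational_exposure = 12 / 28,
                   female = 1 / 28, age_mean = 69)
  )
}

#' Default hazard specification
#'
#' Exponential progression times with log hazard ratios `ln 2.9` per
#' grade step above G1 and `ln 3.8` for HPV positivity — the two
#' independent predictors the simulator plants. Baseline rates are in
#' events per month and calibrated so that, with uniform censoring on
#' \[6, 60\] months, about 14% of a default cohort progresses and about
#' 23% recurs. Recurrence is an independent covariate-free exponential.
#'
#' @param progression_rate baseline progression hazard (per month, G1,
#'   HPV-negative).
#' @param beta_grade log hazard ratio per grade step.
#' @param beta_hpv log hazard ratio for HPV positivity.
#' @param recurrence_rate recurrence hazard (per month).
#' @param censor_min,censor_max uniform censoring-time range (months).
#' @return A `hazard_spec` list.
#' @export
hazard_spec <- function(progression_rate = 0.001562,
                        beta_grade = log(2.9), beta_hpv = log(3.8),
                        recurrence_rate = 0.008161,
                        censor_min = 6, censor_max = 60) {
  if (progression_rate <= 0 || recurrence_rate <= 0) {
    stop("hazard rates must be positive")
  }
  if (censor_min <= 0 || censor_max <= censor_min) {
    stop("need 0 < censor_min < censor_max")
  }
  structure(list(progression_rate = progression_rate,
                 beta_grade = beta_grade, beta_hpv = beta_hpv,
                 recurrence_rate = recurrence_rate,
                 censor_min = censor_min, censor_max = censor_max),
            class = "hazard_spec")
}

#' Default archetype and hazard specifications
#'
#' @return `list(archetypes, hazards)` with [default_archetypes()] and
#'   [hazard_spec()] defaults.
#' @export
default_specs <- function() {
  list(archetypes = default_archetypes(), hazards = hazard_spec())
}

#' Simulate a patient cohort with planted molecular archetypes
#'
#' Each patient draws an archetype by mixing proportion, then markers and
#' clinical covariates independently from that archetype's distributions.
#' Progression times are exponential with rate
#' `progression_rate * exp(beta_grade * (grade - 1) + beta_hpv * hpv)`,
#' censored by an independent uniform draw; recurrence is an independent
#' covariate-free exponential. Deterministic under `seed`.
#'
#' @param n cohort size.
#' @param seed RNG seed.
#' @param archetypes list of [archetype_spec()] objects; proportions must
#'   sum to 1.
#' @param hazards a [hazard_spec()].
#' @return Validated cohort data.frame with attribute `true_subtype` (the
#'   planted archetype per patient).
#' @examples
#' coh <- simulate_cohort(n = 104, seed = 1)
#' table(attr(coh, "true_subtype"))
#' @export
simulate_cohort <- function(n = 104L, seed = NULL,
                            archetypes = default_archetypes(),
                            hazards = hazard_spec()) {
  stopifnot(n >= 1L)
  lapply(archetypes, .validate_archetype)
  if (!inherits(hazards, "hazard_spec")) stop("invalid hazard spec")
  props <- vapply(archetypes, `[[`, 0, "proportion")
  if (abs(sum(props) - 1) > 1e-8) {
    stop("archetype proportions must sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)

  arch_names <- vapply(archetypes, `[[`, "", "name")
  z <- sample.int(length(archetypes), n, replace = TRUE, prob = props)

  draw_cat <- function(get_probs, codes) {
    vapply(z, function(a) {
      sample(codes, 1L, prob = get_probs(archetypes[[a]]))
    }, codes[1L])
  }
  marker_names <- c(cohort_fields()$markers, "cdkn2a_a148t")
  M <- vapply(marker_names, function(m) {
    p <- vapply(archetypes, function(a) a$markers[[m]], 0)[z]
    as.integer(stats::runif(n) < p)
  }, integer(n))
  M <- matrix(M, nrow = n, dimnames = list(NULL, marker_names))

  bern <- function(field) {
    p <- vapply(archetypes, `[[`, 0, field)[z]
    as.integer(stats::runif(n) < p)
  }
  grade <- draw_cat(function(a) a$grade, 1:3)
  hpv <- M[, "hpv_pos"]
  rate_prog <- hazards$progression_rate *
    exp(hazards$beta_grade * (grade - 1) + hazards$beta_hpv * hpv)
  T_prog <- stats::rexp(n, rate_prog)
  C_prog <- stats::runif(n, hazards$censor_min, hazards$censor_max)
  T_rec <- stats::rexp(n, hazards$recurrence_rate)
  C_rec <- stats::runif(n, hazards$censor_min, hazards$censor_max)

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    M,
    cyp1b1 = draw_cat(function(a) a$cyp1b1, 0:2),
    tp53_codon72 = draw_cat(function(a) a$tp53_codon72, 0:2),
    grade = grade,
    stage = draw_cat(function(a) a$stage, .stage_levels),
    diameter_gt2cm = bern("diameter_gt2cm"),
    multiplicity_gt1 = bern("multiplicity_gt1"),
    smoker_ever = bern("smoker_ever"),
    occupational_exposure = bern("occupational_exposure"),
    age = round(pmin(95, pmax(30, stats::rnorm(
      n, vapply(archetypes, `[[`, 0, "age_mean")[z],
      vapply(archetypes, `[[`, 0, "age_sd")[z]))), 1L),
    sex = ifelse(bern("female") == 1L, "F", "M"),
    t_progression = round(pmin(T_prog, C_prog), 2L),
    progression_event = as.integer(T_prog <= C_prog),
    t_recurrence = round(pmin(T_rec, C_rec), 2L),
    recurrence_event = as.integer(T_rec <= C_rec),
    stringsAsFactors = FALSE
  )
  cohort$t_progression <- pmax(cohort$t_progression, 0.01)
  cohort$t_recurrence <- pmax(cohort$t_recurrence, 0.01)
  cohort <- validate_cohort(cohort)
  attr(cohort, "true_subtype") <- arch_names[z]
  cohort
}

#' Simulate a structureless null cohort
#'
#' Every variable is drawn from the pooled cohort-wide marginal
#' distribution, independently of every other, and both endpoints are
#' covariate-free exponentials (progression rate calibrated to the same
#' ~14% event fraction). Used for type-I-error and calibration checks: no
#' marker is associated with any other marker or with outcome.
#'
#' @inheritParams simulate_cohort
#' @return Validated cohort data.frame.
#' @export
generate_null_cohort <- function(n = 104L, seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  p_marker <- c(chek2_mut = 7, fgfr3_mut = 39, tp53_mut = 15,
                tp53_expr_altered = 29, loh9 = 33, loh13 = 6, loh17 = 12,
                urovysion_pos = 74, hpv_pos = 14, cdkn2a_a148t = 7) / 104
  M <- vapply(names(p_marker), function(m) {
    as.integer(stats::runif(n) < p_marker[[m]])
  }, integer(n))
  M <- matrix(M, nrow = n, dimnames = list(NULL, names(p_marker)))
  hz <- hazard_spec()
  lam_prog <- 0.004650   # covariate-free rate giving ~14% events
  T_prog <- stats::rexp(n, lam_prog)
  C_prog <- stats::runif(n, hz$censor_min, hz$censor_max)
  T_rec <- stats::rexp(n, hz$recurrence_rate)
  C_rec <- stats::runif(n, hz$censor_min, hz$censor_max)
  cohort <- data.frame(
    patient_id = sprintf("N%04d", seq_len(n)),
    M,
    cyp1b1 = sample(0:2, n, replace = TRUE, prob = c(44, 46, 14) / 104),
    tp53_codon72 = sample(0:2, n, replace = TRUE, prob = c(55, 41, 8) / 104),
    grade = sample(1:3, n, replace = TRUE,
                   prob = c(60 / 104, 0.7 * 44 / 104, 0.3 * 44 / 104)),
    stage = sample(.stage_levels, n, replace = TRUE,
                   prob = c(70, 21, 13) / 104),
    diameter_gt2cm = as.integer(stats::runif(n) < 50 / 104),
    multiplicity_gt1 = as.integer(stats::runif(n) < 30 / 104),
    smoker_ever = as.integer(stats::runif(n) < 99 / 104),
    occupational_exposure = as.integer(stats::runif(n) < 39 / 104),
    age = round(pmin(95, pmax(30, stats::rnorm(n, 66, 11))), 1L),
    sex = ifelse(stats::runif(n) < 12 / 104, "F", "M"),
    t_progression = round(pmax(pmin(T_prog, C_prog), 0.01), 2L),
    progression_event = as.integer(T_prog <= C_prog),
    t_recurrence = round(pmax(pmin(T_rec, C_rec), 0.01), 2L),
    recurrence_event = as.integer(T_rec <= C_rec),
    stringsAsFactors = FALSE
  )
  validate_cohort(cohort)
}
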