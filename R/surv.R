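#' Kaplan-Meier product-limit estimate
#'
#' @param times strictly positive follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return A `km_curve`: list with `time` (distinct observed times),
#'   `n_risk`, `n_event`, `n_censor`, `survival`, and totals `n`,
#'   `n_events`. The curve starts at 1 before the first event and is
#'   non-increasing.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
#' km$survival  # 2/3 after t = 1, unchanged at t = 2, 0 after t = 3
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  stopifnot(length(times) == length(events),
            all(events %in% c(0, 1)), all(times > 0))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "none")
  structure(
    list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
         n_censor = sf$n.censor, survival = sf$surv,
         n = length(times), n_events = sum(events)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: n = %d, events = %d\n", x$n, x$n_events))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
             n_censor = x$n_censor, survival = x$survival)
}

#' k-group log-rank test
#'
#' Observed-minus-expected chi-square over distinct event times,
#' supporting any number of groups (the four-subcluster comparison needs
#' k = 4). Wraps [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @param groups group labels, same length as `times`.
#' @return List with `statistic`, `df` (= groups - 1), `p_value`, and
#'   per-group `n`, `observed`, `expected`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 non-empty groups")
  if (sum(events) == 0L) {
    return(list(statistic = 0, df = length(tab) - 1L, p_value = 1,
                n = as.vector(tab), observed = rep(0, length(tab)),
                expected = rep(0, length(tab))))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(tab) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(unname(sd$chisq), df, lower.tail = FALSE),
       n = as.vector(sd$n), observed = as.vector(sd$obs),
       expected = as.vector(sd$exp))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood with Breslow tie handling by default
#' (Efron available). Reports hazard ratios with Wald 95% confidence
#' intervals and flags non-convergence and monotone-likelihood
#' (separation) instead of raising.
#'
#' @inheritParams km_estimate
#' @param covariates numeric matrix or data.frame of covariates (no
#'   constant columns).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `cox_fit`: data.frame with one row per covariate (`coef`,
#'   `se`, `hr`, `hr_lower`, `hr_upper`, `p_value`) and attributes
#'   `loglik`, `iterations`, `converged`, `separation`, `score_test`.
#' @examples
#' coh <- simulate_cohort(n = 300, seed = 2)
#' cox_fit(coh[, c("grade", "hpv_pos")], coh$t_progression,
#'         coh$progression_event)
#' @export
cox_fit <- function(covariates, times, events, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (any(vapply(covariates, function(x) length(unique(x)) == 1L, TRUE))) {
    stop("constant covariate")
  }
  if (sum(events) < 1L) stop("need at least one event")
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  separation <- FALSE
  nonconv <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = ties),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|beta may be", msg)) separation <<- TRUE
      if (grepl("did not converge|out of iterations", msg)) nonconv <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  # monotone partial likelihood drives coefficients off to +/- infinity;
  # a log hazard ratio beyond ~10 on these data sizes is separation
  if (any(abs(co[, "coef"]) > 10)) separation <- TRUE
  out <- data.frame(
    covariate = rownames(co),
    coef = co[, "coef"],
    se = co[, "se(coef)"],
    hr = exp(co[, "coef"]),
    hr_lower = exp(co[, "coef"] - stats::qnorm(0.975) * co[, "se(coef)"]),
    hr_upper = exp(co[, "coef"] + stats::qnorm(0.975) * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("cox_fit", "data.frame"),
            loglik = fit$loglik[2L], iterations = fit$iter,
            converged = !nonconv && !separation,
            separation = separation,
            score_test = unname(fit$score))
}

#' Univariable survival screen
#'
#' One log-rank test per variable against both endpoints (recurrence and
#' progression), mirroring a first-pass marker screen: per-level event
#' counts plus the variable-level log-rank p for each endpoint. Variables
#' constant in the cohort are excluded with a warning.
#'
#' @param cohort validated cohort.
#' @param variables variables to screen; defaults to all markers,
#'   genotypes, grade and stage.
#' @return data.frame with columns `variable`, `level`, `n`,
#'   `recurrence_events`, `progression_events`, `p_recurrence`,
#'   `p_progression` (p on each variable's first row only).
#' @export
univariable_screen <- function(cohort,
                               variables = c(cohort_fields()$markers,
                                             cohort_fields()$genotypes,
                                             "grade", "stage")) {
  rows <- list()
  for (v in variables) {
    vals <- cohort[[v]]
    if (is.null(vals)) stop("unknown variable: ", v)
    if (length(unique(vals)) < 2L) {
      warning("excluding constant variable: ", v)
      next
    }
    p_rec <- logrank_test(cohort$t_recurrence, cohort$recurrence_event,
                          vals)$p_value
    p_prog <- logrank_test(cohort$t_progression, cohort$progression_event,
                           vals)$p_value
    lev <- sort(unique(vals), decreasing = TRUE)
    for (i in seq_along(lev)) {
      sel <- vals == lev[i]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = as.character(lev[i]), n = sum(sel),
        recurrence_events = sum(cohort$recurrence_event[sel]),
        progression_events = sum(cohort$progression_event[sel]),
        p_recurrence = if (i == 1L) p_rec else NA_real_,
        p_progression = if (i == 1L) p_prog else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multivariable Cox model over univariably significant variables
#'
#' Runs the univariable log-rank screen on the progression endpoint and
#' fits one Cox model containing every variable that passes `alpha`
#' (grade and ordinal genotypes enter as numeric codes, stage as its
#' ordered level index).
#'
#' @param cohort validated cohort.
#' @param alpha univariable inclusion threshold (default 0.05).
#' @param variables candidate variables; defaults as in
#'   [univariable_screen()].
#' @return A `cox_fit` over the selected variables, with attribute
#'   `selected` naming them; `NULL` (with a message) when nothing
#'   passes the screen.
#' @export
multivariable_progression <- function(cohort, alpha = 0.05,
                                      variables = c(cohort_fields()$markers,
                                                    cohort_fields()$genotypes,
                                                    "grade", "stage")) {
  scr <- univariable_screen(cohort, variables)
  pp <- scr[!is.na(scr$p_progression), c("variable", "p_progression")]
  keep <- pp$variable[pp$p_progression < alpha]
  if (length(keep) == 0L) {
    message("no variable passes the univariable screen at alpha = ", alpha)
    return(NULL)
  }
  Xc <- lapply(keep, function(v) {
    if (v == "stage") as.integer(factor(cohort$stage, levels = .stage_levels))
    else cohort[[v]]
  })
  names(Xc) <- keep
  fit <- cox_fit(as.data.frame(Xc), cohort$t_progression,
                 cohort$progression_event)
  attr(fit, "selected") <- keep
  fit
}
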