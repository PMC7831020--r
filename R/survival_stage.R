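#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of overall survival with the median survival time
#' (earliest time at which the estimate drops to 0.5 or below; undefined
#' when never reached).
#'
#' @param times follow-up times (months), nonnegative.
#' @param events event indicators (TRUE/1 = death, FALSE/0 = censored).
#' @return An object of class `km_estimate`: `time` and `surv` step-function
#'   vectors, `median` (NA when not reached), `median_reached`, and the
#'   underlying [survival::survfit()] `fit`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1L) stop("need at least one subject")
  if (any(times < 0)) stop("negative survival times")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv,
                 n = length(times), n_events = sum(events),
                 median = med, median_reached = !is.na(med), fit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (x$median_reached) sprintf("%.3g", x$median)
              else "not reached"))
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' Omnibus log-rank chi-square test over k groups (k - 1 degrees of
#' freedom), optionally with unadjusted pairwise log-rank tests between all
#' group pairs, as customarily reported alongside a three-group comparison.
#'
#' @param times,events survival data.
#' @param group group membership (factor or character), each group nonempty.
#' @param pairwise also compute pairwise tests when k > 2.
#' @return list with `statistic`, `df`, `p.value`, and optionally `pairwise`
#'   (data.frame group1, group2, statistic, p.value).
#' @export
logrank_test <- function(times, events, group, pairwise = FALSE) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (any(tabulate(group) == 0L)) stop("a group has no subjects")
  events <- as.integer(as.logical(events))
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  k <- nlevels(group)
  out <- list(statistic = unname(sd$chisq), df = k - 1L,
              p.value = stats::pchisq(sd$chisq, df = k - 1L,
                                      lower.tail = FALSE))
  if (pairwise && k > 2L) {
    prs <- utils::combn(levels(group), 2)
    out$pairwise <- do.call(rbind, apply(prs, 2, function(pp) {
      sel <- group %in% pp
      sub <- survival::survdiff(
        survival::Surv(times[sel], events[sel]) ~ droplevels(group[sel]))
      data.frame(group1 = pp[1], group2 = pp[2],
                 statistic = unname(sub$chisq),
                 p.value = stats::pchisq(sub$chisq, 1, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Cox proportional-hazards regression over stratification factors
#'
#' Fits each factor alone (univariate) or all jointly (multivariate) with
#' Efron handling of tied event times, and reports per-level hazard ratios
#' against the factor's reference level with 95 percent confidence intervals
#' and Wald p-values. Constant covariates raise an error; non-convergence is
#' reported as a warning on the affected fit, never silently passed.
#'
#' @param data data.frame with `os_time`, `event` and factor columns (e.g.
#'   from [build_strata()]).
#' @param factors character vector of factor column names, reference level
#'   first in each factor.
#' @param mode "univariate" or "multivariate".
#' @return data.frame: factor, level, n, hr, ci_low, ci_high, p, mode.
#' @export
cox_regression <- function(data, factors,
                           mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  stopifnot(all(c("os_time", "event") %in% names(data)))
  missing_cols <- setdiff(factors, names(data))
  if (length(missing_cols))
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  for (f in factors) {
    v <- data[[f]][!is.na(data[[f]])]
    if (length(unique(v)) < 2L)
      stop("covariate '", f, "' is constant: no contrast to estimate")
  }
  fit_one <- function(fs) {
    fml <- stats::as.formula(paste(
      "survival::Surv(os_time, as.integer(event)) ~",
      paste(sprintf("`%s`", fs), collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(fml, data = data, ties = "efron"),
      warning = function(w) {
        warning("Cox fit for [", paste(fs, collapse = ", "), "]: ",
                conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    ci <- s$conf.int
    coefs <- s$coefficients
    rows <- lapply(fs, function(f) {
      lv <- levels(droplevels(as.factor(data[[f]])))
      term_names <- paste0("`", f, "`", lv[-1])
      i <- match(term_names, rownames(coefs))
      if (anyNA(i)) i <- match(paste0(f, lv[-1]), rownames(coefs))
      data.frame(factor = f, level = lv[-1],
                 n = as.integer(table(data[[f]])[lv[-1]]),
                 hr = coefs[i, "exp(coef)"],
                 ci_low = ci[i, "lower .95"],
                 ci_high = ci[i, "upper .95"],
                 p = coefs[i, "Pr(>|z|)"],
                 mode = mode, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- if (mode == "univariate")
    do.call(rbind, lapply(factors, fit_one))
  else fit_one(factors)
  rownames(out) <- NULL
  out
}

#' Build stratified survival data from cohort records
#'
#' Merges patient covariates with lesion summaries and derives the
#' dichotomized analysis factors: age and total-volume groups split at the
#' in-sample median (overridable), Ki-67 groups for the primary and the
#' metastasis, lesion-number group, infratentorial involvement (a patient
#' with any infratentorial lesion falls in the "with" group), radiotherapy
#' (WBRT or SRS received) and the treatment category. Median splits place
#' values tied at the median in the upper (">= median") group. Reference
#' levels follow the usual convention: young, female, lung primary, one
#' lesion, small volume, no infratentorial involvement, no radiotherapy.
#'
#' @param records patient covariate data.frame (see [simulate_cohort()]).
#' @param summaries per-patient lesion summaries ([summarize_cohort()]).
#' @param medians optional named list overriding the in-sample medians for
#'   `age`, `tv`, `ki67_primary`, `ki67_bm`.
#' @return data.frame of class `survival_data` with `os_time`, `event` and
#'   the factor columns age_group, sex, primary_group, lung_subtype,
#'   ki67_primary_group, ki67_bm_group, number_group, tv_group,
#'   infratentorial, radiotherapy, treatment_category.
#' @export
build_strata <- function(records, summaries, medians = list()) {
  need <- c("patient_id", "os_time", "event")
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  d <- merge(records, summaries, by = "patient_id", sort = TRUE)

  med_of <- function(name, values) {
    if (!is.null(medians[[name]])) medians[[name]] else
      stats::median(values, na.rm = TRUE)
  }
  split_at <- function(values, med, lo, hi)
    factor(ifelse(values >= med, hi, lo), levels = c(lo, hi))

  d$age_group <- split_at(d$age, med_of("age", d$age),
                          "young", "old")
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$primary_group <- factor(
    ifelse(d$primary_class == "lung", "lung",
           ifelse(d$primary_class == "breast", "breast", "other")),
    levels = c("lung", "breast", "other"))
  d$lung_subtype <- factor(d$lung_subtype)
  if (all(is.na(d$ki67_primary))) {
    warning("Ki-67 (primary) missing for all patients; stratum omitted")
    d$ki67_primary_group <- factor(rep(NA_character_, nrow(d)),
                                   levels = c("low", "high"))
  } else {
    d$ki67_primary_group <- split_at(
      d$ki67_primary, med_of("ki67_primary", d$ki67_primary), "low", "high")
  }
  if (all(is.na(d$ki67_bm))) {
    warning("Ki-67 (metastasis) missing for all patients; stratum omitted")
    d$ki67_bm_group <- factor(rep(NA_character_, nrow(d)),
                              levels = c("low", "high"))
  } else {
    d$ki67_bm_group <- split_at(d$ki67_bm, med_of("ki67_bm", d$ki67_bm),
                                "low", "high")
  }
  d$number_group <- factor(d$number_group, levels = c("1", "2", "3+"))
  # TV median over per-patient total volumes, not over lesions
  d$tv_group <- split_at(d$tv_mm3, med_of("tv", d$tv_mm3), "small", "large")
  d$infratentorial <- factor(
    ifelse(d$infratentorial_involvement, "with", "without"),
    levels = c("without", "with"))
  d$radiotherapy <- factor(
    ifelse(is.na(d$treatments), NA_character_,
           ifelse(grepl("WBRT|SRS", d$treatments), "yes", "no")),
    levels = c("no", "yes"))
  d$treatment_category <- factor(d$treatments,
                                 levels = names(sort(table(d$treatments),
                                                     decreasing = TRUE)))
  class(d) <- c("survival_data", class(d))
  d
}
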