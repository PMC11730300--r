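#' Kaplan-Meier survival curves by group
#'
#' Product-limit estimator per group (ties handled by simultaneous
#' multiplication at the tied time), via [survival::survfit()].
#'
#' @param data Data frame.
#' @param time,event,group Column names for follow-up time (years, >= 0),
#'   event indicator (0/1) and group label (`NULL` for a single curve).
#' @return Object of class `ecgage_km`: list with `curves` (tibble: `group`,
#'   `time`, `n_risk`, `n_event`, `surv`) and the underlying `survfit`
#'   object. `tidy()` returns the tibble; `autoplot()` draws step curves.
#' @export
km_estimate <- function(data, time = "time_years", event = "died",
                        group = "group") {
  stopifnot(is.data.frame(data), time %in% names(data), event %in% names(data))
  tt <- data[[time]]
  if (any(tt < 0, na.rm = TRUE)) abort("negative follow-up times.")
  has_group <- !is.null(group) && group %in% names(data)
  df <- data.frame(.time = tt, .event = data[[event]])
  df$.group <- if (has_group) factor(data[[group]]) else factor("all")
  fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(df$.group), length(sm$time)) else
    sub("^\\.group=", "", as.character(sm$strata))
  curves <- tibble::tibble(group = grp, time = sm$time, n_risk = sm$n.risk,
                           n_event = sm$n.event, surv = sm$surv)
  structure(list(curves = curves, fit = fit), class = "ecgage_km")
}

#' @export
print.ecgage_km <- function(x, ...) {
  cat("<ecgage_km>\n"); print(x$fit); invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ecgage_km <- function(x, ...) x$curves

# Wald 95% intervals and p-values on the exponentiated-coefficient scale.
effect_table <- function(fit, n, model_label, estimate_label) {
  cf <- summary(fit)$coefficients
  se_col <- grep("^(se\\(coef\\)|Std\\. Error)$", colnames(cf))
  p_col <- grep("^Pr\\(", colnames(cf))
  z <- qnorm(0.975)
  out <- tibble::tibble(
    model = model_label,
    term = rownames(cf),
    estimate = unname(exp(cf[, 1])),
    ci_low = unname(exp(cf[, 1] - z * cf[, se_col])),
    ci_high = unname(exp(cf[, 1] + z * cf[, se_col])),
    p = unname(cf[, p_col[length(p_col)]]),
    n = n,
    type = estimate_label
  )
  out[out$term != "(Intercept)", ]
}

#' Cox proportional-hazards ratios for aging-effect groups
#'
#' Partial-likelihood fit (Breslow tie handling by default) of follow-up time
#' on the aging-effect group with optional covariate adjustment; reports
#' exponentiated coefficients with Wald 95% confidence intervals and
#' p-values. The reference level is "Correct prediction".
#'
#' @param data Data frame (typically one row per subject, e.g. the baseline
#'   exam rows of a cohort table).
#' @param group Column with the aging-effect group.
#' @param covariates Character vector of adjustment columns (may be empty).
#' @param time,event Column names for time and event indicator.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param ref Reference level of the group factor.
#' @return Object of class `ecgage_cox`: `estimates` tibble (`term`, `estimate`
#'   = HR, `ci_low`, `ci_high`, `p`, `n`) and the `coxph` fit. A failed or
#'   non-converged fit raises an error with diagnostics. `tidy()` returns the
#'   estimate table, `glance()` the fit summary.
#' @export
cox_hr <- function(data, group = "group", covariates = character(0),
                   time = "time_years", event = "died",
                   ties = c("breslow", "efron"), ref = "Correct prediction") {
  ties <- match.arg(ties)
  stopifnot(all(c(group, covariates, time, event) %in% names(data)))
  df <- as.data.frame(data)
  df[[group]] <- relevel(factor(df[[group]]), ref = ref)
  ev_by_group <- tapply(df[[event]], df[[group]], sum)
  if (any(is.na(ev_by_group)) || any(ev_by_group == 0)) {
    abort("need at least one event in every group.")
  }
  rhs <- paste(c(sprintf("`%s`", group), sprintf("`%s`", covariates)),
               collapse = " + ")
  fml <- as.formula(sprintf("survival::Surv(`%s`, `%s`) ~ %s", time, event, rhs))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = ties),
    error = function(e) abort(paste("Cox fit failed:", conditionMessage(e)))
  )
  if (!is.null(fit$info) || any(!is.finite(coef(fit)))) {
    abort("Cox fit did not converge (non-finite coefficients).")
  }
  est <- effect_table(fit, nrow(df), "cox", "HR")
  est$term <- sub(sprintf("^`?%s`?", group), "", est$term)
  structure(list(estimates = est, fit = fit, group_counts = table(df[[group]])),
            class = "ecgage_cox")
}

#' @export
print.ecgage_cox <- function(x, ...) {
  cat("<ecgage_cox> hazard ratios (ref: Correct prediction)\n")
  print(x$estimates); invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ecgage_cox <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.ecgage_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(n = s$n, n_event = s$nevent,
                 concordance = unname(s$concordance[1]))
}

#' Logistic-regression odds ratios for aging-effect groups
#'
#' Maximum-likelihood logistic fit of a binary outcome on the aging-effect
#' group (reference "Correct prediction") with covariate adjustment; Wald 95%
#' confidence intervals. With `stratify_by_sex = TRUE`, two independent fits
#' are run (one per sex) with `sex` removed from the covariates.
#'
#' @param data Data frame.
#' @param outcome Binary outcome column (0/1).
#' @param group Aging-effect group column.
#' @param covariates Adjustment columns.
#' @param stratify_by_sex Fit females and males separately.
#' @return Object of class `ecgage_logistic` with an `estimates` tibble
#'   (`model`, `term`, `estimate` = OR, `ci_low`, `ci_high`, `p`, `n`) and the
#'   fit(s). Perfect separation (non-converged or exploding estimates) raises
#'   an error.
#' @export
logistic_or <- function(data, outcome, group = "group",
                        covariates = character(0), stratify_by_sex = FALSE) {
  stopifnot(all(c(outcome, group, covariates) %in% names(data)))
  df <- as.data.frame(data)
  y <- df[[outcome]]
  if (!all(y %in% c(0, 1, NA))) abort("`outcome` must be binary 0/1.")
  df[[group]] <- relevel(factor(df[[group]]), ref = "Correct prediction")

  fit_one <- function(d, covs, label) {
    ev <- tapply(d[[outcome]], d[[group]], sum)
    if (any(is.na(ev)) || any(ev == 0)) {
      abort(sprintf("no events in some group (%s model).", label))
    }
    rhs <- paste(c(sprintf("`%s`", group), sprintf("`%s`", covs)),
                 collapse = " + ")
    fml <- as.formula(sprintf("`%s` ~ %s", outcome, rhs))
    fit <- glm(fml, data = d, family = binomial())
    if (!fit$converged || any(abs(coef(fit)) > 15)) {
      abort(sprintf("logistic fit flagged as separated/non-converged (%s).",
                    label))
    }
    est <- effect_table(fit, nrow(d), label, "OR")
    est$term <- sub(sprintf("^`?%s`?", group), "", est$term)
    list(est = est, fit = fit)
  }

  if (stratify_by_sex) {
    stopifnot("sex" %in% names(df))
    covs <- setdiff(covariates, "sex")
    fits <- lapply(split(df, df$sex), function(d) {
      fit_one(d, covs, paste0("logistic_", unique(d$sex)))
    })
    est <- dplyr::bind_rows(lapply(fits, `[[`, "est"))
    fitobj <- lapply(fits, `[[`, "fit")
  } else {
    one <- fit_one(df, covariates, "logistic")
    est <- one$est; fitobj <- one$fit
  }
  structure(list(estimates = est, fit = fitobj, outcome = outcome),
            class = "ecgage_logistic")
}

#' @export
print.ecgage_logistic <- function(x, ...) {
  cat("<ecgage_logistic> odds ratios for", x$outcome, "\n")
  print(x$estimates); invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ecgage_logistic <- function(x, ...) x$estimates

#' Serial-ECG mortality analysis with label-leakage guard
#'
#' Fits three Cox models on subjects with both exams: *Baseline* (group from
#' exam 0, clock starting at exam 0), *Follow-up* (group from exam 1, clock
#' starting at exam 1) and *Serial* (ordered group pair from both exams,
#' reference "Correct prediction, correct prediction", clock starting at exam
#' 1). Subjects who die before the follow-up exam cannot contribute a
#' follow-up ECG and are excluded from the Follow-up and Serial models. The
#' leakage guard asserts that no subject contributes follow-up time accrued
#' before their group-defining exam: every time-at-risk is the death-or-censor
#' time minus the exam time and must be nonnegative.
#'
#' @param cohort Cohort tibble (both exam rows per subject) with
#'   `subject_id`, `exam`, `exam_years`, `time_years`, `died` and covariates.
#' @param predictions Tibble with `subject_id`, `exam`, `group` (e.g. from
#'   [delta_and_validate()] predictions or the cohort's `true_group`).
#' @param covariates Adjustment columns (taken from the baseline exam row).
#' @param min_category_n Serial pair categories with fewer subjects are
#'   dropped (reported in `dropped_categories`).
#' @return Object of class `ecgage_serial`: `estimates` (combined tidy tibble
#'   for the three models), `category_n` (serial pair counts), `data` (the
#'   per-subject analysis table) and `dropped_categories`.
#' @export
serial_hr_analysis <- function(cohort, predictions, covariates = character(0),
                               min_category_n = 2) {
  stopifnot(all(c("subject_id", "exam", "exam_years", "time_years", "died")
                %in% names(cohort)))
  both <- intersect(
    cohort$subject_id[cohort$exam == 0],
    cohort$subject_id[cohort$exam == 1]
  )
  dropped <- setdiff(unique(cohort$subject_id), both)
  if (length(dropped) > 0) {
    message(sprintf("serial_hr_analysis: %d subjects without both exams dropped",
                    length(dropped)))
  }
  pr <- serial_group(predictions[predictions$subject_id %in% both, ])

  base <- cohort[cohort$exam == 0 & cohort$subject_id %in% both, ]
  fup <- cohort[cohort$exam == 1 & cohort$subject_id %in% both, ]
  d <- dplyr::left_join(
    dplyr::select(base, "subject_id", "time_years", "died",
                  dplyr::all_of(covariates)),
    dplyr::select(fup, "subject_id", exam1_years = "exam_years"),
    by = "subject_id"
  )
  d <- dplyr::left_join(d, pr, by = "subject_id")
  d$time_from_exam1 <- d$time_years - d$exam1_years

  # label-leakage guard: the clock of any model keyed to the follow-up exam
  # starts there; nobody may contribute time accrued before it
  if (any(d$time_from_exam1 < 0)) {
    abort("leakage guard tripped: follow-up time before the group-defining exam.")
  }

  fit_cox <- function(df, group_col, time_col, label, ref) {
    df$.t <- df[[time_col]]
    cx <- cox_hr(df, group = group_col, covariates = covariates,
                 time = ".t", event = "died", ref = ref)
    est <- cx$estimates
    est$model <- label
    est
  }

  est_base <- fit_cox(d, "baseline_group", "time_years", "baseline",
                      "Correct prediction")

  cat_n <- dplyr::summarise(dplyr::group_by(d, .data$pair),
                            n = dplyr::n(), events = sum(.data$died),
                            .groups = "drop")
  # a category is estimable only with enough subjects and at least one event
  keep_pairs <- cat_n$pair[cat_n$n >= min_category_n & cat_n$events >= 1]
  ds <- d[d$pair %in% keep_pairs, ]

  est_fup <- fit_cox(d, "followup_group", "time_from_exam1", "followup",
                     "Correct prediction")
  est_serial <- fit_cox(ds, "pair", "time_from_exam1", "serial",
                        "Correct prediction, correct prediction")

  structure(
    list(estimates = dplyr::bind_rows(est_base, est_fup, est_serial),
         category_n = cat_n, data = d,
         dropped_categories = setdiff(cat_n$pair, keep_pairs),
         dropped_subjects = dropped),
    class = "ecgage_serial"
  )
}

#' @export
print.ecgage_serial <- function(x, ...) {
  cat("<ecgage_serial> baseline / follow-up / serial hazard ratios\n")
  print(x$estimates); invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ecgage_serial <- function(x, ...) x$estimates

#' Benjamini-Hochberg adjustment helper
#'
#' Convenience wrapper adding a BH-adjusted p-value column to a tidy estimate
#' table. Off by default everywhere: per-outcome p-values are reported
#' unadjusted, matching standard epidemiological presentation.
#'
#' @param estimates A tidy estimate tibble with a `p` column.
#' @return The tibble with an extra `p_adj` column.
#' @export
adjust_bh <- function(estimates) {
  stopifnot("p" %in% names(estimates))
  estimates$p_adj <- stats::p.adjust(estimates$p, method = "BH")
  estimates
}
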