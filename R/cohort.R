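#' Configuration for the synthetic longitudinal ECG cohort
#'
#' Collects every generator parameter with defaults that emulate a
#' population-based screening cohort: two exams per subject 5-6 years apart,
#' covariate prevalences of the order seen in such cohorts, a three-component
#' latent aging-offset mixture giving roughly equal delta-age groups, and
#' exponential proportional-hazards survival over up to 21 years of
#' follow-up keyed to the latent baseline aging-effect group.
#'
#' @param n_subjects Number of subjects.
#' @param seed Master seed; all output is a pure function of the config.
#' @param exam_gap_range Uniform range (years) between baseline and follow-up.
#' @param fs,record_duration_s Waveform parameters.
#' @param noise_sd Additive white-noise sd in mV: a scalar for uniform record
#'   quality, or a length-2 range from which each record draws its own noise
#'   level (variable signal quality across recordings).
#' @param age_range Baseline chronological age range (uniform).
#' @param prob_female Probability of female sex.
#' @param covariate_prevalence Named Bernoulli prevalences for hypertension,
#'   hyperlipidemia, diabetes, beta_blocker, calcium_channel_blocker,
#'   antiarrhythmic.
#' @param outcome_prevalence Baseline prevalences of AF/HF/MI.
#' @param outcome_or_over,outcome_or_under Conditional odds ratios applied to
#'   the outcome logits for latent Over-/Underestimation subjects.
#' @param incidence_rate Baseline inter-exam incidence probabilities.
#' @param outcome_age_coef Logit slope per year of age for outcomes.
#' @param group_multipliers Hazard multipliers by latent baseline group
#'   (Overestimation / Correct prediction / Underestimation).
#' @param serial_multipliers Hazard multipliers by latent (baseline,
#'   follow-up) group pair, used when `hazard_scope = "serial"`.
#' @param hazard_scope `"baseline"` (hazard keyed to the baseline latent
#'   group) or `"serial"` (keyed to the pair, so consistent groups carry
#'   their own risk).
#' @param baseline_hazard Baseline hazard rate (events/year).
#' @param hazard_age_coef,hazard_sex_male Log-hazard slopes for age (per
#'   year, centred at 55) and male sex.
#' @param covariate_hr Named hazard multipliers for comorbidity flags.
#' @param max_followup_years Administrative censoring horizon.
#' @param mixture_weights,mixture_means,mixture_sds Aging-offset mixture
#'   (years): Overestimation N(+14, 4), Correct N(0, 5), Underestimation
#'   N(-14, 4) at equal weights by default, which clears the +-8 y grouping
#'   threshold with margin.
#' @param transient_sd Sd (years) of the per-exam transient added to the
#'   persistent offset when forming latent per-exam groups; emulates the
#'   exam-to-exam wobble of a model with a high single-exam MAE.
#' @param jitter_sd Morphology jitter sd (ms) passed to
#'   [morphology_from_age()].
#' @param generate_ecgs Generate waveforms (`TRUE`) or the cohort table only.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          seed = 1L,
                          exam_gap_range = c(5, 6),
                          fs = 400,
                          record_duration_s = 10,
                          noise_sd = 0.02,
                          age_range = c(38, 72),
                          prob_female = 0.52,
                          covariate_prevalence = c(
                            hypertension = 0.48, hyperlipidemia = 0.35,
                            diabetes = 0.10, beta_blocker = 0.15,
                            calcium_channel_blocker = 0.08,
                            antiarrhythmic = 0.02),
                          outcome_prevalence = c(af = 0.02, hf = 0.05, mi = 0.03),
                          outcome_or_over = c(af = 2.5, hf = 1.4, mi = 1.3),
                          outcome_or_under = c(af = 0.4, hf = 0.8, mi = 0.6),
                          incidence_rate = c(af = 0.025, hf = 0.035, mi = 0.025),
                          outcome_age_coef = 0.04,
                          group_multipliers = c(
                            "Overestimation" = 1.4,
                            "Correct prediction" = 1.0,
                            "Underestimation" = 0.65),
                          serial_multipliers = NULL,
                          hazard_scope = c("baseline", "serial"),
                          baseline_hazard = 0.012,
                          hazard_age_coef = 0.07,
                          hazard_sex_male = 0.4,
                          covariate_hr = c(hypertension = 1.4, diabetes = 1.6),
                          max_followup_years = 21,
                          mixture_weights = c(over = 1, correct = 1, under = 1) / 3,
                          mixture_means = c(over = 14, correct = 0, under = -14),
                          mixture_sds = c(over = 4, correct = 5, under = 4),
                          transient_sd = 6,
                          jitter_sd = 5,
                          generate_ecgs = TRUE) {
  hazard_scope <- match.arg(hazard_scope)
  if (is.null(serial_multipliers)) serial_multipliers <- default_serial_multipliers()
  stopifnot(n_subjects >= 0,
            length(noise_sd) %in% 1:2, all(noise_sd >= 0),
            all(covariate_prevalence >= 0 & covariate_prevalence <= 1),
            all(outcome_prevalence >= 0 & outcome_prevalence <= 1),
            all(group_multipliers > 0), all(serial_multipliers > 0),
            baseline_hazard >= 0, max_followup_years > 0,
            all(mixture_weights >= 0), sum(mixture_weights) > 0)
  cfg <- as.list(environment())
  cfg$mixture_weights <- mixture_weights / sum(mixture_weights)
  structure(cfg, class = "cohort_config")
}

# Hazard multipliers for (baseline, follow-up) latent group pairs under the
# consistency-dependent hazard model; consistent pairs carry their own risk.
default_serial_multipliers <- function() {
  c("Overestimation, overestimation" = 1.65,
    "Correct prediction, overestimation" = 1.52,
    "Overestimation, correct prediction" = 1.34,
    "Underestimation, underestimation" = 0.68,
    "Correct prediction, underestimation" = 0.91,
    "Underestimation, correct prediction" = 1.41,
    "Correct prediction, correct prediction" = 1.0,
    "Overestimation, underestimation" = 1.0,
    "Underestimation, overestimation" = 1.0)
}

pair_key <- function(g0, g1) {
  paste0(as.character(g0), ", ", tolower(as.character(g1)))
}

#' Simulate a longitudinal two-exam ECG cohort
#'
#' Draws per-subject demographics, a persistent latent aging offset from the
#' configured mixture, per-exam latent delta-age (offset plus transient),
#' comorbidity and outcome flags whose odds depend on the latent baseline
#' group, and exponential survival with administrative censoring whose hazard
#' is keyed to the latent group (or group pair). Optionally synthesises one
#' 12-lead ECG per subject and exam whose morphology reflects the biological
#' age (chronological age + persistent offset). Follow-up rows exist only for
#' subjects alive at the follow-up exam.
#'
#' @param config A [cohort_config()].
#' @return A list of class `ecg_cohort`: `cohort` (tibble, one row per exam)
#'   and `records` (list of [ecg_record()], or `NULL` when
#'   `generate_ecgs = FALSE`), plus the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  set.seed(config$seed)
  if (n == 0) {
    return(structure(list(cohort = empty_cohort_table(),
                          records = if (config$generate_ecgs) list() else NULL,
                          config = config),
                     class = "ecg_cohort"))
  }
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)

  id <- sprintf("S%05d", seq_len(n))
  sex <- ifelse(runif(n) < config$prob_female, "female", "male")
  age0 <- runif(n, config$age_range[1], config$age_range[2])
  gap <- runif(n, config$exam_gap_range[1], config$exam_gap_range[2])

  comp <- sample(names(config$mixture_weights), n, replace = TRUE,
                 prob = config$mixture_weights)
  offset <- rnorm(n, config$mixture_means[comp], config$mixture_sds[comp])
  delta0 <- offset + rnorm(n, 0, config$transient_sd)
  delta1 <- offset + rnorm(n, 0, config$transient_sd)
  g0 <- classify_aging(delta0)
  g1 <- classify_aging(delta1)

  cov <- sapply(names(config$covariate_prevalence), function(cv) {
    rbinom(n, 1, config$covariate_prevalence[cv])
  })

  logit_p <- function(base, or_over, or_under) {
    plogis(qlogis(base) +
             log(or_over) * (g0 == "Overestimation") +
             log(or_under) * (g0 == "Underestimation") +
             config$outcome_age_coef * (age0 - 55))
  }
  prev <- sapply(names(config$outcome_prevalence), function(oc) {
    rbinom(n, 1, logit_p(config$outcome_prevalence[oc],
                         config$outcome_or_over[oc],
                         config$outcome_or_under[oc]))
  })
  inc <- sapply(names(config$incidence_rate), function(oc) {
    raw <- rbinom(n, 1, logit_p(config$incidence_rate[oc],
                                config$outcome_or_over[oc],
                                config$outcome_or_under[oc]))
    as.integer(raw == 1 & prev[, oc] == 0)   # incidence implies prior absence
  })

  mult <- if (config$hazard_scope == "baseline") {
    unname(config$group_multipliers[as.character(g0)])
  } else {
    unname(config$serial_multipliers[pair_key(g0, g1)])
  }
  hz <- config$baseline_hazard * mult *
    exp(config$hazard_age_coef * (age0 - 55)) *
    exp(config$hazard_sex_male * (sex == "male"))
  for (cv in names(config$covariate_hr)) {
    hz <- hz * config$covariate_hr[cv]^cov[, cv]
  }
  death_time <- ifelse(hz > 0, rexp(n, pmax(hz, 1e-300)), Inf)
  died <- as.integer(death_time <= config$max_followup_years)
  time_years <- pmin(death_time, config$max_followup_years)
  alive_at_followup <- death_time > gap

  subj <- tibble::tibble(
    subject_id = id, sex = sex, aging_offset = offset,
    mixture_component = comp, exam_gap = gap,
    tibble::as_tibble(cov),
    af_prevalent0 = prev[, "af"], hf_prevalent0 = prev[, "hf"],
    mi_prevalent0 = prev[, "mi"],
    af_incident = inc[, "af"], hf_incident = inc[, "hf"],
    mi_incident = inc[, "mi"],
    died = died, time_years = time_years,
    death_time = ifelse(died == 1, death_time, NA_real_),
    censor_time = config$max_followup_years,
    subject_seed = subject_seeds
  )

  row_for_exam <- function(e) {
    keep <- if (e == 0) rep(TRUE, n) else alive_at_followup
    d <- subj[keep, ]
    d$exam <- e
    d$exam_years <- if (e == 0) 0 else d$exam_gap
    d$age_at_exam <- age0[keep] + d$exam_years
    d$delta_latent <- if (e == 0) delta0[keep] else delta1[keep]
    d$true_group <- if (e == 0) g0[keep] else g1[keep]
    d$af_prevalent <- if (e == 0) d$af_prevalent0 else
      as.integer(d$af_prevalent0 | d$af_incident)
    d$hf_prevalent <- if (e == 0) d$hf_prevalent0 else
      as.integer(d$hf_prevalent0 | d$hf_incident)
    d$mi_prevalent <- if (e == 0) d$mi_prevalent0 else
      as.integer(d$mi_prevalent0 | d$mi_incident)
    d
  }
  cohort <- dplyr::bind_rows(row_for_exam(0), row_for_exam(1))
  cohort <- dplyr::arrange(cohort, .data$subject_id, .data$exam)
  cohort <- dplyr::select(cohort, "subject_id", "exam", "exam_years",
                          "age_at_exam", "sex", "aging_offset",
                          "mixture_component", "delta_latent", "true_group",
                          dplyr::all_of(names(config$covariate_prevalence)),
                          "af_prevalent", "hf_prevalent", "mi_prevalent",
                          "af_incident", "hf_incident", "mi_incident",
                          "died", "time_years", "death_time", "censor_time",
                          "subject_seed")

  records <- NULL
  if (config$generate_ecgs) {
    records <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      ro <- cohort[i, ]
      set.seed((ro$subject_seed + ro$exam) %% .Machine$integer.max)
      bio <- min(max(ro$age_at_exam + ro$aging_offset, 18), 100)
      m <- morphology_from_age(bio, ro$sex, jitter_sd = config$jitter_sd)
      nsd <- if (length(config$noise_sd) == 2) {
        runif(1, config$noise_sd[1], config$noise_sd[2])
      } else config$noise_sd
      records[[i]] <- simulate_ecg(
        m, fs = config$fs, duration_s = config$record_duration_s,
        noise_sd = nsd, subject_id = ro$subject_id,
        exam = ro$exam, age_at_exam = ro$age_at_exam, sex = ro$sex)
    }
    names(records) <- paste0(cohort$subject_id, "_e", cohort$exam)
  }
  cohort$subject_seed <- NULL
  structure(list(cohort = cohort, records = records, config = config),
            class = "ecg_cohort")
}

empty_cohort_table <- function() {
  tibble::tibble(
    subject_id = character(0), exam = integer(0), exam_years = numeric(0),
    age_at_exam = numeric(0), sex = character(0), aging_offset = numeric(0),
    mixture_component = character(0), delta_latent = numeric(0),
    true_group = factor(character(0), levels = AGING_GROUPS),
    hypertension = integer(0), hyperlipidemia = integer(0),
    diabetes = integer(0), beta_blocker = integer(0),
    calcium_channel_blocker = integer(0), antiarrhythmic = integer(0),
    af_prevalent = integer(0), hf_prevalent = integer(0),
    mi_prevalent = integer(0), af_incident = integer(0),
    hf_incident = integer(0), mi_incident = integer(0),
    died = integer(0), time_years = numeric(0), death_time = numeric(0),
    censor_time = numeric(0)
  )
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("<ecg_cohort> %d subjects, %d exam rows%s\n",
              dplyr::n_distinct(x$cohort$subject_id), nrow(x$cohort),
              if (is.null(x$records)) " (no waveforms)" else
                sprintf(", %d ECG records", length(x$records))))
  invisible(x)
}
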