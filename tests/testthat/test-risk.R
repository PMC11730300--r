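test_that("Kaplan-Meier equals hand-computed product-limit values", {
  # classic mixed-censoring fixture; expected survival computed by hand from
  # the product-limit definition: S(t) = prod (1 - d_i / n_i)
  df <- tibble::tibble(
    time = c(1, 2, 3, 3, 4, 5, 6, 7, 8, 9),
    died = c(1, 0, 1, 1, 0, 1, 0, 1, 0, 0)
  )
  km <- km_estimate(df, time = "time", event = "died", group = NULL)
  cv <- tidy(km)
  s_at <- function(t) cv$surv[cv$time == t]
  expect_equal(s_at(1), 0.9)                     # 1 - 1/10
  expect_equal(s_at(3), 0.9 * 6 / 8)             # two tied deaths, n = 8
  expect_equal(s_at(5), 0.9 * 6 / 8 * 4 / 5)
  expect_equal(s_at(7), 0.9 * 6 / 8 * 4 / 5 * 2 / 3)
  expect_true(all(diff(cv$surv) <= 1e-12))       # nonincreasing
})

test_that("KM reduces to the ECDF complement without censoring", {
  df <- tibble::tibble(time = c(1, 2, 3, 4), died = 1)
  cv <- tidy(km_estimate(df, time = "time", event = "died", group = NULL))
  expect_equal(cv$surv, c(0.75, 0.5, 0.25, 0))
  allc <- tibble::tibble(time = c(2, 5, 9), died = 0)
  cvc <- tidy(km_estimate(allc, time = "time", event = "died", group = NULL))
  expect_true(all(cvc$surv == 1))
  expect_error(km_estimate(tibble::tibble(time = -1, died = 1),
                           time = "time", event = "died", group = NULL),
               "negative")
})

test_that("unadjusted logistic OR equals the contingency cross-product", {
  df <- tibble::tibble(
    group = rep(c("Overestimation", "Correct prediction"), each = 100),
    y = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  )
  or <- tidy(logistic_or(df, outcome = "y"))
  expect_equal(or$estimate[or$term == "Overestimation"],
               (30 * 90) / (70 * 10), tolerance = 1e-7)
})

test_that("Cox point estimates are invariant to row duplication", {
  set.seed(15)
  n <- 400
  df <- tibble::tibble(
    group = sample(c("Correct prediction", "Overestimation"), n, TRUE),
    time_years = rexp(n, 0.1 * ifelse(group == "Overestimation", 1.5, 1)),
    died = 1
  )
  fit1 <- tidy(cox_hr(df))
  fit2 <- tidy(cox_hr(dplyr::bind_rows(df, df)))
  expect_equal(fit1$estimate, fit2$estimate, tolerance = 1e-6)
  expect_lt(fit2$ci_high[1] - fit2$ci_low[1],
            fit1$ci_high[1] - fit1$ci_low[1])    # CIs shrink
})

test_that("Cox recovers a known two-group hazard ratio", {
  set.seed(16)
  n <- 2000
  g <- rep(c("Correct prediction", "Overestimation"), each = n / 2)
  rate <- 0.05 * ifelse(g == "Overestimation", 1.5, 1)
  t <- rexp(n, rate)
  cens <- 12                                    # ~40-50% events
  df <- tibble::tibble(group = g, time_years = pmin(t, cens),
                       died = as.integer(t <= cens))
  est <- tidy(cox_hr(df))
  expect_true(est$ci_low[1] < 1.5 & 1.5 < est$ci_high[1])
})

test_that("fit guards: missing events, separation, bad outcomes", {
  df <- tibble::tibble(
    group = rep(c("Correct prediction", "Overestimation"), each = 10),
    time_years = rexp(20, 0.1),
    died = c(rep(1, 10), rep(0, 10))
  )
  expect_error(cox_hr(df), "event in every group")
  df2 <- tibble::tibble(
    group = rep(c("Correct prediction", "Overestimation"), each = 20),
    y = c(rbinom(20, 1, 0.5), rep(1, 20))       # separation in one group
  )
  expect_error(logistic_or(df2, outcome = "y"), "separated|events")
  df3 <- df2; df3$y[1] <- 2
  expect_error(logistic_or(df3, outcome = "y"), "binary")
})

test_that("sex-stratified logistic fits drop sex from the covariates", {
  cfg <- cohort_config(n_subjects = 8000, seed = 17, generate_ecgs = FALSE)
  base <- dplyr::filter(simulate_cohort(cfg)$cohort, exam == 0)
  lo <- logistic_or(base, outcome = "hf_prevalent", group = "true_group",
                    covariates = c("age_at_exam", "sex"), stratify_by_sex = TRUE)
  est <- tidy(lo)
  expect_setequal(unique(est$model), c("logistic_female", "logistic_male"))
  expect_false(any(grepl("sex", est$term)))
})

test_that("serial analysis anchors the clock at the follow-up exam", {
  cfg <- cohort_config(n_subjects = 3000, seed = 18, generate_ecgs = FALSE,
                       hazard_scope = "serial")
  co <- simulate_cohort(cfg)$cohort
  pr <- dplyr::transmute(co, subject_id, exam, group = true_group)
  sa <- suppressMessages(serial_hr_analysis(co, pr))
  # leakage guard: time at risk nonnegative and equal to total minus exam-1
  expect_true(all(sa$data$time_from_exam1 >= 0))
  expect_equal(sa$data$time_from_exam1,
               sa$data$time_years - sa$data$exam1_years)
  # subjects dying before exam 1 are not in the serial data
  base <- dplyr::filter(co, exam == 0)
  early <- base$subject_id[!is.na(base$death_time) &
                             base$death_time <= base$exam_years + 5]
  expect_length(intersect(early, sa$data$subject_id), 0)
  # all three models present
  expect_setequal(unique(tidy(sa)$model), c("baseline", "followup", "serial"))
})

test_that("a transition-free cohort has no transition categories", {
  cfg <- cohort_config(n_subjects = 800, seed = 19, generate_ecgs = FALSE,
                       transient_sd = 0, mixture_sds = c(over = 0.1,
                                                         correct = 0.1,
                                                         under = 0.1))
  co <- simulate_cohort(cfg)$cohort
  pr <- dplyr::transmute(co, subject_id, exam, group = true_group)
  sa <- suppressMessages(serial_hr_analysis(co, pr))
  expect_true(all(sa$category_n$pair %in% c(
    "Correct prediction, correct prediction",
    "Overestimation, overestimation",
    "Underestimation, underestimation")))
})

test_that("BH helper adds adjusted p-values without altering the input", {
  est <- tibble::tibble(p = c(0.01, 0.02, 0.5))
  out <- adjust_bh(est)
  expect_equal(out$p, est$p)
  expect_equal(out$p_adj, stats::p.adjust(est$p, "BH"))
})
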