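test_that("surrogate gradients agree with central finite differences", {
  mod <- get_surrogate()
  set.seed(21)
  for (rep in 1:2) {
    m <- morphology_from_age(runif(1, 40, 80), sample(c("female", "male"), 1))
    r <- simulate_ecg(m, fs = 400, duration_s = 10, noise_sd = 0.02,
                      seed = 50 + rep)
    g <- mod$gradient(r)
    h <- 1e-3
    for (k in 1:5) {
      j <- sample(12, 1); idx <- sample(ncol(r$signals), 1)
      rp <- r; rp$signals[j, idx] <- rp$signals[j, idx] + h
      rm <- r; rm$signals[j, idx] <- rm$signals[j, idx] - h
      fd <- (mod$predict(rp) - mod$predict(rm)) / (2 * h)
      if (abs(fd) > 1e-6 || abs(g[j, idx]) > 1e-6) {
        expect_lt(abs(fd - g[j, idx]) / max(abs(fd), abs(g[j, idx])), 1e-3)
      }
    }
  }
})

test_that("calibrated surrogate recovers biological age on clean records", {
  mod <- get_surrogate()
  # deterministic morphology (jitter off, noise free): per-subject error
  for (a in c(45, 50, 65)) {
    for (sx in c("female", "male")) {
      r <- make_clean_record(age = a, sex = sx, hr = 62)
      expect_lt(abs(mod$predict(r) - a), 3)
    }
  }
  # model is deterministic
  r <- make_clean_record(age = 58)
  expect_identical(mod$predict(r), mod$predict(r))
  # fs contract
  r200 <- make_clean_record(fs = 200, duration = 8)
  expect_error(mod$predict(r200), "fs")
})

test_that("most subjects recover their generator-intended group", {
  mod <- get_surrogate()
  set.seed(31)
  n_ok <- 0; n <- 66
  offs <- rep(c(14, 0, -14), length.out = n)
  for (i in seq_len(n)) {
    chron <- runif(1, 40, 75)
    m <- morphology_from_age(min(chron + offs[i], 100),
                             sample(c("female", "male"), 1))
    r <- simulate_ecg(m, fs = 400, duration_s = 10, noise_sd = 0)
    g <- classify_aging(mod$predict(r) - chron)
    want <- classify_aging(offs[i])
    n_ok <- n_ok + (g == want)
  }
  expect_gte(n_ok / n, 0.85)
})

test_that("delta-age grouping uses strict outer and closed inner bounds", {
  # worked examples: 51 -> 72 and 52 -> 41
  expect_equal(as.character(classify_aging(72 - 51)), "Overestimation")
  expect_equal(as.character(classify_aging(41 - 52)), "Underestimation")
  # boundary belongs to the middle class
  expect_equal(as.character(classify_aging(8)), "Correct prediction")
  expect_equal(as.character(classify_aging(-8)), "Correct prediction")
  expect_equal(as.character(classify_aging(8.0001)), "Overestimation")
  expect_error(classify_aging(NaN), "finite")
})

test_that("grouping is mirror-symmetric off the boundary", {
  set.seed(1)
  d <- runif(50, -30, 30)
  d <- d[abs(abs(d) - 8) > 1e-6]
  flip <- c("Overestimation" = "Underestimation",
            "Underestimation" = "Overestimation",
            "Correct prediction" = "Correct prediction")
  expect_equal(unname(flip[as.character(classify_aging(d))]),
               as.character(classify_aging(-d)))
})

test_that("age-range filter keeps the closed interval", {
  co <- tibble::tibble(age_at_exam = c(39.9, 40, 75, 75.1))
  expect_message(out <- filter_age_range(co), "kept 2 of 4")
  expect_equal(out$age_at_exam, c(40, 75))
  expect_equal(nrow(suppressMessages(filter_age_range(co[0, ]))), 0)
  allin <- tibble::tibble(age_at_exam = c(50, 60))
  expect_equal(suppressMessages(filter_age_range(allin)), allin)
})

test_that("validation metrics match a spreadsheet-style recomputation", {
  df <- tibble::tibble(chronological_age = c(40, 50, 60, 70),
                       predicted_age = c(50, 48, 75, 66))
  v <- delta_and_validate(df)
  # independent recomputation from the definitions
  d <- df$predicted_age - df$chronological_age
  mae <- sum(abs(d)) / 4
  xc <- df$chronological_age - mean(df$chronological_age)
  yc <- df$predicted_age - mean(df$predicted_age)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  expect_equal(v$metrics$mae, mae)
  expect_equal(v$metrics$r, r)
  expect_equal(v$metrics$r2, r^2)
  expect_equal(as.character(v$predictions$group),
               c("Overestimation", "Correct prediction", "Overestimation",
                 "Correct prediction"))
})

test_that("validation handles affine shifts and degenerate input", {
  df <- tibble::tibble(chronological_age = c(40, 50, 60),
                       predicted_age = c(50, 60, 70))
  v <- delta_and_validate(df)
  expect_equal(v$metrics$mae, 10)
  expect_equal(v$metrics$r, 1)

  same <- tibble::tibble(chronological_age = rep(50, 3),
                         predicted_age = rep(50, 3))
  expect_error(delta_and_validate(same), "zero variance")
  expect_error(delta_and_validate(df[1, ]), "two rows")
})

test_that("serial categories pair baseline and follow-up groups in order", {
  pr <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 2),
    exam = rep(0:1, 3),
    group = factor(c("Overestimation", "Overestimation",
                     "Correct prediction", "Overestimation",
                     "Underestimation", "Underestimation"),
                   levels = c("Correct prediction", "Overestimation",
                              "Underestimation"))
  )
  sg <- serial_group(pr)
  expect_equal(sg$pair, c("Overestimation, overestimation",
                          "Correct prediction, overestimation",
                          "Underestimation, underestimation"))
  expect_equal(sg$consistent, c(TRUE, FALSE, TRUE))

  expect_error(serial_group(pr[-2, ]), "both an exam 0 and an exam 1")
  expect_error(serial_group(rbind(pr, pr[1, ])), "exactly one row")
})

test_that("SNR-delta correlation behaves as a null and as identity", {
  set.seed(7)
  snr <- rnorm(5000); delta <- rnorm(5000)   # independent by construction
  res <- snr_prediction_correlation(snr, delta)
  expect_lt(abs(res$r), 0.05)
  expect_equal(snr_prediction_correlation(snr, snr)$r, 1)
  expect_error(snr_prediction_correlation(1:2, 1:2), "at least 3")
  expect_error(snr_prediction_correlation(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("predict_ecg_age carries record metadata", {
  mod <- get_surrogate()
  recs <- list(make_clean_record(age = 50), make_clean_record(age = 70))
  recs[[1]]$subject_id <- "s1"; recs[[1]]$exam <- 0L
  recs[[2]]$subject_id <- "s2"; recs[[2]]$exam <- 0L
  recs[[1]]$age_at_exam <- 50; recs[[2]]$age_at_exam <- 70
  tb <- predict_ecg_age(recs, mod)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$subject_id, c("s1", "s2"))
  expect_true(all(abs(tb$predicted_age - c(50, 70)) < 5))
})
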