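test_that("integrated gradients is exact for a linear model, zero baseline", {
  set.seed(8)
  w <- matrix(rnorm(12 * 100), 12, 100)
  x <- matrix(rnorm(12 * 100), 12, 100)
  rec <- ecg_record(x, fs = 100)
  ig <- integrated_gradients(linear_model(w, intercept = 3), rec, steps = 4)
  expect_equal(ig$values, w * x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(ig$completeness_gap, 1e-9)
})

test_that("a record identical to its baseline gets zero attribution", {
  x <- matrix(rnorm(12 * 50), 12, 50)
  rec <- ecg_record(x, fs = 50)
  ig <- integrated_gradients(linear_model(x), rec, baseline = rec, steps = 8)
  expect_true(all(ig$values == 0))
})

test_that("integrated gradients is linear in the model", {
  set.seed(9)
  w1 <- matrix(rnorm(12 * 60), 12, 60)
  w2 <- matrix(rnorm(12 * 60), 12, 60)
  x <- matrix(rnorm(12 * 60), 12, 60)
  rec <- ecg_record(x, fs = 60)
  a <- 2.5; b <- -1.25
  comb <- linear_model(a * w1 + b * w2)
  ig_comb <- integrated_gradients(comb, rec, steps = 8)
  ig1 <- integrated_gradients(linear_model(w1), rec, steps = 8)
  ig2 <- integrated_gradients(linear_model(w2), rec, steps = 8)
  expect_equal(ig_comb$values, a * ig1$values + b * ig2$values,
               tolerance = 1e-10)
})

test_that("surrogate attributions satisfy completeness and converge", {
  mod <- get_surrogate()
  set.seed(10)
  m <- morphology_from_age(68, "female")
  r <- simulate_ecg(m, fs = 400, duration_s = 10, noise_sd = 0.02, seed = 10)
  ig128 <- integrated_gradients(mod, r, steps = 128)
  ig256 <- integrated_gradients(mod, r, steps = 256)
  span <- abs(ig256$prediction - ig256$baseline_prediction)
  expect_lt(ig256$completeness_gap, 1e-3 * span)
  # doubling the steps must not worsen the gap by more than 10%
  expect_lte(ig256$completeness_gap, 1.1 * ig128$completeness_gap)
})

test_that("normalisation rescales to [-1, 1] preserving signs", {
  v <- matrix(rnorm(12 * 40), 12, 40)
  v[1, 1] <- 4; v <- v / max(abs(v)) * 4        # max |v| exactly 4
  map <- structure(list(values = v, completeness_gap = 0, steps = 1,
                        prediction = 0, baseline_prediction = 0,
                        baseline_ref = "zero", normalized = FALSE, fs = 40,
                        subject_id = NA, exam = NA),
                   class = "relevance_map")
  nm <- normalize_relevance(map)
  expect_equal(nm$values, v / 4)
  expect_equal(max(abs(nm$values)), 1)
  expect_equal(sign(nm$values), sign(v))
  expect_equal(normalize_relevance(nm)$values, nm$values)  # idempotent

  zmap <- map; zmap$values <- matrix(0, 12, 40)
  expect_warning(zn <- normalize_relevance(zmap), "all-zero")
  expect_equal(zn$values, zmap$values)
})

test_that("beat alignment averages retained slices only", {
  fs <- 400
  rec <- ecg_record(matrix(0, 12, fs * 3), fs = fs)
  seg <- segment_beats(rec, 1.5)
  v <- matrix(rnorm(12 * fs * 3), 12)
  map <- structure(list(values = v, fs = fs, normalized = TRUE,
                        completeness_gap = 0, steps = 1, prediction = 0,
                        baseline_prediction = 0, baseline_ref = "zero",
                        subject_id = NA, exam = NA),
                   class = "relevance_map")
  al <- beat_align(list(map), list(seg))
  i0 <- seg$start_idx[1]; L <- ncol(seg$samples[[1]])
  expect_equal(al$curve, v[, i0:(i0 + L - 1)], ignore_attr = TRUE)
  expect_equal(al$n_beats, 1)

  # two slices s and -s cancel
  seg2 <- segment_beats(rec, c(1.0, 2.0))
  v2 <- matrix(0, 12, fs * 3)
  s <- matrix(rnorm(12 * L), 12)
  i1 <- seg2$start_idx[1]; i2 <- seg2$start_idx[2]
  v2[, i1:(i1 + L - 1)] <- s
  v2[, i2:(i2 + L - 1)] <- -s
  map2 <- map; map2$values <- v2
  al2 <- beat_align(list(map2), list(seg2))
  expect_equal(max(abs(al2$curve)), 0)

  # aggregation is permutation invariant in record order
  maps <- list(map, map2); segs <- list(seg, seg2)
  a12 <- beat_align(maps, segs)
  a21 <- beat_align(rev(maps), rev(segs))
  expect_equal(a12$curve, a21$curve)

  # invalid-only segments cannot be aggregated
  seg_bad <- segment_beats(rec, c(1.0, 1.3))    # overlapping, both invalid
  expect_error(beat_align(list(map), list(seg_bad)), "no retained")
})

test_that("lead importance is a scale-invariant weight distribution", {
  v <- matrix(0, 12, 30); v[7, ] <- rnorm(30) + 2   # all relevance in V1
  map <- structure(list(values = v, fs = 30, normalized = FALSE,
                        completeness_gap = 0, steps = 1, prediction = 0,
                        baseline_prediction = 0, baseline_ref = "zero",
                        subject_id = NA, exam = NA),
                   class = "relevance_map")
  w <- lead_importance(map)
  expect_equal(unname(w["V1"]), 1)
  expect_equal(sum(w), 1)

  map2 <- map; map2$values <- matrix(1, 12, 30)     # equal lead sums
  expect_equal(unname(lead_importance(map2)), rep(1 / 12, 12))

  map3 <- map; map3$values <- map$values * 17       # positive scaling
  expect_equal(lead_importance(map3), w)

  mapz <- map; mapz$values <- matrix(0, 12, 30)
  expect_warning(wz <- lead_importance(mapz), "zero total")
  expect_equal(unname(wz), rep(1 / 12, 12))

  # signed variant keeps signs but normalises by total magnitude
  map4 <- map; map4$values[10, ] <- -map$values[7, ]
  ws <- lead_importance(map4, signed = TRUE)
  expect_equal(sum(abs(ws)), 1)
  expect_lt(ws["V4"], 0)
})

test_that("ablating the P-duration weight suppresses P-window relevance", {
  mod <- get_surrogate()
  modP <- ablate_features(mod, "occ_p")
  p_window_rel <- function(model) {
    maps <- list(); segs <- list()
    for (i in 1:3) {
      set.seed(300 + i)
      m <- morphology_from_age(runif(1, 45, 80), sample(c("female", "male"), 1))
      r <- simulate_ecg(m, fs = 400, duration_s = 10, noise_sd = 0,
                        seed = 100 + i)
      maps[[i]] <- normalize_relevance(integrated_gradients(model, r, steps = 32))
      segs[[i]] <- segment_beats(r, detect_consensus(r))
    }
    al <- beat_align(maps, segs)
    wm <- al$window_means
    mean(wm$mean_abs_relevance[wm$window == "P"])
  }
  expect_lt(p_window_rel(modP), 0.5 * p_window_rel(mod))
  # the full P-wave pathway (occupancy + PR timing) removes it almost entirely
  expect_lt(p_window_rel(ablate_features(mod, "p_wave")),
            0.1 * p_window_rel(mod))
})

test_that("QRS window dominates aligned relevance in the strongest lead", {
  mod <- get_surrogate()
  set.seed(77)
  m <- morphology_from_age(70, "male")
  r <- simulate_ecg(m, fs = 400, duration_s = 10, noise_sd = 0, seed = 77)
  map <- normalize_relevance(integrated_gradients(mod, r, steps = 32))
  al <- beat_align(list(map), list(segment_beats(r, detect_consensus(r))))
  wm <- al$window_means
  # lead with the largest total |relevance|
  tot <- tapply(wm$mean_abs_relevance, wm$lead, sum)
  lead <- names(which.max(tot))
  sub <- wm[wm$lead == lead, ]
  expect_equal(sub$window[which.max(sub$mean_abs_relevance)], "QRS")
})
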