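#' Canonical per-lead amplitude templates
#'
#' Fixed 12-lead projection factors (millivolts at deflection peak) for the P,
#' R, S and T deflections. Two R templates are provided: a left-precordial
#' dominant pattern (normal late R progression) and a V1-V3 dominant pattern
#' (early R progression, as seen with right-ventricular hypertrophy). The
#' generator interpolates linearly between them with the `r_progression`
#' parameter. Lead II carries a pure R deflection (S amplitude 0) so that
#' threshold-based interval measurement on lead II is exact by construction.
#'
#' @return A named list of numeric vectors of length 12 (`p`, `r_left`,
#'   `r_right`, `s`, `t`), in lead order I, II, III, AVR, AVL, AVF, V1-V6.
#' @export
lead_amplitude_template <- function() {
  list(
    p = c(0.05, 0.15, 0.10, -0.10, 0.02, 0.12,
          0.05, 0.06, 0.07, 0.08, 0.08, 0.07),
    r_left = c(0.7, 1.0, 0.5, -0.8, 0.3, 0.7,
               0.2, 0.4, 0.7, 1.3, 1.5, 1.2),
    r_right = c(0.5, 0.9, 0.4, -0.7, 0.2, 0.6,
                1.2, 1.5, 1.3, 0.9, 0.7, 0.5),
    s = c(-0.10, 0.0, -0.15, 0.20, -0.05, -0.10,
          -0.80, -0.90, -0.50, -0.30, -0.20, -0.10),
    t = c(0.15, 0.30, 0.15, -0.20, 0.05, 0.20,
          0.10, 0.25, 0.30, 0.35, 0.30, 0.25)
  )
}

# Default affine interval model (ms as a function of biological age in years).
# QT is parameterised at 60 bpm and Bazett-scaled to the realised heart rate.
INTERVAL_MODEL <- list(
  p   = c(intercept = 85,  slope = 0.35),
  pr  = c(intercept = 130, slope = 0.60),
  qrs = c(intercept = 80,  slope = 0.25),
  qt60 = c(intercept = 360, slope = 0.70)
)

# Width of the half-maximum-style support of a Gaussian deflection: the
# deflection is treated as starting/ending where its amplitude falls to 5% of
# peak, i.e. at +-2.4477 sigma. duration = 2 * 2.4477 * sigma.
GAUSS_5PCT_HALFWIDTH <- sqrt(-2 * log(0.05))

#' Morphology parameters as a function of biological age
#'
#' Maps a biological age to a set of beat-morphology parameters. All four
#' standard intervals (P duration, PR, QRS, QT) are strictly increasing affine
#' functions of biological age, with optional seeded Gaussian jitter on top;
#' the precordial R-progression factor also increases with age. Females get
#' the documented +10 ms QTc offset. QT is scaled from its 60-bpm value by
#' Bazett's square-root-of-RR rule.
#'
#' Defaults: P = 85 + 0.35 a, PR = 130 + 0.60 a, QRS = 80 + 0.25 a,
#' QTc = 360 + 0.70 a (ms, a = biological age in years); jitter sd 5 ms.
#'
#' @param biological_age Biological age in years, in \[18, 100\].
#' @param sex `"female"` or `"male"`.
#' @param jitter_sd Standard deviation (ms) of the Gaussian jitter added to
#'   each interval; `0` switches jitter off and makes the output a
#'   deterministic function of age. Draws come from the current RNG stream.
#' @param heart_rate Mean heart rate in beats/min; jittered with sd
#'   `hr_jitter_sd` when jitter is on.
#' @param hr_jitter_sd Heart-rate jitter sd (beats/min); scaled to 0 when
#'   `jitter_sd = 0`.
#' @param qtc_sex_offset QTc shift (ms) applied to females; default +10.
#' @param r_progression_jitter_sd Jitter sd on the R-progression factor.
#' @return An object of class `morphology_params`: a list with elements
#'   `p_duration`, `pr_interval`, `qrs_duration`, `qt_interval` (all ms, QT at
#'   the realised heart rate), `heart_rate`, `r_progression`,
#'   `lead_amplitudes` (list of 12-vectors for P/R/S/T) and `t_width` (ms).
#' @export
morphology_from_age <- function(biological_age,
                                sex = c("female", "male"),
                                jitter_sd = 5,
                                heart_rate = 62,
                                hr_jitter_sd = 3,
                                qtc_sex_offset = 10,
                                r_progression_jitter_sd = 0.05) {
  sex <- match.arg(sex)
  if (!is.finite(biological_age) || biological_age < 18 || biological_age > 100) {
    abort("`biological_age` must lie in [18, 100].")
  }
  jit <- function(s) if (jitter_sd > 0) rnorm(1, 0, s) else 0
  a <- biological_age

  p   <- INTERVAL_MODEL$p["intercept"]   + INTERVAL_MODEL$p["slope"] * a   + jit(jitter_sd)
  pr  <- INTERVAL_MODEL$pr["intercept"]  + INTERVAL_MODEL$pr["slope"] * a  + jit(jitter_sd)
  qrs <- INTERVAL_MODEL$qrs["intercept"] + INTERVAL_MODEL$qrs["slope"] * a + jit(jitter_sd)
  qt60 <- INTERVAL_MODEL$qt60["intercept"] + INTERVAL_MODEL$qt60["slope"] * a +
    jit(jitter_sd) + if (sex == "female") qtc_sex_offset else 0

  hr <- heart_rate + jit(hr_jitter_sd)
  hr <- min(max(hr, 40), 150)
  rr <- 60 / hr
  qt <- qt60 * sqrt(rr)

  # guard invariants (jitter is small relative to the affine trends)
  pr <- max(pr, p + 5)
  qt <- max(qt, qrs + 180)

  rp <- 0.1 + 0.6 * (a - 30) / 60 +
    if (jitter_sd > 0) rnorm(1, 0, r_progression_jitter_sd) else 0
  rp <- min(max(rp, 0), 1)

  tpl <- lead_amplitude_template()
  amp <- list(
    p = tpl$p,
    r = (1 - rp) * tpl$r_left + rp * tpl$r_right,
    s = tpl$s,
    t = tpl$t
  )
  amp <- lapply(amp, function(v) setNames(as.numeric(v), ECG_LEADS))

  structure(
    list(
      p_duration = unname(p), pr_interval = unname(pr),
      qrs_duration = unname(qrs), qt_interval = unname(qt),
      heart_rate = unname(hr), r_progression = rp,
      lead_amplitudes = amp, t_width = 160,
      biological_age = a, sex = sex
    ),
    class = "morphology_params"
  )
}

#' @export
print.morphology_params <- function(x, ...) {
  cat("<morphology_params>\n")
  cat(sprintf("  P %.1f ms | PR %.1f ms | QRS %.1f ms | QT %.1f ms | HR %.1f bpm\n",
              x$p_duration, x$pr_interval, x$qrs_duration, x$qt_interval,
              x$heart_rate))
  cat(sprintf("  R progression %.2f, sex %s, biological age %.1f y\n",
              x$r_progression, x$sex, x$biological_age))
  invisible(x)
}

validate_morphology <- function(m) {
  stopifnot(
    m$p_duration > 0, m$qrs_duration > 0,
    m$pr_interval >= m$p_duration,
    m$qt_interval > m$qrs_duration,
    m$heart_rate >= 30, m$heart_rate <= 220
  )
  invisible(m)
}

#' Construct an ECG record object
#'
#' @param signals 12 x N numeric matrix (millivolts), rows in standard lead
#'   order (I, II, III, AVR, AVL, AVF, V1-V6).
#' @param fs Sampling rate in Hz.
#' @param subject_id,exam,age_at_exam,sex Cohort linkage metadata (optional).
#' @param r_times Optional generator ground-truth R-peak times (s).
#' @param morphology Optional `morphology_params` ground truth.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signals, fs, subject_id = NA_character_,
                       exam = NA_integer_, age_at_exam = NA_real_,
                       sex = NA_character_, r_times = NULL,
                       morphology = NULL) {
  if (!is.matrix(signals) || nrow(signals) != 12) {
    abort("`signals` must be a 12 x N matrix (one row per lead).")
  }
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be positive.")
  rownames(signals) <- ECG_LEADS
  structure(
    list(signals = signals, fs = fs, duration = ncol(signals) / fs,
         subject_id = subject_id, exam = exam, age_at_exam = age_at_exam,
         sex = sex, r_times = r_times, morphology = morphology),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> 12 x %d samples @ %g Hz (%.1f s)",
              ncol(x$signals), x$fs, x$duration))
  if (!is.na(x$subject_id)) {
    cat(sprintf(" | subject %s exam %s", x$subject_id, x$exam))
  }
  cat("\n")
  invisible(x)
}

#' Synthesise a 12-lead ECG from morphology parameters
#'
#' Builds repeated P-QRS-T beats from smooth Gaussian deflections whose 5%%
#' amplitude-threshold onsets and offsets realise the morphology intervals,
#' applies the per-lead amplitude factors, and adds white Gaussian noise.
#' Identical `(morph, seed)` pairs give identical waveforms.
#'
#' Beat layout (times relative to QRS onset): P spans `[-pr, -pr + p]`; the R
#' deflection spans `[0, qrs]`; a narrow S deflection sits at `0.8 qrs`
#' (absent in lead II); the T deflection ends at `qt` with fixed width
#' `t_width`.
#'
#' @param morph A `morphology_params` object.
#' @param fs Sampling rate (Hz), default 400.
#' @param duration_s Record length (s), default 10.
#' @param noise_sd Additive white-noise sd in mV (0 = noise free).
#' @param seed Optional integer seed for the noise draw.
#' @param ... Metadata passed to [ecg_record()] (`subject_id`, `exam`, ...).
#' @return An [ecg_record()] carrying the true R-peak times and morphology as
#'   generator ground truth.
#' @export
simulate_ecg <- function(morph, fs = 400, duration_s = 10, noise_sd = 0,
                         seed = NULL, ...) {
  validate_morphology(morph)
  n <- round(fs * duration_s)
  rr <- 60 / morph$heart_rate
  p_s <- morph$p_duration / 1000
  pr_s <- morph$pr_interval / 1000
  qrs_s <- morph$qrs_duration / 1000
  qt_s <- morph$qt_interval / 1000
  tw_s <- morph$t_width / 1000

  # QRS onsets: leave room for the P wave before the first beat and the full
  # T wave after the last one.
  first_onset <- pr_s + 0.05
  last_onset <- duration_s - qt_s - 0.02
  if (last_onset < first_onset) {
    abort("`duration_s` too short for one full beat at this heart rate.")
  }
  onsets <- seq(first_onset, last_onset, by = rr)

  tvec <- (seq_len(n) - 1) / fs
  x <- matrix(0, nrow = 12, ncol = n)
  amp <- morph$lead_amplitudes

  add_bump <- function(x, center, sigma, amps) {
    # restrict to +-5 sigma support for speed
    i0 <- max(1L, floor((center - 5 * sigma) * fs) + 1L)
    i1 <- min(n, ceiling((center + 5 * sigma) * fs) + 1L)
    if (i1 < i0) return(x)
    idx <- i0:i1
    shape <- exp(-((tvec[idx] - center)^2) / (2 * sigma^2))
    x[, idx] <- x[, idx] + outer(amps, shape)
    x
  }

  sig_p <- p_s / (2 * GAUSS_5PCT_HALFWIDTH)
  sig_r <- qrs_s / (2 * GAUSS_5PCT_HALFWIDTH)
  sig_s <- qrs_s / 10
  sig_t <- tw_s / (2 * GAUSS_5PCT_HALFWIDTH)

  for (o in onsets) {
    x <- add_bump(x, o - pr_s + p_s / 2, sig_p, amp$p)
    x <- add_bump(x, o + qrs_s / 2, sig_r, amp$r)
    x <- add_bump(x, o + 0.8 * qrs_s, sig_s, amp$s)
    x <- add_bump(x, o + qt_s - tw_s / 2, sig_t, amp$t)
  }

  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    x <- x + matrix(rnorm(12 * n, 0, noise_sd), nrow = 12)
  }

  ecg_record(x, fs = fs, r_times = onsets + qrs_s / 2, morphology = morph, ...)
}
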