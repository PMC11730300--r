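#' Measure standard ECG intervals from a waveform
#'
#' Locates wave onsets and offsets by 5% amplitude-threshold crossings of the
#' lightly smoothed absolute signal in search windows around each deflection,
#' beat by beat, and returns the beat-median of each interval. All four
#' intervals are measured on lead II by default (the generator's lead II
#' carries a pure R deflection, which makes the threshold rule exact); the
#' measurement lead is configurable. QTc uses Bazett's correction by default.
#'
#' Per beat: QRS onset/offset are the outermost 5%-of-R-peak crossings around
#' the R-peak; the P-wave is the largest deflection in the 300 ms before QRS
#' onset with its own 5%-of-P-peak boundaries; the T-wave is the largest
#' deflection after QRS offset with its offset defining the end of QT.
#'
#' @param record An [ecg_record()].
#' @param consensus_times Sorted consensus R-peak times (s); at least 3.
#' @param lead Measurement lead (default `"II"`).
#' @param qtc Correction formula, `"bazett"` (default) or `"fridericia"`.
#' @param smooth_ms Moving-average smoothing of the absolute signal (ms).
#' @return One-row tibble of class `interval_set`: `p_duration`,
#'   `pr_interval`, `qrs_duration`, `qt_interval`, `qtc`, `rr_mean` (s) and
#'   `reason` (NA, or why P-dependent fields are missing). Intervals in ms;
#'   undetectable P-waves yield `NA` for `p_duration`/`pr_interval`.
#' @export
measure_intervals <- function(record, consensus_times, lead = "II",
                              qtc = c("bazett", "fridericia"),
                              smooth_ms = 5) {
  stopifnot(inherits(record, "ecg_record"), lead %in% ECG_LEADS)
  qtc <- match.arg(qtc)
  if (length(consensus_times) < 3) abort("need at least 3 consensus beats.")
  fs <- record$fs
  x <- record$signals[lead, ]
  n <- length(x)
  k <- max(1L, round(smooth_ms / 1000 * fs))
  ax <- as.numeric(stats::filter(abs(x), rep(1 / k, k), sides = 2))
  ax[is.na(ax)] <- 0

  rr <- median(diff(consensus_times))
  idx_of <- function(t) round(t * fs) + 1L

  # threshold crossing scan: from index i walk outward while above threshold
  scan_edge <- function(i, thr, dir) {
    j <- i
    while (j + dir >= 1 && j + dir <= n && ax[j + dir] >= thr) j <- j + dir
    j
  }

  per_beat <- purrr::map_dfr(consensus_times, function(rt) {
    ri <- idx_of(rt)
    if (ri < round(0.35 * fs) || ri + round(0.5 * fs) > n) {
      return(tibble::tibble(p = NA_real_, pr = NA_real_, qrs = NA_real_,
                            qt = NA_real_))
    }
    thr_r <- 0.05 * ax[ri]
    q_on <- scan_edge(ri, thr_r, -1L)
    q_off <- scan_edge(ri, thr_r, +1L)
    qrs_ms <- (q_off - q_on) / fs * 1000

    # P wave: largest smoothed deflection in the 300 ms before QRS onset
    p_lo <- max(1L, q_on - round(0.30 * fs))
    p_hi <- q_on - round(0.012 * fs)
    p <- pr <- NA_real_
    if (p_hi > p_lo) {
      seg <- ax[p_lo:p_hi]
      pk <- p_lo + which.max(seg) - 1L
      if (ax[pk] > 0.04 * ax[ri]) {      # needs a detectable P deflection
        thr_p <- 0.05 * ax[pk]
        p_on <- scan_edge(pk, thr_p, -1L)
        p_off <- scan_edge(pk, thr_p, +1L)
        p <- (p_off - p_on) / fs * 1000
        pr <- (q_on - p_on) / fs * 1000
      }
    }

    # T wave: largest deflection after QRS offset, bounded by the next beat
    t_lo <- q_off + round(0.04 * fs)
    t_hi <- min(n, ri + round(min(0.55, rr - 0.1) * fs))
    qt <- NA_real_
    if (t_hi > t_lo) {
      seg <- ax[t_lo:t_hi]
      pk <- t_lo + which.max(seg) - 1L
      if (ax[pk] > 0.03 * ax[ri]) {
        thr_t <- 0.05 * ax[pk]
        t_off <- scan_edge(pk, thr_t, +1L)
        qt <- (t_off - q_on) / fs * 1000
      }
    }
    tibble::tibble(p = p, pr = pr, qrs = qrs_ms, qt = qt)
  })

  med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  p <- med(per_beat$p); pr <- med(per_beat$pr)
  qrs <- med(per_beat$qrs); qt <- med(per_beat$qt)
  qtc_val <- if (is.na(qt)) NA_real_ else {
    if (qtc == "bazett") qtc_bazett(qt, rr) else qtc_fridericia(qt, rr)
  }
  reason <- if (is.na(p)) "no detectable P-wave" else NA_character_
  out <- tibble::tibble(p_duration = p, pr_interval = pr, qrs_duration = qrs,
                        qt_interval = qt, qtc = qtc_val, rr_mean = rr,
                        reason = reason)
  class(out) <- c("interval_set", class(out))
  out
}

#' Bazett heart-rate correction of the QT interval
#'
#' `QTc = QT / sqrt(RR)` with RR in seconds.
#'
#' @param qt QT interval in ms.
#' @param rr RR interval in seconds (> 0).
#' @return QTc in ms.
#' @export
qtc_bazett <- function(qt, rr) {
  if (any(rr <= 0)) abort("`rr` must be positive.")
  qt / sqrt(rr)
}

#' Fridericia heart-rate correction of the QT interval
#'
#' `QTc = QT / RR^(1/3)` with RR in seconds.
#'
#' @inheritParams qtc_bazett
#' @return QTc in ms.
#' @export
qtc_fridericia <- function(qt, rr) {
  if (any(rr <= 0)) abort("`rr` must be positive.")
  qt / rr^(1 / 3)
}

#' Pairwise group comparison of a clinical feature
#'
#' Welch two-sided t-tests between every pair of groups, with per-group
#' summaries for boxplot-style reporting. Unequal variances are assumed
#' (group sizes in this design are unequal).
#'
#' @param data Data frame with the feature values and a grouping column.
#' @param value Name of the numeric feature column.
#' @param group Name of the grouping column (>= 2 groups, each with >= 2
#'   finite values).
#' @return A list of class `group_feature_test` with `pairwise` (tibble:
#'   `group1`, `group2`, `t`, `p`, `mean_diff`) and `summary` (tibble:
#'   `group`, `n`, `mean`, `sd`). `tidy()` returns the pairwise table.
#' @export
group_feature_test <- function(data, value, group = "group") {
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  v <- data[[value]]; g <- as.factor(as.character(data[[group]]))
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  lv <- levels(g)
  if (length(lv) < 2) abort("need at least two groups.")
  smry <- tibble::tibble(
    group = lv,
    n = as.integer(table(g)[lv]),
    mean = tapply(v, g, mean)[lv],
    sd = tapply(v, g, sd)[lv]
  )
  if (any(smry$n < 2) || any(smry$sd == 0)) {
    abort("each group needs >= 2 values with nonzero spread.")
  }
  pairs <- utils::combn(lv, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    tt <- t.test(v[g == g1], v[g == g2], var.equal = FALSE)
    tibble::tibble(group1 = g1, group2 = g2, t = unname(tt$statistic),
                   p = tt$p.value, mean_diff = mean(v[g == g1]) - mean(v[g == g2]))
  })
  structure(list(pairwise = pw, summary = smry, feature = value),
            class = "group_feature_test")
}

#' @export
print.group_feature_test <- function(x, ...) {
  cat("<group_feature_test>", x$feature, "\n")
  print(x$pairwise)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_feature_test <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.group_feature_test <- function(x, ...) x$summary
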