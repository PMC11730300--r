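#' Spectral signal-to-noise ratio of an ECG record
#'
#' Splits each lead's discrete Fourier power into an in-band "signal" part
#' (default 0.66-2.5 Hz, i.e. 40-150 beats/min) and an out-of-band "noise"
#' part (DC bin excluded) and reports `10 log10(P_signal / P_noise)` in dB.
#' A Hann window is applied before the FFT by default to confine spectral
#' leakage; the ratio itself is invariant to uniform amplitude scaling.
#'
#' An all-zero lead yields the sentinel `-Inf` (no signal power); such leads
#' are dropped from the record-level mean.
#'
#' @param record An [ecg_record()].
#' @param band Length-2 numeric, in-band frequency range in Hz.
#' @param hann Apply a Hann window before the FFT (default `TRUE`).
#' @return A list of class `snr_result`: `per_lead_db` (named 12-vector),
#'   `record_db` (mean over leads with finite SNR) and `band`.
#' @export
compute_snr <- function(record, band = c(0.66, 2.5), hann = TRUE) {
  stopifnot(inherits(record, "ecg_record"), length(band) == 2, band[1] < band[2])
  n <- ncol(record$signals)
  if (n / record$fs < 4) abort("record must be at least 4 s long for SNR.")
  w <- if (hann) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)) else rep(1, n)
  freqs <- (seq_len(n) - 1) * record$fs / n
  half <- 2:floor(n / 2)            # positive frequencies, DC (bin 1) excluded
  in_band <- half[freqs[half] >= band[1] & freqs[half] <= band[2]]
  out_band <- setdiff(half, in_band)

  per_lead <- apply(record$signals, 1, function(x) {
    p <- Mod(fft(x * w))^2
    ps <- sum(p[in_band])
    pn <- sum(p[out_band])
    if (ps == 0) return(-Inf)
    if (pn == 0) return(Inf)
    10 * log10(ps / pn)
  })
  structure(
    list(per_lead_db = setNames(per_lead, ECG_LEADS),
         record_db = mean(per_lead[is.finite(per_lead)]),
         band = band),
    class = "snr_result"
  )
}

#' Single-lead R-peak detection
#'
#' A Pan-Tompkins-style envelope detector: band-pass filter (5-15 Hz
#' Butterworth, zero-phase), derivative, squaring, moving-window integration,
#' then peak picking with an adaptive threshold (a fraction of the median of
#' the strongest envelope peaks) and a 200 ms refractory period. Each
#' detection is refined to the local maximum of the squared raw signal, which
#' makes the returned times insensitive to lead polarity.
#'
#' @param x Numeric vector, one lead in mV.
#' @param fs Sampling rate (Hz).
#' @param refractory_s Minimum spacing between peaks (s), default 0.2.
#' @param threshold_frac Fraction of the reference envelope level used as the
#'   detection threshold.
#' @return Sorted numeric vector of peak times in seconds (possibly empty).
#' @export
detect_rpeaks_lead <- function(x, fs, refractory_s = 0.2, threshold_frac = 0.35) {
  stopifnot(all(is.finite(x)))
  n <- length(x)
  if (n < fs) return(numeric(0))
  if (max(abs(x)) == 0) return(numeric(0))

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  env <- c(0, diff(xf))^2
  k <- max(3L, round(0.15 * fs))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0

  # local maxima of the envelope
  lm <- which(diff(sign(diff(env))) < 0) + 1L
  if (length(lm) == 0) return(numeric(0))
  # adaptive reference level: median of the strongest peaks (top ~1 per 1.5 s)
  ntop <- max(1L, ceiling(n / fs / 1.5))
  ref <- median(sort(env[lm], decreasing = TRUE)[seq_len(min(ntop, length(lm)))])
  cand <- lm[env[lm] >= threshold_frac * ref]
  if (length(cand) == 0) return(numeric(0))

  # greedy refractory suppression, strongest first
  cand <- cand[order(env[cand], decreasing = TRUE)]
  keep <- integer(0)
  gap <- round(refractory_s * fs)
  for (i in cand) {
    if (all(abs(keep - i) > gap)) keep <- c(keep, i)
  }
  keep <- sort(keep)

  # refine each detection to the local max of the squared raw signal
  half <- as.integer(round(0.06 * fs))
  refined <- vapply(keep, function(i) {
    lo <- max(1L, as.integer(i) - half); hi <- min(n, as.integer(i) + half)
    lo + which.max(x[lo:hi]^2) - 1L
  }, integer(1))
  sort(unique(refined - 1L)) / fs
}

#' Multi-lead consensus R-peaks
#'
#' Pools per-lead peak times, forms candidate clusters by single linkage
#' (adjacent pooled times within `tolerance` chain into one cluster), keeps at
#' most one peak per lead per cluster (the one closest to the cluster median),
#' and emits the median member time of every cluster supported by at least
#' `min_leads` leads. Any two emitted times are separated by more than
#' `tolerance`.
#'
#' @param per_lead_peaks List of 12 sorted numeric vectors (times in s).
#' @param tolerance Cluster tolerance in seconds (default 0.010 = 10 ms).
#' @param min_leads Minimum number of agreeing leads (default 7).
#' @return Sorted numeric vector of consensus times (s).
#' @export
consensus_rpeaks <- function(per_lead_peaks, tolerance = 0.010, min_leads = 7) {
  stopifnot(is.list(per_lead_peaks))
  times <- unlist(per_lead_peaks, use.names = FALSE)
  leads <- rep(seq_along(per_lead_peaks),
               vapply(per_lead_peaks, length, integer(1)))
  if (length(times) == 0) return(numeric(0))
  o <- order(times)
  times <- times[o]; leads <- leads[o]

  # single-linkage components: break where the gap between adjacent pooled
  # times exceeds the tolerance
  comp <- cumsum(c(1, as.integer(diff(times) > tolerance + 1e-12)))

  out <- numeric(0)
  for (g in unique(comp)) {
    idx <- which(comp == g)
    tt <- times[idx]; ll <- leads[idx]
    # one peak per lead: keep the member closest to the component median
    if (anyDuplicated(ll)) {
      med0 <- median(tt)
      keep <- vapply(split(seq_along(tt), ll),
                     function(ii) ii[which.min(abs(tt[ii] - med0))], integer(1))
      tt <- tt[sort(keep)]; ll <- ll[sort(keep)]
    }
    if (length(unique(ll)) >= min_leads) out <- c(out, median(tt))
  }
  sort(out)
}

#' Fixed-length beat segmentation with overlap exclusion
#'
#' Cuts one half-open window `[r - pre, r + post)` per consensus R-peak. A
#' segment whose window would extend beyond the record is dropped outright; a
#' segment whose window intersects the window of either neighbour is kept but
#' marked invalid (`valid = FALSE`), so that each analysed heartbeat is
#' independent. Windows are half-open, so two beats exactly `pre + post`
#' apart touch without overlapping and are both retained.
#'
#' @param record An [ecg_record()].
#' @param consensus_times Sorted R-peak times (s).
#' @param pre,post Window extent before/after the R-peak (s); defaults 0.250
#'   and 0.400 (650 ms total).
#' @return A tibble with one row per in-record segment: `r_time`, `start_idx`
#'   (1-based first sample), `valid`, and the matrix column `samples`
#'   (list-column of 12 x L matrices, L = `round((pre+post) * fs)`).
#' @export
segment_beats <- function(record, consensus_times, pre = 0.250, post = 0.400) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  n <- ncol(record$signals)
  L <- round((pre + post) * fs)
  starts <- round((consensus_times - pre) * fs) + 1L
  inside <- starts >= 1L & (starts + L - 1L) <= n
  starts <- starts[inside]
  r_times <- consensus_times[inside]
  k <- length(starts)
  if (k == 0) {
    return(tibble::tibble(r_time = numeric(0), start_idx = integer(0),
                          valid = logical(0), samples = list()))
  }
  valid <- rep(TRUE, k)
  if (k > 1) {
    # half-open [start, start + L): overlap iff next start < this start + L
    ov <- starts[-1] < starts[-k] + L
    valid[-k][ov] <- FALSE
    valid[-1][ov] <- FALSE
  }
  samples <- lapply(seq_len(k), function(i) {
    record$signals[, starts[i]:(starts[i] + L - 1L), drop = FALSE]
  })
  tibble::tibble(r_time = r_times, start_idx = starts, valid = valid,
                 samples = samples)
}

#' Default physiological windows around the R-peak
#'
#' Named half-open intervals in ms relative to the R-peak used to summarise
#' beat-aligned relevance: P `[-250, -120)`, PQ `[-120, -60)`, QRS
#' `[-60, +100)`, ST_T `[+100, +400)`. Together they partition the 650 ms
#' segment exactly.
#'
#' @return A `waveform_windows` object (named list of length-2 numeric
#'   vectors, ms).
#' @export
default_windows <- function() {
  waveform_windows(list(P = c(-250, -120), PQ = c(-120, -60),
                        QRS = c(-60, 100), ST_T = c(100, 400)))
}

#' Validate a set of waveform windows
#'
#' @param windows Named list of length-2 numeric vectors (start, end) in ms
#'   relative to the R-peak; intervals must be ordered, non-overlapping and
#'   lie within `[-250, 400)`.
#' @return The validated list with class `waveform_windows`.
#' @export
waveform_windows <- function(windows) {
  stopifnot(is.list(windows), length(windows) >= 1,
            !is.null(names(windows)), all(nzchar(names(windows))))
  m <- do.call(rbind, windows)
  if (any(m[, 2] <= m[, 1])) abort("every window must have positive length.")
  if (any(m[, 1] < -250) || any(m[, 2] > 400)) {
    abort("windows must lie within [-250, 400) ms.")
  }
  o <- order(m[, 1])
  if (any(m[o, 2][-nrow(m)] > m[o, 1][-1] + 1e-9)) {
    abort("windows must not overlap.")
  }
  structure(windows[o], class = "waveform_windows")
}
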