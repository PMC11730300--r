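#' Integrated-gradients attribution for an ECG-age model
#'
#' Path-integral attribution from a baseline record to the actual record:
#' `attr_i = (x_i - b_i) * mean_k gradient_i(b + (k - 0.5)/steps * (x - b))`
#' (midpoint Riemann rule). By the completeness axiom the attributions sum to
#' `f(x) - f(baseline)` up to quadrature error; the realised gap is recorded
#' in the result.
#'
#' @param model An `ecg_age_model` (or any list with `predict` and `gradient`
#'   functions over [ecg_record()] input).
#' @param record The record to explain.
#' @param baseline Baseline record of identical shape; `NULL` (default) uses
#'   the all-zero record.
#' @param steps Number of Riemann steps (default 64).
#' @return Object of class `relevance_map`: list with `values` (12 x N
#'   matrix), `prediction`, `baseline_prediction`, `completeness_gap`,
#'   `steps`, `baseline_ref`, `normalized` and the source `record` metadata
#'   (`fs`, `subject_id`, `exam`).
#' @export
integrated_gradients <- function(model, record, baseline = NULL, steps = 64) {
  stopifnot(inherits(record, "ecg_record"), steps >= 1)
  if (is.null(baseline)) {
    baseline <- ecg_record(matrix(0, 12, ncol(record$signals)), fs = record$fs)
    baseline_ref <- "all-zero record"
  } else {
    stopifnot(inherits(baseline, "ecg_record"))
    if (!all(dim(baseline$signals) == dim(record$signals))) {
      abort("baseline and record must have identical shape.")
    }
    baseline_ref <- "user-supplied record"
  }
  dx <- record$signals - baseline$signals
  acc <- matrix(0, 12, ncol(record$signals))
  probe <- record
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    probe$signals <- baseline$signals + alpha * dx
    g <- model$gradient(probe)
    if (any(!is.finite(g))) abort("non-finite gradients along the path.")
    acc <- acc + g
  }
  values <- dx * acc / steps
  fx <- model$predict(record)
  fb <- model$predict(baseline)
  structure(
    list(values = values, prediction = fx, baseline_prediction = fb,
         completeness_gap = abs(sum(values) - (fx - fb)), steps = steps,
         baseline_ref = baseline_ref, normalized = FALSE, fs = record$fs,
         subject_id = record$subject_id, exam = record$exam),
    class = "relevance_map"
  )
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf(
    "<relevance_map> 12 x %d | f(x) %.2f, f(b) %.2f | gap %.3g | steps %d%s\n",
    ncol(x$values), x$prediction, x$baseline_prediction, x$completeness_gap,
    x$steps, if (x$normalized) " | normalized" else ""))
  invisible(x)
}

#' Normalise a relevance map to \[-1, 1\]
#'
#' Divides all values by the record-level maximum absolute relevance, so the
#' largest magnitude becomes 1 while signs are preserved (positive relevance
#' marks regions that push the predicted age up). An all-zero map is returned
#' unchanged with a warning.
#'
#' @param map A `relevance_map`.
#' @return The normalised `relevance_map` (`normalized = TRUE`).
#' @export
normalize_relevance <- function(map) {
  stopifnot(inherits(map, "relevance_map"))
  m <- max(abs(map$values))
  if (m == 0) {
    warn("all-zero relevance map; returned unchanged.")
    return(map)
  }
  map$values <- map$values / m
  map$normalized <- TRUE
  map
}

#' Beat-aligned cross-record relevance aggregation
#'
#' Extracts the relevance slice over every retained (non-overlapping,
#' in-record) beat segment, averages lead-wise across all slices from all
#' records, and summarises the aligned curve over a set of physiological
#' windows. Invalid segments contribute nothing. Sample 1 of the aligned
#' curve sits at -250 ms relative to the R-peak.
#'
#' @param maps List of `relevance_map` objects (normalise first if averaging
#'   across records of different magnitude is intended).
#' @param segments List of segment tibbles from [segment_beats()], parallel
#'   to `maps`.
#' @param windows A [waveform_windows()] set; default [default_windows()].
#' @return Object of class `aligned_relevance`: list with `curve` (12 x L
#'   mean relevance matrix), `tau_ms` (length-L time axis), `n_beats`, and
#'   `window_means` (tibble lead x window). `tidy()` returns the curve in
#'   long form.
#' @export
beat_align <- function(maps, segments, windows = default_windows()) {
  stopifnot(is.list(maps), is.list(segments), length(maps) == length(segments))
  slices <- list()
  fs <- NULL
  for (i in seq_along(maps)) {
    map <- maps[[i]]; seg <- segments[[i]]
    stopifnot(inherits(map, "relevance_map"))
    fs <- fs %||% map$fs
    keep <- seg[seg$valid, , drop = FALSE]
    if (nrow(keep) == 0) next
    L <- ncol(keep$samples[[1]])
    for (r in seq_len(nrow(keep))) {
      i0 <- keep$start_idx[r]
      slices[[length(slices) + 1L]] <- map$values[, i0:(i0 + L - 1L), drop = FALSE]
    }
  }
  if (length(slices) == 0) abort("no retained beat segments to aggregate.")
  curve <- Reduce(`+`, slices) / length(slices)
  rownames(curve) <- ECG_LEADS
  L <- ncol(curve)
  tau_ms <- (seq_len(L) - 1 - round(0.25 * fs)) * 1000 / fs

  wm <- purrr::map_dfr(names(windows), function(w) {
    idx <- which(tau_ms >= windows[[w]][1] & tau_ms < windows[[w]][2])
    tibble::tibble(window = w, lead = ECG_LEADS,
                   mean_relevance = rowMeans(curve[, idx, drop = FALSE]),
                   mean_abs_relevance = rowMeans(abs(curve[, idx, drop = FALSE])))
  })
  structure(list(curve = curve, tau_ms = tau_ms, n_beats = length(slices),
                 window_means = wm),
            class = "aligned_relevance")
}

#' @export
print.aligned_relevance <- function(x, ...) {
  cat(sprintf("<aligned_relevance> 12 x %d samples | %d beats aggregated\n",
              ncol(x$curve), x$n_beats))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aligned_relevance <- function(x, ...) {
  tibble::tibble(
    lead = rep(ECG_LEADS, each = ncol(x$curve)),
    tau_ms = rep(x$tau_ms, times = 12),
    relevance = as.numeric(t(x$curve))
  )
}

#' Lead importance from a relevance map
#'
#' Adds relevance lead-wise and normalises across leads into a weight vector
#' summing to one. By default the absolute value of each lead sum is taken
#' before normalising (signed lead sums can cancel and cannot form a weight
#' distribution); `signed = TRUE` returns the signed lead shares instead.
#'
#' @param map A `relevance_map`.
#' @param signed Use signed lead sums (normalised by the total absolute sum).
#' @return Named numeric vector of 12 weights; with `signed = FALSE` they are
#'   nonnegative and sum to 1. An all-zero map yields uniform weights with a
#'   warning.
#' @export
lead_importance <- function(map, signed = FALSE) {
  stopifnot(inherits(map, "relevance_map"), all(is.finite(map$values)))
  s <- rowSums(map$values)
  tot <- sum(abs(s))
  if (tot == 0) {
    warn("zero total relevance; returning uniform lead importance.")
    return(setNames(rep(1 / 12, 12), ECG_LEADS))
  }
  w <- if (signed) s / tot else abs(s) / tot
  setNames(w, ECG_LEADS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
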