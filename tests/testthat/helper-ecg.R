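# shared fixtures, all generated in code

# clean deterministic record with known morphology ground truth
make_clean_record <- function(age = 60, sex = "male", hr = 60, fs = 400,
                              duration = 10, noise_sd = 0, seed = NULL) {
  m <- morphology_from_age(age, sex, jitter_sd = 0, heart_rate = hr)
  simulate_ecg(m, fs = fs, duration_s = duration, noise_sd = noise_sd,
               seed = seed)
}

detect_consensus <- function(record) {
  per <- lapply(seq_len(12), function(j) {
    detect_rpeaks_lead(record$signals[j, ], record$fs)
  })
  consensus_rpeaks(per)
}

# the default surrogate calibrates once per session and is cached internally
get_surrogate <- function() surrogate_model(400)

# independent consensus oracle: pairwise union-find clustering (quadratic,
# different machinery from the sorted single-linkage implementation), lead
# de-duplication by distance to the cluster median, >= min_leads rule,
# median emission
oracle_consensus <- function(per_lead_peaks, tolerance = 0.010, min_leads = 7) {
  times <- unlist(per_lead_peaks, use.names = FALSE)
  leads <- rep(seq_along(per_lead_peaks),
               vapply(per_lead_peaks, length, integer(1)))
  n <- length(times)
  if (n == 0) return(numeric(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(times[i] - times[j]) <= tolerance + 1e-12) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- numeric(0)
  for (g in unique(roots)) {
    idx <- which(roots == g)
    tt <- times[idx]; ll <- leads[idx]
    med0 <- stats::median(tt)
    keep <- vapply(split(seq_along(tt), ll),
                   function(ii) ii[which.min(abs(tt[ii] - med0))], integer(1))
    tt2 <- tt[keep]; ll2 <- ll[keep]
    if (length(unique(ll2)) >= min_leads) out <- c(out, stats::median(tt2))
  }
  sort(out)
}

# random small consensus instance: <= 5 beats, 12 leads, jitter <= 15 ms,
# occasional spurious single-lead peaks
random_consensus_instance <- function(seed) {
  set.seed(seed)
  k <- sample(1:5, 1)
  base <- sort(runif(k, 0.5, 4.5))
  while (k > 1 && min(diff(base)) < 0.2) base <- sort(runif(k, 0.5, 4.5))
  lapply(1:12, function(j) {
    t <- base[runif(k) < 0.75]
    t <- t + runif(length(t), -0.015, 0.015)
    if (runif(1) < 0.2) t <- c(t, runif(1, 0.5, 4.5))
    sort(t)
  })
}

# tiny linear age "model" over raw samples, for exact integrated-gradients
# checks: f(x) = sum(w * x) + intercept
linear_model <- function(w, intercept = 0) {
  list(
    predict = function(record) sum(w * record$signals) + intercept,
    gradient = function(record) w
  )
}
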