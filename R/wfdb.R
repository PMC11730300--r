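# Minimal single-segment WFDB (format 16) reader/writer: one .hea text header
# plus one interleaved little-endian int16 .dat per record. Covers exactly
# what this package writes; not a general-purpose WFDB implementation.

WFDB_GAIN <- 200  # ADC units per mV -> 5 uV resolution

#' Write an ECG record as a WFDB record
#'
#' Writes `<name>.hea` and `<name>.dat` (format 16, little-endian, gain
#' recorded as `200/mV`). Subject metadata is stored in `#` comment lines.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if missing).
#' @param name Record name (basename of the two files).
#' @return Invisibly, the path to the header file.
#' @export
write_wfdb_record <- function(record, dir, name) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- ncol(record$signals)
  adc <- round(record$signals * WFDB_GAIN)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  adc <- matrix(as.integer(adc), nrow = 12)

  chks <- as.integer((rowSums(adc) %% 65536 + 65536) %% 65536)
  chks[chks > 32767] <- chks[chks > 32767] - 65536L

  hea <- c(
    sprintf("%s 12 %g %d", name, record$fs, n),
    sprintf("%s.dat 16 %d/mV 16 0 %d %d 0 %s",
            name, WFDB_GAIN, adc[, 1], chks, ECG_LEADS),
    sprintf("# subject_id: %s", record$subject_id),
    sprintf("# exam: %s", record$exam),
    sprintf("# age_at_exam: %s", record$age_at_exam),
    sprintf("# sex: %s", record$sex)
  )
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  con <- file(file.path(dir, paste0(name, ".dat")), "wb")
  on.exit(close(con))
  # column-major vector = sample-major interleaving (lead 1..12 per sample)
  writeBin(as.integer(adc), con, size = 2, endian = "little")
  invisible(file.path(dir, paste0(name, ".hea")))
}

#' Read a WFDB record written by [write_wfdb_record()]
#'
#' @param dir Directory containing the record.
#' @param name Record name.
#' @return An [ecg_record()] (signals in mV).
#' @export
read_wfdb_record <- function(dir, name) {
  hea <- readLines(file.path(dir, paste0(name, ".hea")))
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  if (nsig != 12) abort("expected a 12-lead record.")
  gain <- as.numeric(sub("/mV$", "", strsplit(hea[2], "\\s+")[[1]][3]))

  meta <- function(key, cast = identity) {
    ln <- grep(paste0("^# ", key, ":"), hea, value = TRUE)
    if (length(ln) == 0) return(NA)
    v <- trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
    if (v %in% c("NA", "")) NA else cast(v)
  }
  con <- file(file.path(dir, paste0(name, ".dat")), "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = nsig * n, size = 2, endian = "little",
                 signed = TRUE)
  x <- matrix(raw, nrow = nsig) / gain
  ecg_record(x, fs = fs,
             subject_id = as.character(meta("subject_id")),
             exam = suppressWarnings(as.integer(meta("exam"))),
             age_at_exam = suppressWarnings(as.numeric(meta("age_at_exam"))),
             sex = as.character(meta("sex")))
}

#' Write a simulated cohort to disk
#'
#' Writes one WFDB record per ECG, the per-exam cohort table as
#' `cohort.csv`, and a JSON manifest carrying the full generator
#' configuration (including the seed), so the cohort can be regenerated or
#' re-read exactly.
#'
#' @param sim An `ecg_cohort` from [simulate_cohort()].
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_cohort <- function(sim, out_dir) {
  stopifnot(inherits(sim, "ecg_cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(sim$cohort, file.path(out_dir, "cohort.csv"))
  rec_names <- character(0)
  if (!is.null(sim$records) && length(sim$records) > 0) {
    rec_names <- names(sim$records)
    for (nm in rec_names) write_wfdb_record(sim$records[[nm]], out_dir, nm)
  }
  cfg <- unclass(sim$config)
  manifest <- list(config = cfg, records = rec_names,
                   n_rows = nrow(sim$cohort))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list of class `ecg_cohort` with `cohort`, `records` and the
#'   manifest `config` (as a plain list).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cohort <- readr::read_csv(file.path(dir, "cohort.csv"),
                            show_col_types = FALSE,
                            col_types = readr::cols(subject_id = "c"))
  if (nrow(cohort) > 0 && "true_group" %in% names(cohort)) {
    cohort$true_group <- factor(cohort$true_group, levels = AGING_GROUPS)
  }
  records <- NULL
  if (length(manifest$records) > 0) {
    records <- lapply(manifest$records, function(nm) read_wfdb_record(dir, nm))
    names(records) <- manifest$records
  } else if (!is.null(manifest$records)) {
    records <- list()
  }
  structure(list(cohort = cohort, records = records, config = manifest$config),
            class = "ecg_cohort")
}
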