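# Minimal WFDB (PhysioNet waveform database) format-16 support: enough to
# round-trip single-channel records for the real-data ingestion path.

#' Write a single-channel WFDB record (format 16)
#'
#' Writes `<record>.hea` and `<record>.dat` with 16-bit little-endian samples
#' quantised by `gain` counts per physical unit.
#'
#' @param dir directory for the record files.
#' @param record record name.
#' @param signal numeric vector (physical units).
#' @param fs sampling rate in Hz.
#' @param gain ADC counts per physical unit (default 200).
#' @param units physical unit string (default "mV").
#' @return the record path prefix (`file.path(dir, record)`), invisibly.
#' @export
write_wfdb <- function(dir, record, signal, fs, gain = 200, units = "mV") {
  stopifnot(is.numeric(signal), fs > 0, gain > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  digital <- as.integer(round(signal * gain))
  if (any(abs(digital) > 32767)) stop("signal overflows 16-bit range at this gain")
  hea <- c(
    sprintf("%s 1 %g %d", record, fs, length(signal)),
    sprintf("%s.dat 16 %g(0)/%s 16 0 %d 0 0 ECG", record, gain, units,
            digital[1])
  )
  writeLines(hea, file.path(dir, paste0(record, ".hea")))
  con <- file(file.path(dir, paste0(record, ".dat")), "wb")
  on.exit(close(con))
  writeBin(digital, con, size = 2L, endian = "little")
  invisible(file.path(dir, record))
}

#' Read a single-channel WFDB record (format 16)
#'
#' @param record path prefix of the record (without extension).
#' @return list with `signal` (physical units), `fs`, `n` and `record` name.
#' @export
read_wfdb <- function(record) {
  hea <- readLines(paste0(record, ".hea"))
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  if (nsig != 1L) stop("only single-channel records are supported")
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  sigline <- strsplit(trimws(hea[2]), "\\s+")[[1]]
  if (sigline[2] != "16") stop("only WFDB format 16 is supported")
  gspec <- sigline[3]
  gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gspec)))
  baseline <- if (grepl("\\(", gspec))
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gspec)) else 0
  con <- file(paste0(record, ".dat"), "rb")
  on.exit(close(con))
  digital <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                     endian = "little")
  if (length(digital) != n) stop("corrupt record: sample count mismatch")
  list(signal = (digital - baseline) / gain, fs = fs, n = n,
       record = basename(record))
}

#' Read WFDB records into a task dataset
#'
#' Adapter for the real-data path: each record becomes one labeled segment;
#' all records must share length and sampling rate.
#'
#' @param records character vector of record path prefixes.
#' @param label integer labels, one per record.
#' @param task_id task id for the resulting dataset.
#' @param split split per record (default all "train").
#' @param patient_id per-record patient id (default the record name).
#' @return a `task_dataset`.
#' @export
wfdb_task <- function(records, label, task_id = 1L,
                      split = rep("train", length(records)),
                      patient_id = basename(records)) {
  recs <- lapply(records, read_wfdb)
  ln <- unique(vapply(recs, `[[`, integer(1), "n"))
  fs <- unique(vapply(recs, `[[`, numeric(1), "fs"))
  if (length(ln) != 1L || length(fs) != 1L)
    stop("records differ in length or sampling rate")
  sig <- do.call(rbind, lapply(recs, `[[`, "signal"))
  task_dataset(task_id, sig, label, basename(records), patient_id, split)
}
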