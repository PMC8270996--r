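#' Write a task stream to disk
#'
#' Serialises a stream as a delimited manifest (`manifest.csv`: instance_id,
#' task_id, label, split, patient_id, offset, length), a flat little-endian
#' double array container (`signals.bin`) and a JSON metadata file
#' (`stream.json`). The double container makes write/read round trips
#' bitwise exact.
#'
#' @param stream a `task_stream`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "task_stream"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(path, "signals.bin"), "wb")
  on.exit(close(con))
  rows <- list()
  offset <- 0
  for (tk in stream$tasks) {
    for (i in seq_along(tk$instance_id)) {
      writeBin(as.double(tk$signal[i, ]), con, size = 8L, endian = "little")
      rows[[length(rows) + 1L]] <- data.frame(
        instance_id = tk$instance_id[i], task_id = tk$task_id,
        label = tk$label[i], split = tk$split[i],
        patient_id = tk$patient_id[i], offset = offset,
        length = ncol(tk$signal), stringsAsFactors = FALSE)
      offset <- offset + ncol(tk$signal)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(path, "manifest.csv"), row.names = FALSE)
  meta <- list(scenario = stream$scenario, head_policy = stream$head_policy,
               L = stream$L, fs = stream$fs, n_classes = stream$n_classes,
               class_sets = lapply(stream$tasks, `[[`, "class_set"),
               task_ids = vapply(stream$tasks, `[[`, integer(1), "task_id"))
  jsonlite::write_json(meta, file.path(path, "stream.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a task stream written by [write_stream()]
#'
#' @param path directory containing `manifest.csv`, `signals.bin` and
#'   `stream.json`.
#' @return a `task_stream`; signals are bitwise identical to what was
#'   written.
#' @export
read_stream <- function(path) {
  manifest <- read.csv(file.path(path, "manifest.csv"),
                       stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(path, "stream.json"),
                              simplifyVector = TRUE)
  bin <- file.path(path, "signals.bin")
  expected <- sum(manifest$length) * 8
  if (file.info(bin)$size != expected)
    stop("corrupt stream: signal container size does not match the manifest")
  con <- file(bin, "rb")
  on.exit(close(con))
  all_sig <- readBin(con, "double", n = sum(manifest$length), size = 8L,
                     endian = "little")
  tasks <- lapply(seq_along(meta$task_ids), function(j) {
    tid <- meta$task_ids[j]
    m <- manifest[manifest$task_id == tid, , drop = FALSE]
    if (!nrow(m)) stop("corrupt stream: manifest has no rows for task ", tid)
    sig <- t(vapply(seq_len(nrow(m)), function(i)
      all_sig[m$offset[i] + seq_len(m$length[i])], numeric(m$length[1])))
    cs <- if (is.list(meta$class_sets)) meta$class_sets[[j]] else meta$class_sets[j, ]
    task_dataset(tid, sig, m$label, m$instance_id, m$patient_id, m$split,
                 class_set = as.integer(cs))
  })
  str <- new_task_stream(meta$scenario, tasks, meta$L, meta$fs, meta$n_classes)
  if (str$head_policy != meta$head_policy)
    stop("corrupt stream: inconsistent head policy")
  str
}
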