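#' Write a recording dataset to a directory of CSV files
#'
#' Layout: `manifest.json` (the [dataset_manifest()] fields), `index.json`
#' (one row per recording: label, subject, session, repetition, file
#' names), and per recording `recNNNN_emg.csv` / `recNNNN_events.csv` in
#' the package's CSV interchange formats.
#'
#' @param dataset list `(recordings, manifest)` as produced by
#'   [generate_dataset()].
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(unclass(dataset$manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  idx <- lapply(seq_along(dataset$recordings), function(i) {
    r <- dataset$recordings[[i]]
    emg_f <- sprintf("rec%04d_emg.csv", i)
    ev_f <- sprintf("rec%04d_events.csv", i)
    write_emg(r$emg, file.path(dir, emg_f))
    write_events(r$dvs, file.path(dir, ev_f))
    list(label = r$label, subject = r$subject, session = r$session,
         repetition = r$repetition, emg = emg_f, events = ev_f)
  })
  jsonlite::write_json(idx, file.path(dir, "index.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a recording dataset written by [write_dataset()]
#' @param dir dataset directory.
#' @return list `(recordings, manifest)`.
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  manifest <- dataset_manifest(man$n_subjects, man$n_sessions,
                               man$n_repetitions, man$n_gestures,
                               man$n_chunks_per_recording,
                               man$recording_duration_s,
                               man$chunk_duration_ms)
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = FALSE)
  recordings <- lapply(idx, function(r)
    list(emg = load_emg(file.path(dir, r$emg)),
         dvs = load_events(file.path(dir, r$events)),
         label = r$label, subject = r$subject, session = r$session,
         repetition = r$repetition))
  list(recordings = recordings, manifest = manifest)
}
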