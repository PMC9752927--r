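#' Write a recording as a delimited matrix with a JSON sidecar
#'
#' The samples x channels matrix goes to `<prefix>.tsv` (header = electrode
#' labels) and the metadata (sampling rate, labels, subject id, optional
#' clinical record) to `<prefix>.json`. The pair round-trips losslessly
#' through [read_recording()].
#'
#' @param rec An [eeg_recording()].
#' @param prefix File path prefix (without extension).
#' @param record Optional one-row data.frame of clinical covariates.
#' @return The prefix, invisibly.
#' @export
write_recording <- function(rec, prefix, record = NULL) {
  m <- t(rec$data)
  colnames(m) <- rec$labels
  utils::write.table(m, paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(fs = rec$fs, labels = rec$labels, subject_id = rec$subject_id)
  if (!is.null(record)) meta$record <- record
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix File path prefix (without extension).
#' @return List with `recording` (an [eeg_recording()]) and `record` (a
#'   data.frame or NULL).
#' @export
read_recording <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  if (!file.exists(tsv) || !file.exists(js)) {
    pg_stop(sprintf("missing recording file(s) at prefix '%s'", prefix),
            "pg_io_error")
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(tsv, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  rec <- eeg_recording(t(m), meta$fs, meta$labels,
                       meta$subject_id %||% "")
  list(recording = rec,
       record = if (!is.null(meta$record)) as.data.frame(meta$record) else NULL)
}

#' Write / read a pipeline configuration
#'
#' Configurations round-trip losslessly through JSON.
#'
#' @param config A [default_config()] list.
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$bands <- as.data.frame(cfg$bands)
  cfg$node_sets <- lapply(cfg$node_sets, unlist)
  structure(cfg, class = "pligraph_config")
}

#' Write a square connectivity matrix as delimited text
#'
#' @param cm A `pli_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  m <- cm$pli
  dimnames(m) <- list(cm$labels, cm$labels)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write the tidy result tables of a subject run
#'
#' One TSV per table under `dir`, named `<subject_id>_<table>.tsv`.
#'
#' @param res Result of [run_subject()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_subject_results <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sid <- res$network$subject_id[1]
  for (nm in names(res)) {
    utils::write.table(res[[nm]],
                       file.path(dir, sprintf("%s_%s.tsv", sid, nm)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
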