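#' Plain-text I/O for markers, hypnograms, cohorts and configuration
#'
#' Stimulation markers and event tables travel as tab-separated tables,
#' hypnograms as one stage per line (30-s epochs), cohort and participant
#' tables as CSV, and configurations as JSON or YAML. Recordings are
#' serialised as a TSV sample matrix plus a JSON metadata sidecar.
#'
#' @param markers marker data.frame.
#' @param path file path.
#' @name plas_io
NULL

#' @rdname plas_io
#' @export
write_markers <- function(markers, path) {
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname plas_io
#' @export
read_markers <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(out) <- c("plas_markers", "data.frame")
  out
}

#' @rdname plas_io
#' @param hypnogram character vector of stages, one per 30-s epoch.
#' @export
write_hypnogram <- function(hypnogram, path) {
  writeLines(hypnogram, path)
  invisible(path)
}

#' @rdname plas_io
#' @export
read_hypnogram <- function(path) {
  hyp <- readLines(path)
  bad <- setdiff(unique(hyp), STAGES)
  if (length(bad)) stop("unknown sleep stage(s): ", paste(bad, collapse = ", "))
  hyp
}

#' @rdname plas_io
#' @param cohort cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname plas_io
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("plas_cohort", "data.frame")
  out
}

#' @rdname plas_io
#' @param config configuration list.
#' @param format `"json"` or `"yaml"` (inferred from the extension when
#'   missing).
#' @export
write_config <- function(config, path, format = NULL) {
  format <- format %||% if (grepl("\\.ya?ml$", path)) "yaml" else "json"
  plain <- unclass(config)
  if (format == "yaml") yaml::write_yaml(plain, path)
  else jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' @rdname plas_io
#' @export
read_config <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.ya?ml$", path)) "yaml" else "json"
  raw <- if (format == "yaml") yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(plas_config, conform_config(raw, plas_config()))
}

# JSON/YAML objects come back as named lists of scalars; restore the shape
# (named vector vs nested list) the default configuration uses.
conform_config <- function(raw, default) {
  if (is.list(default)) {
    if (!is.list(raw)) return(raw)
    out <- raw
    for (nm in intersect(names(raw), names(default)))
      out[[nm]] <- conform_config(raw[[nm]], default[[nm]])
    return(out)
  }
  if (is.atomic(default)) {
    if (is.list(raw)) raw <- unlist(raw)
    # JSON drops the names of named vectors; restore them from the default
    if (!is.null(names(default)) && is.null(names(raw)) &&
        length(raw) == length(default))
      names(raw) <- names(default)
  }
  raw
}

#' @rdname plas_io
#' @param rec recording to serialise.
#' @param prefix path prefix; writes `<prefix>_signals.tsv`,
#'   `<prefix>_meta.json`, `<prefix>_hypnogram.txt`, `<prefix>_events.tsv`.
#' @param seed optional seed recorded in the metadata.
#' @export
export_recording <- function(rec, prefix, seed = NULL) {
  sig <- as.data.frame(t(rec$data))
  names(sig) <- rec$channel_names
  write.table(sig, paste0(prefix, "_signals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(rate = rec$rate, night = rec$night,
               participant = rec$participant,
               channel_names = rec$channel_names,
               layout = rec$layout, seed = seed)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  write_hypnogram(rec$hypnogram, paste0(prefix, "_hypnogram.txt"))
  write.table(rec$events, paste0(prefix, "_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname plas_io
#' @export
import_recording <- function(prefix) {
  sig <- read.table(paste0(prefix, "_signals.tsv"), header = TRUE, sep = "\t",
                    check.names = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  structure(list(data = t(as.matrix(sig)), rate = meta$rate,
                 channel_names = meta$channel_names,
                 layout = as.data.frame(meta$layout),
                 hypnogram = read_hypnogram(paste0(prefix, "_hypnogram.txt")),
                 events = read.table(paste0(prefix, "_events.tsv"),
                                     header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE),
                 night = meta$night, participant = meta$participant),
            class = "plas_recording")
}
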