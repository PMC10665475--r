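#' Write a multimodal recording as delimited text
#'
#' Channels are grouped by sampling rate; each group becomes one
#' tab-delimited file `channels_<fs>Hz.txt` with a header row of channel
#' names, alongside a `recording.yaml` sidecar holding subject, scenario
#' and the file-to-channel mapping with per-file sampling rates. This is
#' the same plain-text convention the reader consumes, mirroring the
#' deposited-dataset style of one text file per rate group.
#'
#' @param rec A [multimodal_recording].
#' @param path Destination directory (created if absent).
#' @param digits Decimal digits written per sample.
#' @return Invisibly, the paths of the files written.
#' @export
write_recording <- function(rec, path, digits = 8) {
  stopifnot(inherits(rec, "multimodal_recording"))
  if (length(rec$channels) == 0L) stop("write_recording: nothing to write")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("write_recording: cannot create '", path, "'")

  fs_vals <- vapply(rec$channels, function(ch) ch$fs, numeric(1))
  groups <- split(names(rec$channels), factor(fs_vals, levels = unique(fs_vals)))
  files <- list()
  for (fs_key in names(groups)) {
    chans <- groups[[fs_key]]
    fs <- as.numeric(fs_key)
    fname <- sprintf("channels_%gHz.txt", fs)
    cols <- lapply(rec$channels[chans],
                   function(ch) round(ch$samples, digits))
    n <- unique(vapply(cols, length, integer(1)))
    if (length(n) != 1L) {
      stop("write_recording: channels at ", fs,
           " Hz have unequal lengths; cannot share a file")
    }
    dt <- data.table::as.data.table(cols)
    data.table::fwrite(dt, file.path(path, fname), sep = "\t")
    files[[fname]] <- list(channels = as.list(chans), fs = fs)
  }
  meta <- list(subject_id = rec$subject_id, scenario = rec$scenario,
               files = files)
  yaml::write_yaml(meta, file.path(path, "recording.yaml"))
  invisible(file.path(path, c(names(files), "recording.yaml")))
}

detect_delimiter <- function(file) {
  line <- readLines(file, n = 1L)
  for (sep in c("\t", ",", ";")) {
    if (grepl(sep, line, fixed = TRUE)) return(sep)
  }
  " "
}

read_delimited_numeric <- function(file, sep = "auto") {
  if (identical(sep, "auto")) sep <- detect_delimiter(file)
  dt <- data.table::fread(file, sep = sep, header = TRUE,
                          colClasses = "character", data.table = TRUE)
  out <- vector("list", ncol(dt))
  names(out) <- names(dt)
  for (j in seq_along(out)) {
    raw <- dt[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(raw %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf(
        "read_recording: non-numeric value '%s' at row %d, column '%s' of %s",
        raw[bad[1]], bad[1], names(dt)[j], basename(file)))
    }
    if (anyNA(num)) {
      stop(sprintf("read_recording: missing value at row %d, column '%s' of %s",
                   which(is.na(num))[1], names(dt)[j], basename(file)))
    }
    out[[j]] <- num
  }
  out
}

#' Read a multimodal recording from delimited text files
#'
#' The column-to-channel mapping is resolved from, in order of precedence:
#' an explicit `channel_map` argument, a `channel_map` attached to the
#' configuration (see [read_config]), or a `recording.yaml` sidecar in the
#' directory (as written by [write_recording]). A mapping is a named list
#' `file -> list(channels = <column names or NULL for all>, fs = <Hz>)`.
#' Columns present in a file but not mapped are ignored with a logged
#' warning; a mapped column missing from its file is an error naming the
#' channel.
#'
#' @param path Directory holding the text files (or a single file).
#' @param config Optional [pipeline_config]; its `delimiter` is honoured
#'   and a `channel_map` attribute is used if present.
#' @param channel_map Explicit mapping, overriding config and sidecar.
#' @param subject_id,scenario Metadata; required when no sidecar supplies
#'   them.
#' @param required Character vector of channel names that must be present.
#' @return A [multimodal_recording].
#' @export
read_recording <- function(path, config = NULL, channel_map = NULL,
                           subject_id = NULL, scenario = NULL,
                           required = NULL) {
  sep <- if (!is.null(config)) config$delimiter else "auto"
  meta <- NULL
  dir <- if (dir.exists(path)) path else dirname(path)
  sidecar <- file.path(dir, "recording.yaml")
  if (is.null(channel_map) && !is.null(config)) {
    channel_map <- attr(config, "channel_map")
  }
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  if (is.null(channel_map)) {
    if (is.null(meta)) {
      stop("read_recording: no channel_map given and no recording.yaml found in '",
           dir, "'")
    }
    channel_map <- meta$files
  }
  if (is.null(subject_id)) subject_id <- meta$subject_id %||% "unknown"
  if (is.null(scenario)) scenario <- meta$scenario %||% "city"

  channels <- list()
  for (fname in names(channel_map)) {
    entry <- channel_map[[fname]]
    fpath <- if (dir.exists(path)) file.path(path, fname) else path
    if (!file.exists(fpath)) stop("read_recording: file not found: ", fpath)
    cols <- read_delimited_numeric(fpath, sep)
    wanted <- unlist(entry$channels) %||% names(cols)
    missing <- setdiff(wanted, names(cols))
    if (length(missing)) {
      stop("read_recording: channel(s) ", paste(missing, collapse = ", "),
           " mapped but absent from ", fname)
    }
    ignored <- setdiff(names(cols), wanted)
    if (length(ignored)) {
      rf_log("ignoring unmapped column(s) in ", fname, ": ",
             paste(ignored, collapse = ", "), force = TRUE)
    }
    for (nm in wanted) {
      channels[[nm]] <- channel_trace(nm, cols[[nm]], entry$fs)
    }
  }
  missing_req <- setdiff(required, names(channels))
  if (length(missing_req)) {
    stop("read_recording: required channel(s) missing: ",
         paste(missing_req, collapse = ", "))
  }
  multimodal_recording(subject_id, scenario, channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
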