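#' Write a recording to paired CSV files
#'
#' The data file begins with a comment header `# participant=<id> rate=<Hz>`
#' followed by a CSV table with columns `sample_index` (0-based) and the
#' four channels by name. The companion events file has columns
#' `label,start,end` (0-based half-open sample indices); the mandatory
#' `rest` row comes first, followed by the task blocks.
#'
#' @param recording a `"nirs_recording"`.
#' @param path data CSV path.
#' @param events_path events CSV path; defaults to `<path minus .csv>_events.csv`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path,
                            events_path = default_events_path(path)) {
  stopifnot(inherits(recording, "nirs_recording"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# participant=%s rate=%s", recording$participant_id,
                     format(recording$sampling_rate)), con)
  df <- data.frame(sample_index = seq_len(nrow(recording$channels)) - 1L,
                   recording$channels, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)

  events <- rbind(
    data.frame(label = "rest", start = recording$rest_interval[1L],
               end = recording$rest_interval[2L], stringsAsFactors = FALSE),
    recording$task_blocks
  )
  utils::write.csv(events, events_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_events_path <- function(path) {
  sub("\\.csv$", "_events.csv", path)
}

#' Read a recording from paired CSV files
#'
#' Inverse of [write_recording()]. Validates the header, the channel count
#' (exactly 4), interval bounds, block disjointness, and that the `rest`
#' interval precedes all task blocks; malformed input raises an error naming
#' the offending row.
#'
#' @param path data CSV path.
#' @param events_path events CSV path.
#' @return A `"nirs_recording"`.
#' @export
read_recording <- function(path, events_path = default_events_path(path)) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("^# participant=(\\S+) rate=([0-9.eE+-]+)$", header))[[1L]]
  if (length(m) != 3L) {
    stop(sprintf("malformed header line in %s: %s", path, header), call. = FALSE)
  }
  participant_id <- m[[2L]]
  rate <- as.numeric(m[[3L]])

  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  if (!identical(names(df)[1L], "sample_index")) {
    stop("first column must be sample_index", call. = FALSE)
  }
  ch_names <- names(df)[-1L]
  if (length(ch_names) != 4L) {
    stop(sprintf("expected 4 channels, found %d (%s)", length(ch_names),
                 paste(ch_names, collapse = ", ")), call. = FALSE)
  }
  channels <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(channels)) stop("missing values in channel data", call. = FALSE)
  n <- nrow(channels)

  events <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  if (!identical(names(events), c("label", "start", "end"))) {
    stop("events file must have columns label,start,end", call. = FALSE)
  }
  if (nrow(events) < 1L || events$label[1L] != "rest") {
    stop("events row 1: mandatory 'rest' row missing", call. = FALSE)
  }
  for (i in seq_len(nrow(events))) {
    if (events$start[i] < 0 || events$end[i] > n || events$start[i] >= events$end[i]) {
      stop(sprintf("events row %d (%s): interval [%d, %d) out of series range [0, %d)",
                   i, events$label[i], events$start[i], events$end[i], n),
           call. = FALSE)
    }
  }
  blocks <- events[-1L, , drop = FALSE]
  rownames(blocks) <- NULL
  if (nrow(blocks) > 0) {
    ord <- order(blocks$start)
    b <- blocks[ord, ]
    if (any(b$start[-1L] < b$end[-nrow(b)])) {
      bad <- which(b$start[-1L] < b$end[-nrow(b)])[1L] + 1L
      stop(sprintf("events: task block %d overlaps its predecessor", bad),
           call. = FALSE)
    }
    if (any(blocks$start < events$end[1L])) {
      stop("events: rest interval must precede all task blocks", call. = FALSE)
    }
    if (!all(blocks$label %in% c("1-back", "2-back"))) {
      stop("events: task labels must be 1-back or 2-back", call. = FALSE)
    }
  }

  rec <- list(
    participant_id = participant_id,
    gender_tag = NULL,
    sampling_rate = rate,
    channels = channels,
    rest_interval = c(as.integer(events$start[1L]), as.integer(events$end[1L])),
    task_blocks = data.frame(label = blocks$label,
                             start = as.integer(blocks$start),
                             end = as.integer(blocks$end),
                             stringsAsFactors = FALSE),
    misleading = NA
  )
  class(rec) <- "nirs_recording"
  rec
}

#' Write / read a cohort directory
#'
#' A cohort is a directory of paired recording CSVs plus a `cohort.yaml`
#' manifest listing the participants in order and the sampling rate.
#'
#' @param cohort a `"nirs_cohort"`.
#' @param dir target directory (created if needed).
#' @return `dir` (write) or a `"nirs_cohort"` (read).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nirs_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(cohort, function(r) r$participant_id, character(1))
  for (rec in cohort) {
    write_recording(rec, file.path(dir, paste0(rec$participant_id, ".csv")))
  }
  manifest <- list(participants = as.list(ids),
                   sampling_rate = cohort[[1L]]$sampling_rate,
                   n_participants = length(cohort))
  yaml::write_yaml(manifest, file.path(dir, "cohort.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "cohort.yaml")
  if (!file.exists(manifest_path)) {
    stop(sprintf("no cohort.yaml manifest in %s", dir), call. = FALSE)
  }
  manifest <- yaml::read_yaml(manifest_path)
  cohort <- lapply(manifest$participants, function(id) {
    read_recording(file.path(dir, paste0(id, ".csv")))
  })
  class(cohort) <- "nirs_cohort"
  cohort
}
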