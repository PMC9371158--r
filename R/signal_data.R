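## Core data model: fixed-length tri-axial accelerometer windows and the
## on-disk dataset directory (windows.npy + meta.tsv + schema.json).

#' Construct a single sensor window
#'
#' A window is a fixed-length, multi-axis slice of an accelerometer recording
#' in m/s^2, labelled with the activity performed, the subject identifier and
#' a trial index. Timesteps are 0-based: sample `i` occurs at
#' `i / sample_rate_hz` seconds.
#'
#' @param values numeric matrix, timesteps x axes, acceleration in m/s^2.
#' @param activity character scalar activity label.
#' @param subject integer subject identifier.
#' @param trial non-negative integer trial index.
#' @param sample_rate_hz sampling rate in Hz (default 50).
#' @return an object of class `signal_window`.
#' @export
signal_window <- function(values, activity, subject, trial = 1L,
                          sample_rate_hz = 50) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("window contains missing values", call. = FALSE)
  if (!is.numeric(values)) stop("window values must be numeric", call. = FALSE)
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive", call. = FALSE)
  structure(
    list(values = values, activity = as.character(activity),
         subject = as.integer(subject), trial = as.integer(trial),
         sample_rate_hz = as.numeric(sample_rate_hz)),
    class = "signal_window"
  )
}

#' @export
print.signal_window <- function(x, ...) {
  cat(sprintf("<signal_window> %d x %d @ %g Hz | activity=%s subject=%d trial=%d\n",
              nrow(x$values), ncol(x$values), x$sample_rate_hz,
              x$activity, x$subject, x$trial))
  invisible(x)
}

#' Construct a windowed accelerometer dataset
#'
#' The container holds all windows in one `n x timesteps x axes` array plus a
#' metadata table, an ordered activity vocabulary and a sorted subject roster.
#' Not every subject need appear in every activity.
#'
#' @param values numeric array, `n_windows x n_timesteps x n_axes`.
#' @param meta data frame with columns `activity`, `subject`, `trial`
#'   (one row per window, in window order).
#' @param activity_vocabulary ordered character vector of allowed labels;
#'   defaults to the labels present, in order of first appearance.
#' @param subject_roster sorted integer vector of subject ids; defaults to the
#'   subjects present.
#' @param sample_rate_hz sampling rate shared by all windows (default 50).
#' @return an object of class `har_dataset`.
#' @export
har_dataset <- function(values, meta, activity_vocabulary = NULL,
                        subject_roster = NULL, sample_rate_hz = 50) {
  if (length(dim(values)) != 3L) {
    stop("values must be a 3-d array (windows x timesteps x axes)", call. = FALSE)
  }
  meta <- as.data.frame(meta)
  if (nrow(meta) != dim(values)[1]) {
    stop(sprintf("metadata rows (%d) do not match window count (%d)",
                 nrow(meta), dim(values)[1]), call. = FALSE)
  }
  if (is.null(activity_vocabulary)) {
    activity_vocabulary <- unique(as.character(meta$activity))
  }
  if (is.null(subject_roster)) {
    subject_roster <- sort(unique(as.integer(meta$subject)))
  }
  meta$activity <- as.character(meta$activity)
  meta$subject <- as.integer(meta$subject)
  meta$trial <- as.integer(meta$trial)
  structure(
    list(values = values, meta = meta,
         activity_vocabulary = as.character(activity_vocabulary),
         subject_roster = as.integer(subject_roster),
         n_timesteps = dim(values)[2], n_axes = dim(values)[3],
         sample_rate_hz = as.numeric(sample_rate_hz)),
    class = "har_dataset"
  )
}

#' @export
print.har_dataset <- function(x, ...) {
  cat(sprintf("<har_dataset> %d windows of %d x %d @ %g Hz\n",
              n_windows(x), x$n_timesteps, x$n_axes, x$sample_rate_hz))
  cat(sprintf("  %d activities, %d subjects\n",
              length(x$activity_vocabulary), length(x$subject_roster)))
  invisible(x)
}

#' Number of windows in a dataset
#' @param dataset a `har_dataset`.
#' @return integer count.
#' @export
n_windows <- function(dataset) dim(dataset$values)[1]

#' Extract one window from a dataset
#' @param dataset a `har_dataset`.
#' @param i window index (1-based).
#' @return a `signal_window`.
#' @export
get_window <- function(dataset, i) {
  stopifnot(i >= 1, i <= n_windows(dataset))
  v <- dataset$values[i, , ]
  dim(v) <- c(dataset$n_timesteps, dataset$n_axes)
  signal_window(v, dataset$meta$activity[i], dataset$meta$subject[i],
                dataset$meta$trial[i], dataset$sample_rate_hz)
}

#' Validate a dataset against its structural invariants
#'
#' Checks window shape, absence of missing values, label membership in the
#' activity vocabulary and subject membership in the roster. Violations are
#' reported with stable issue codes, never thrown.
#'
#' Issue codes: `LENGTH_MISMATCH`, `AXES_MISMATCH`, `MISSING_VALUES`,
#' `UNKNOWN_LABEL`, `UNKNOWN_SUBJECT`, `BAD_RATE`, `META_MISMATCH`.
#'
#' @param dataset a `har_dataset`.
#' @return a list of class `validation_report` with elements `ok` (logical)
#'   and `issues` (data frame: `code`, `message`, `window`).
#' @export
validate_dataset <- function(dataset) {
  issues <- list()
  add <- function(code, message, window = NA_integer_) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, message = message, window = window,
      stringsAsFactors = FALSE)
  }
  if (dataset$sample_rate_hz <= 0) {
    add("BAD_RATE", sprintf("sample_rate_hz = %g is not positive",
                            dataset$sample_rate_hz))
  }
  if (nrow(dataset$meta) != n_windows(dataset)) {
    add("META_MISMATCH", "metadata row count differs from window count")
  }
  dims <- dim(dataset$values)
  if (dims[2] != dataset$n_timesteps) {
    add("LENGTH_MISMATCH", sprintf("array has %d timesteps, expected %d",
                                   dims[2], dataset$n_timesteps))
  }
  if (dims[3] != dataset$n_axes) {
    add("AXES_MISMATCH", sprintf("array has %d axes, expected %d",
                                 dims[3], dataset$n_axes))
  }
  n <- min(n_windows(dataset), nrow(dataset$meta))
  for (i in seq_len(n)) {
    if (anyNA(dataset$values[i, , ])) {
      add("MISSING_VALUES", "window contains missing values", i)
    }
    if (!(dataset$meta$activity[i] %in% dataset$activity_vocabulary)) {
      add("UNKNOWN_LABEL",
          sprintf("activity '%s' not in vocabulary", dataset$meta$activity[i]), i)
    }
    if (!(dataset$meta$subject[i] %in% dataset$subject_roster)) {
      add("UNKNOWN_SUBJECT",
          sprintf("subject %d not in roster", dataset$meta$subject[i]), i)
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(code = character(), message = character(), window = integer())
  structure(list(ok = nrow(issues) == 0L, issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("dataset OK\n") else {
    cat(nrow(x$issues), "issue(s):\n")
    print(x$issues)
  }
  invisible(x)
}

#' Write a dataset directory
#'
#' Layout: `windows.npy` (float32, windows x timesteps x axes, C order),
#' `meta.tsv` (tab-separated, header `index  activity  subject  trial`,
#' 0-based index, UTF-8, newline-terminated) and `schema.json`. Overwrites
#' idempotently; two writes of the same dataset yield byte-identical text
#' files.
#'
#' @param dataset a `har_dataset`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)

  write_npy(dataset$values, file.path(path, "windows.npy"), dtype = "float32")

  meta_lines <- c(
    "index\tactivity\tsubject\ttrial",
    if (n_windows(dataset) > 0)
      sprintf("%d\t%s\t%d\t%d", seq_len(n_windows(dataset)) - 1L,
              dataset$meta$activity, dataset$meta$subject, dataset$meta$trial)
  )
  writeLines(meta_lines, file.path(path, "meta.tsv"), useBytes = TRUE)

  schema <- list(
    n_timesteps = dataset$n_timesteps, n_axes = dataset$n_axes,
    sample_rate_hz = dataset$sample_rate_hz,
    activity_vocabulary = dataset$activity_vocabulary,
    subject_roster = dataset$subject_roster
  )
  writeLines(jsonlite::toJSON(schema, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(path, "schema.json"), useBytes = TRUE)
  invisible(path)
}

#' Read a dataset directory
#'
#' Inverse of [write_dataset()]. Window order matches `meta.tsv` row order.
#'
#' @param path dataset directory.
#' @return a `har_dataset`.
#' @export
read_dataset <- function(path) {
  for (f in c("windows.npy", "meta.tsv", "schema.json")) {
    if (!file.exists(file.path(path, f))) {
      stop("dataset directory is missing file: ", f, call. = FALSE)
    }
  }
  schema <- jsonlite::fromJSON(file.path(path, "schema.json"))
  values <- read_npy(file.path(path, "windows.npy"))
  meta <- utils::read.delim(file.path(path, "meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c("integer", "character",
                                           "integer", "integer"))
  if (nrow(meta) == 0L && length(values) == 0L) {
    values <- array(numeric(0),
                    dim = c(0L, schema$n_timesteps, schema$n_axes))
  }
  if (length(dim(values)) != 3L || dim(values)[1] != nrow(meta)) {
    stop(sprintf(
      "format error: windows.npy holds %d window(s) but meta.tsv has %d row(s)",
      if (length(dim(values)) == 3L) dim(values)[1] else NA_integer_,
      nrow(meta)), call. = FALSE)
  }
  har_dataset(values, meta[, c("activity", "subject", "trial")],
              activity_vocabulary = schema$activity_vocabulary,
              subject_roster = schema$subject_roster,
              sample_rate_hz = schema$sample_rate_hz)
}

#' Load an external archive into a dataset
#'
#' Best-effort adapter for third-party archives whose windows are stored as
#' flat records. The `"unimib"` layout expects a matrix of flat records of
#' length `3 * window_length` (concatenated per-axis blocks by default:
#' axis 1 first, then axis 2, then axis 3) plus activity/subject/trial label
#' vectors. The archive internals are not standardized, so the layout is
#' configurable and should be verified against the actual download.
#'
#' @param records numeric matrix, one flat record per row, or a path to a
#'   `.npy` file holding it.
#' @param activity,subject,trial label vectors, one entry per record
#'   (trial defaults to 1).
#' @param layout adapter name; only `"unimib"` is provided.
#' @param window_length samples per axis (default 151).
#' @param interleaved if `TRUE`, samples alternate across axes
#'   (x1,y1,z1,x2,...) instead of concatenated per-axis blocks.
#' @param sample_rate_hz sampling rate (default 50).
#' @return a `har_dataset`.
#' @export
load_external_archive <- function(records, activity, subject, trial = NULL,
                                  layout = "unimib", window_length = 151L,
                                  interleaved = FALSE, sample_rate_hz = 50) {
  if (!identical(layout, "unimib")) {
    stop("unknown archive layout: ", layout, call. = FALSE)
  }
  if (is.character(records)) records <- read_npy(records)
  records <- as.matrix(records)
  n_axes <- 3L
  if (ncol(records) %% n_axes != 0L ||
      ncol(records) != n_axes * window_length) {
    stop(sprintf(
      "format error: record length %d does not divide into %d axes of %d samples",
      ncol(records), n_axes, window_length), call. = FALSE)
  }
  n <- nrow(records)
  if (length(activity) != n || length(subject) != n) {
    stop("label vectors must have one entry per record", call. = FALSE)
  }
  if (is.null(trial)) trial <- rep(1L, n)

  values <- array(NA_real_, dim = c(n, window_length, n_axes))
  for (a in seq_len(n_axes)) {
    cols <- if (interleaved) seq(a, by = n_axes, length.out = window_length)
            else ((a - 1L) * window_length + 1L):(a * window_length)
    values[, , a] <- records[, cols]
  }
  har_dataset(values,
              data.frame(activity = as.character(activity),
                         subject = as.integer(subject),
                         trial = as.integer(trial)),
              sample_rate_hz = sample_rate_hz)
}
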