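#' Read an epoch-count CSV
#'
#' Reads minute-epoch (or finer) triaxial counts from either an
#' ActiGraph-style export (`dialect = "actigraph_header"`: a metadata header
#' block followed by per-epoch axis columns) or a plain timestamped CSV
#' (`dialect = "plain"`: columns `timestamp, axis1, axis2, axis3[, vm]`).
#' The vector magnitude is always recomputed from the axis counts.
#'
#' The ActiGraph header is accepted with or without commas; the required keys
#' are the start time, start date, and epoch period lines (exports vary by
#' ActiLife version). Plain-dialect timestamps must be strictly increasing
#' with a constant step, which becomes the epoch length.
#'
#' @param path Path to the CSV file.
#' @param dialect `"actigraph_header"` or `"plain"`.
#' @return An [epoch_series()].
#' @export
#' @examples
#' sample <- system.file("extdata", "actigraph_sample.csv",
#'                       package = "bedrestdt")
#' read_epoch_csv(sample, dialect = "actigraph_header")
read_epoch_csv <- function(path, dialect = c("actigraph_header", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "actigraph_header") {
    read_actigraph_csv(path)
  } else {
    read_plain_csv(path)
  }
}

parse_hms_seconds <- function(txt) {
  m <- regmatches(txt, regexpr("[0-9]{1,2}:[0-9]{2}:[0-9]{2}", txt))
  if (length(m) == 0L) return(NA_integer_)
  p <- as.integer(strsplit(m, ":", fixed = TRUE)[[1]])
  p[1] * 3600L + p[2] * 60L + p[3]
}

parse_actigraph_date <- function(txt) {
  txt <- trimws(txt)
  for (fmt in c("%m/%d/%Y", "%Y-%m-%d", "%d/%m/%Y")) {
    d <- as.Date(txt, format = fmt)
    if (!is.na(d)) return(d)
  }
  as.Date(NA)
}

read_actigraph_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # header block ends at the second dashed rule (or where keys stop matching)
  dashed <- grep("^-{5,}", lines)
  header_end <- if (length(dashed) >= 2) dashed[2] else {
    last_key <- max(grep("(Start Time|Start Date|Epoch Period)", lines, ignore.case = TRUE), 0)
    if (last_key == 0) stop("not an ActiGraph header file: no metadata keys found",
                            call. = FALSE)
    last_key
  }
  header <- gsub(",", " ", lines[seq_len(header_end)])

  grab <- function(key) {
    i <- grep(key, header, ignore.case = TRUE)
    if (length(i) == 0L) {
      stop(sprintf("ActiGraph header is missing a '%s' line", key), call. = FALSE)
    }
    sub(paste0(".*", key, "[^0-9]*"), "", header[i[1]], ignore.case = TRUE)
  }
  start_hms <- parse_hms_seconds(grab("Start Time"))
  start_date <- parse_actigraph_date(grab("Start Date"))
  epoch_length <- parse_hms_seconds(grab("Epoch Period"))
  if (is.na(start_hms)) {
    stop(sprintf("unparseable Start Time line (line %d region of header)",
                 grep("Start Time", header, ignore.case = TRUE)[1]), call. = FALSE)
  }
  if (is.na(start_date)) stop("unparseable Start Date in ActiGraph header", call. = FALSE)
  if (is.na(epoch_length) || epoch_length <= 0L) {
    stop("unparseable Epoch Period in ActiGraph header", call. = FALSE)
  }
  start_time <- as.POSIXct(start_date, tz = "UTC") + start_hms

  body <- lines[seq.int(header_end + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("no epoch rows after the ActiGraph header", call. = FALSE)
  fields <- strsplit(body, ",", fixed = TRUE)
  # optional column-name row
  first_numeric <- !is.na(suppressWarnings(as.numeric(fields[[1]][1])))
  if (!first_numeric) {
    body <- body[-1]
    fields <- fields[-1]
    if (length(body) == 0L) stop("no epoch rows after the column header", call. = FALSE)
  }
  nfield <- lengths(fields)
  if (length(unique(nfield)) != 1L) {
    bad <- which(nfield != nfield[1])[1]
    stop(sprintf("inconsistent column count at data row %d (%d fields, expected %d)",
                 bad, nfield[bad], nfield[1]), call. = FALSE)
  }
  if (nfield[1] < 3L) stop("ActiGraph data rows need at least 3 axis columns", call. = FALSE)
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = nfield[1], byrow = TRUE)
  if (anyNA(mat[, 1:3])) {
    stop(sprintf("non-numeric axis value at data row %d",
                 which(apply(is.na(mat[, 1:3, drop = FALSE]), 1, any))[1]),
         call. = FALSE)
  }
  epoch_series(start_time, axis1 = mat[, 1], axis2 = mat[, 2], axis3 = mat[, 3],
               epoch_length = epoch_length,
               meta = list(source = path, dialect = "actigraph_header"))
}

read_plain_csv <- function(path) {
  nf <- utils::count.fields(path, sep = ",")
  if (length(unique(nf)) != 1L) {
    stop(sprintf("inconsistent column count at line %d of %s",
                 which(nf != nf[1])[1], path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "axis1", "axis2", "axis3")
  if (!all(need %in% names(df))) {
    stop(sprintf("plain dialect requires columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  tt <- as.POSIXct(df$timestamp, tz = "UTC")
  if (anyNA(tt)) {
    stop(sprintf("unparseable timestamp at data row %d", which(is.na(tt))[1]),
         call. = FALSE)
  }
  if (nrow(df) >= 2) {
    steps <- as.numeric(diff(tt), units = "secs")
    if (any(steps <= 0)) {
      stop(sprintf("timestamps not strictly increasing at data row %d",
                   which(steps <= 0)[1] + 1L), call. = FALSE)
    }
    if (length(unique(steps)) != 1L) {
      stop(sprintf("timestamp gap at data row %d: gaps must be explicit epochs",
                   which(steps != steps[1])[1] + 1L), call. = FALSE)
    }
    epoch_length <- steps[1]
  } else {
    epoch_length <- 60L
  }
  epoch_series(tt[1], axis1 = df$axis1, axis2 = df$axis2, axis3 = df$axis3,
               epoch_length = epoch_length,
               meta = list(source = path, dialect = "plain"))
}

#' Write and read labeled epoch CSVs
#'
#' `write_labeled_csv()` writes one row per epoch with columns
#' `timestamp, axis1, axis2, axis3, vm, state`; states are written as
#' lowercase tokens (`bedrest`, `wake`, `nonwear`, `excluded` — never blank).
#' `read_labeled_csv()` inverts it, returning the series and labels;
#' the round trip reproduces counts and states exactly.
#'
#' @param series An [epoch_series()].
#' @param labels Aligned label vector (see [label_states]).
#' @param path Output/input path.
#' @return `write_labeled_csv()` returns `path` invisibly;
#'   `read_labeled_csv()` returns `list(series = , labels = )`.
#' @export
write_labeled_csv <- function(series, labels, path) {
  stopifnot(inherits(series, "epoch_series"))
  check_labels(labels, series)
  df <- data.frame(
    timestamp = format(epoch_times(series), "%Y-%m-%d %H:%M:%S"),
    axis1 = series$axis1, axis2 = series$axis2, axis3 = series$axis3,
    vm = series$vm,
    state = tolower(labels)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labeled_csv
#' @export
read_labeled_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "axis1", "axis2", "axis3", "state")
  if (!all(need %in% names(df))) {
    stop(sprintf("labeled CSV requires columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  tt <- as.POSIXct(df$timestamp, tz = "UTC")
  epoch_length <- if (nrow(df) >= 2) as.numeric(tt[2] - tt[1], units = "secs") else 60L
  series <- epoch_series(tt[1], axis1 = df$axis1, axis2 = df$axis2,
                         axis3 = df$axis3, epoch_length = epoch_length,
                         meta = list(source = path))
  labels <- toupper(df$state)
  check_labels(labels, series)
  list(series = series, labels = labels)
}

#' Write an episode table as CSV
#'
#' Serialises the output of [episode_table()] (or [classify_periods()]) with
#' columns `state, start_time, end_time, duration_min`.
#'
#' @param episodes A tibble with those columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_episode_csv <- function(episodes, path) {
  df <- as.data.frame(episodes)
  for (col in c("start_time", "end_time")) {
    if (col %in% names(df) && inherits(df[[col]], "POSIXct")) {
      df[[col]] <- format(df[[col]], "%Y-%m-%d %H:%M:%S")
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
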