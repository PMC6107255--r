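#' Read an epoch-level activity file
#'
#' Two plain-text dialects are supported.  The *simple* dialect is delimited
#' text with a `timestamp,count` header, ISO-8601 timestamps, `#` comment
#' lines (header comments of the form `# key: value` are collected into
#' `meta`), and one record per epoch.  The *awd* dialect mimics legacy
#' actiwatch exports: a 7-line header (subject id, start date `DD-MMM-YYYY`,
#' start time `HH:MM`, epoch code, age, serial, sex) followed by one count
#' per line; epoch codes 1, 2, 4 and 8 mean 15, 30, 60 and 120 s, and any
#' larger value is taken as seconds directly.
#'
#' The epoch length of the simple dialect is inferred from the first two
#' timestamps; spacing must be strictly uniform.
#'
#' @param path path to the file.
#' @param dialect `"simple"` or `"awd"`.
#' @return an [epoch_series()].
#' @seealso [write_epoch_series()]
#' @export
read_epoch_series <- function(path, dialect = c("simple", "awd")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "simple") read_simple_dialect(lines, path)
  else read_awd_dialect(lines, path)
}

read_simple_dialect <- function(lines, path) {
  meta <- list()
  is_comment <- grepl("^\\s*#", lines)
  for (cm in lines[is_comment]) {
    m <- regmatches(cm, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", cm))[[1L]]
    if (length(m) == 3L && !m[2L] %in% c("generator")) {
      meta[[trimws(m[2L])]] <- trimws(m[3L])
    }
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) stop("no records in ", path, call. = FALSE)
  header <- lines[body_idx[1L]]
  if (!grepl("^\\s*timestamp\\s*,\\s*count\\s*$", header)) {
    stop("line ", body_idx[1L], ": expected header 'timestamp,count' in ",
         path, call. = FALSE)
  }
  rec_idx <- body_idx[-1L]
  if (length(rec_idx) == 0L) stop("no records in ", path, call. = FALSE)
  parts <- strsplit(lines[rec_idx], ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad)) {
    stop("line ", rec_idx[bad[1L]], ": malformed record (expected 2 fields)",
         call. = FALSE)
  }
  ts <- as.POSIXct(vapply(parts, `[`, "", 1L), tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) {
    stop("line ", rec_idx[which(is.na(ts))[1L]], ": unparseable timestamp",
         call. = FALSE)
  }
  counts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(counts)) {
    stop("line ", rec_idx[which(is.na(counts))[1L]], ": unparseable count",
         call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("line ", rec_idx[which(counts < 0)[1L]], ": negative count",
         call. = FALSE)
  }
  if (length(ts) < 2L) {
    epoch <- 60L
  } else {
    gaps <- as.numeric(diff(ts), units = "secs")
    epoch <- gaps[1L]
    if (epoch <= 0) {
      stop("timestamps not strictly increasing near line ", rec_idx[2L],
           call. = FALSE)
    }
    off <- which(abs(gaps - epoch) > 1e-6)
    if (length(off)) {
      stop("non-uniform epoch spacing at line ", rec_idx[off[1L] + 1L],
           ": expected ", epoch, " s", call. = FALSE)
    }
  }
  subject <- if (!is.null(meta$subject)) meta$subject else "unknown"
  meta$subject <- NULL
  epoch_series(counts, ts[1L], as.integer(round(epoch)),
               subject_id = subject, meta = meta)
}

awd_epoch_codes <- c(`1` = 15L, `2` = 30L, `4` = 60L, `8` = 120L)

read_awd_dialect <- function(lines, path) {
  if (length(lines) < 8L) stop("no records in ", path, call. = FALSE)
  hdr <- lines[1:7]
  subject <- trimws(hdr[1L])
  start <- as.POSIXct(paste(trimws(hdr[2L]), trimws(hdr[3L])), tz = "UTC",
                      tryFormats = c("%d-%b-%Y %H:%M", "%Y-%m-%d %H:%M"))
  if (is.na(start)) {
    stop("line 2-3: unparseable start date/time in ", path, call. = FALSE)
  }
  code <- suppressWarnings(as.integer(trimws(hdr[4L])))
  if (is.na(code) || code <= 0L) {
    stop("line 4: bad epoch code in ", path, call. = FALSE)
  }
  epoch <- if (as.character(code) %in% names(awd_epoch_codes)) {
    awd_epoch_codes[[as.character(code)]]
  } else code
  body <- trimws(lines[-(1:7)])
  body <- body[nzchar(body)]
  if (!length(body)) stop("no records in ", path, call. = FALSE)
  counts <- suppressWarnings(as.numeric(body))
  if (anyNA(counts)) {
    stop("line ", 7L + which(is.na(counts))[1L], ": unparseable count",
         call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("line ", 7L + which(counts < 0)[1L], ": negative count",
         call. = FALSE)
  }
  epoch_series(counts, start, epoch, subject_id = subject,
               meta = list(awd_age = trimws(hdr[5L]),
                           awd_serial = trimws(hdr[6L]),
                           awd_sex = trimws(hdr[7L])))
}

#' Write an epoch-level activity file
#'
#' Writes the simple dialect: provenance and `meta` annotations as `#`
#' header comments, then `timestamp,count` records.  A series written and
#' re-read reproduces counts, start and epoch length exactly.
#'
#' @param series an [epoch_series()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_epoch_series <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  hdr <- c(
    sprintf("# generator: marmact %s", as.character(utils::packageVersion("marmact"))),
    sprintf("# subject: %s", series$subject_id))
  for (k in names(series$meta)) {
    hdr <- c(hdr, sprintf("# %s: %s", k, as.character(series$meta[[k]])[1L]))
  }
  ts <- format(series$start + (seq_along(series$counts) - 1L) *
                 series$epoch_seconds, "%Y-%m-%dT%H:%M:%S")
  rec <- paste(ts, format(series$counts, digits = 15, scientific = FALSE,
                          trim = TRUE), sep = ",")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, "timestamp,count", rec), con)
  invisible(path)
}
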