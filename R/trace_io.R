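# Plain-text interchange formats: a TSV dialect for intensity traces and a
# JSON schema for analysis results.  TSV was chosen over binary containers so
# traces stay greppable and diffable.

TRACE_MANDATORY_KEYS <- c("substrate", "concentration_nM", "frame_interval_s",
                          "mode", "seed", "version")

#' Write a trace in the package TSV dialect
#'
#' Format: UTF-8 `#key=value` header lines with keys sorted, one column
#' header row `time<TAB>donor<TAB>acceptor`, then one row per frame with
#' fixed 6-decimal floats; newline is `\n`.  Tabs and newlines are reserved
#' and must not appear in metadata values.
#'
#' @param trace A `fret_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- trace$meta
  if (is.null(names(meta)) || any(names(meta) == "")) {
    stop("all trace metadata entries must be named")
  }
  miss <- setdiff(TRACE_MANDATORY_KEYS, names(meta))
  if (length(miss)) {
    stop("trace metadata lacks mandatory key(s): ", paste(miss, collapse = ", "))
  }
  vals <- vapply(meta, function(v) as.character(v)[1], character(1))
  if (any(grepl("[\t\n]", vals)) || any(grepl("[\t\n]", names(meta)))) {
    stop("tab/newline characters are reserved and not allowed in metadata")
  }
  stopifnot(length(trace$donor) == length(trace$time),
            length(trace$acceptor) == length(trace$time))
  ord <- order(names(vals), method = "radix")
  hdr <- sprintf("#%s=%s", names(vals)[ord], vals[ord])
  body <- sprintf("%.6f\t%.6f\t%.6f", trace$time, trace$donor, trace$acceptor)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, "time\tdonor\tacceptor", body), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' Exact parse of the TSV dialect; unknown header keys are preserved
#' verbatim in `meta`.  Missing mandatory keys, ragged rows and a
#' non-uniform time grid are reported as errors naming the offending line.
#'
#' @param path File path.
#' @return A `fret_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- grepl("^#", lines)
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1] - 1L else length(lines)
  hdr <- lines[seq_len(n_hdr)]
  kv <- regmatches(hdr, regexec("^#([^=]+)=(.*)$", hdr))
  bad <- which(vapply(kv, length, integer(1)) != 3)
  if (length(bad)) {
    stop("malformed header at line ", bad[1], " of ", path)
  }
  meta <- stats::setNames(
    lapply(kv, function(m) m[3]),
    vapply(kv, function(m) m[2], character(1)))
  miss <- setdiff(TRACE_MANDATORY_KEYS, names(meta))
  if (length(miss)) {
    stop("missing mandatory key(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  }
  for (k in c("concentration_nM", "frame_interval_s", "seed")) {
    meta[[k]] <- as.numeric(meta[[k]])
  }
  if (length(lines) <= n_hdr ||
      !identical(lines[n_hdr + 1L], "time\tdonor\tacceptor")) {
    stop("expected column header 'time\\tdonor\\tacceptor' at line ",
         n_hdr + 1L, " of ", path)
  }
  data_lines <- lines[-seq_len(n_hdr + 1L)]
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 3)) {
    stop("ragged row (", nf[nf != 3][1], " fields) at line ",
         n_hdr + 1L + which(nf != 3)[1], " of ", path)
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
  if (anyNA(m)) {
    stop("non-numeric value at line ",
         n_hdr + 1L + which(apply(is.na(m), 1, any))[1], " of ", path)
  }
  time <- m[, 1]
  if (length(time) > 1) {
    dt <- diff(time)
    bad_dt <- which(abs(dt - meta$frame_interval_s) > 1e-4)
    if (length(bad_dt)) {
      stop("non-uniform time grid at line ", n_hdr + 2L + bad_dt[1],
           " of ", path)
    }
  }
  structure(list(time = time, donor = m[, 2], acceptor = m[, 3], meta = meta),
            class = "fret_trace")
}

#' Assemble an analysis result container
#'
#' A lightweight schema-versioned container for pipeline outputs (TDP
#' matrices, binding frequencies, Kd estimates, degradation statistics).
#' Every quantity added through [result_quantity()] carries an explicit
#' units field.
#'
#' @param ... Named components.
#' @return An `analysis_result` list with a `schema_version` entry.
#' @export
analysis_result <- function(...) {
  structure(c(list(schema_version = 1L), list(...)),
            class = "analysis_result")
}

#' Wrap a value with its units
#' @param value Numeric value (or vector/matrix).
#' @param units Unit string, e.g. `"s"`, `"nM"`, `"%"`.
#' @param ... Further fields stored alongside (e.g. `concentration_nM`, `n`).
#' @return A list with `value`, `units` and any extra fields.
#' @export
result_quantity <- function(value, units, ...) {
  list(value = value, units = units, ...)
}

#' Write an analysis result as JSON
#' @param result An `analysis_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  if (!inherits(result, "analysis_result")) {
    stop("write_results() expects an 'analysis_result'")
  }
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an analysis result written by [write_results()]
#' @param path File path.
#' @return An `analysis_result`.
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (is.null(x$schema_version)) {
    stop("not an analysis-result file (no schema_version): ", path)
  }
  structure(x, class = "analysis_result")
}
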