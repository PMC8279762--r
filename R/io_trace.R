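#' Construct a two-channel photon-count trace
#'
#' A trace holds the simultaneously recorded green (GFP) and red (mCherry)
#' photon counts per time bin, the canonical observable of a two-color
#' single-molecule coincidence experiment (1 ms bins by default).
#'
#' @param green,red integer vectors of photon counts per bin; equal length.
#' @param bin_width bin width in milliseconds (> 0).
#' @param metadata named character vector or list of free-form metadata
#'   (sample name, laser powers, seed, ...).
#' @return An object of class `trace_file` with fields `bin_width`, `n_bins`,
#'   `green`, `red`, `metadata`.
#' @export
trace_file <- function(green, red, bin_width = 1, metadata = list()) {
  check_counts(green, "green")
  check_counts(red, "red")
  if (length(green) != length(red)) {
    stop_param("green and red must have identical length (",
               length(green), " vs ", length(red), ")")
  }
  check_number(bin_width, "bin_width", lower = .Machine$double.xmin)
  md <- as.list(metadata)
  if (length(md)) md <- lapply(md, as.character)
  structure(
    list(bin_width = as.numeric(bin_width), n_bins = length(green),
         green = as.integer(green), red = as.integer(red), metadata = md),
    class = "trace_file"
  )
}

#' @export
print.trace_file <- function(x, ...) {
  cat("Two-channel photon trace:", x$n_bins, "bins of", x$bin_width, "ms\n")
  cat("  total green:", sum(x$green), " total red:", sum(x$red), "\n")
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a photon trace from its on-disk TSV dialect
#'
#' The format is a block of `# key: value` header lines (which must include
#' `bin_width_ms`) followed by tab-separated columns `bin`, `green`, `red`.
#' Malformed input is rejected with an error naming the offending line;
#' nothing is silently repaired.
#'
#' @param path path to a trace file.
#' @return A [trace_file()] object.
#' @seealso [write_trace()]
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_format("trace file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_header <- grepl("^#", lines)
  if (any(is_header) && !all(which(is_header) == seq_len(sum(is_header)))) {
    stop_format("header lines ('# ...') must precede data in ", path)
  }
  header <- lines[is_header]
  body <- lines[!is_header]
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) != 3L) stop_format("malformed header line: '", h, "'")
    meta[[trimws(m[2])]] <- trimws(m[3])
  }
  if (is.null(meta$bin_width_ms)) {
    stop_format("trace header must declare 'bin_width_ms' (", path, ")")
  }
  bw <- suppressWarnings(as.numeric(meta$bin_width_ms))
  if (is.na(bw) || bw <= 0) stop_format("invalid bin_width_ms: ", meta$bin_width_ms)
  meta$bin_width_ms <- NULL
  if (length(body) < 1L) stop_format("trace has no data rows: ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(cols, c("bin", "green", "red"))) {
    stop_format("expected column header 'bin\\tgreen\\tred', got '", body[1], "'")
  }
  data <- body[-1]
  n_header <- sum(is_header) + 1L
  parts <- strsplit(data, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != 3L)) {
    bad <- which(lens != 3L)[1]
    stop_format("ragged row at line ", n_header + bad, ": '", data[bad], "'")
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  gr <- suppressWarnings(as.numeric(m[, 2]))
  rd <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(gr) | is.na(rd) | gr < 0 | rd < 0 |
                 gr != floor(gr) | rd != floor(rd))
  if (length(bad)) {
    stop_format("invalid count at line ", n_header + bad[1], ": '",
                data[bad[1]], "' (counts must be non-negative integers)")
  }
  trace_file(as.integer(gr), as.integer(rd), bin_width = bw, metadata = meta)
}

#' Write a photon trace in canonical TSV form
#'
#' Canonical form: `# bin_width_ms` first, remaining metadata keys sorted,
#' then `bin\\tgreen\\tred` rows with 1-based bin indices. `read_trace()`
#' followed by `write_trace()` is byte-identical for canonical files.
#'
#' @param trace a [trace_file()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_file"))
  md <- trace$metadata
  keys <- sort(names(md))
  header <- c(sprintf("# bin_width_ms: %s", format(trace$bin_width, digits = 15)),
              sprintf("# %s: %s", keys, unlist(md[keys])))
  body <- sprintf("%d\t%d\t%d", seq_len(trace$n_bins), trace$green, trace$red)
  writeLines(c(header, "bin\tgreen\tred", body), path, useBytes = TRUE)
  invisible(path)
}
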