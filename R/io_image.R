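#' Read a single-channel grayscale image
#'
#' Supports 8/16-bit grayscale TIFF (preferred) and PNG. Returns an integer
#' matrix of raw gray levels (rows = y, columns = x). Multi-channel images
#' are rejected with an error naming the shape.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return integer matrix of gray levels.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_format("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tryCatch(tiff::readTIFF(path, as.is = TRUE),
             error = function(e) stop_format("cannot read TIFF '", path, "': ",
                                             conditionMessage(e)))
  } else if (ext == "png") {
    x <- tryCatch(png::readPNG(path),
                  error = function(e) stop_format("cannot read PNG '", path,
                                                  "': ", conditionMessage(e)))
    # png gives [0,1]; recover integer gray levels assuming 16-bit when any
    # value needs finer than 8-bit quantization
    x8 <- round(x * 255)
    if (max(abs(x * 255 - x8)) < 1e-6) round(x * 255) else round(x * 65535)
  } else {
    stop_format("unsupported image format: '", ext, "' (use TIFF or PNG)")
  }
  if (length(dim(img)) != 2L) {
    stop_format("expected a single-channel image, got shape ",
                paste(dim(img), collapse = "x"), " in ", path)
  }
  storage.mode(img) <- "integer"
  img
}

#' Write a single-channel grayscale image
#'
#' @param img integer (or numeric, rounded) matrix of gray levels.
#' @param path output path, `.tif`/`.tiff` or `.png`.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  if (!is.matrix(img)) stop_param("'img' must be a matrix")
  if (!bits %in% c(8L, 16L)) stop_param("'bits' must be 8 or 16")
  maxval <- 2^bits - 1
  x <- round(img)
  if (any(x < 0) || any(x > maxval)) {
    stop_param("gray levels outside [0, ", maxval, "]")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x / maxval, path, bits.per.sample = bits)
  } else if (ext == "png") {
    png::writePNG(x / maxval, path)
  } else {
    stop_format("unsupported image format: '", ext, "'")
  }
  invisible(path)
}

#' Serialize an analysis result to schema-versioned JSON
#'
#' Loss-free round trip for the package's result objects (classified-burst
#' coincidence results, copy-number estimates, comet records, differential
#' proteome results, ...). The class of the object is recorded so
#' [read_results()] can restore it.
#'
#' @param obj a result object (any classed list of plain fields).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  payload <- list(schema_version = 1L,
                  type = class(obj)[1],
                  data = unclass_deep(obj))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.factor(x)) return(as.character(x))
  if (is.atomic(x) && !is.null(names(x))) {
    return(lapply(stats::setNames(seq_along(x), names(x)), function(i) x[[i]]))
  }
  if (is.data.frame(x)) {
    attr(x, "smc_df") <- NULL
    return(c(list(.df = TRUE), lapply(unclass(x)[names(x)], unclass_deep)))
  }
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

reclass_deep <- function(x) {
  if (is.list(x) && isTRUE(x$.df)) {
    x$.df <- NULL
    return(as.data.frame(lapply(x, unlist_or_null), stringsAsFactors = FALSE))
  }
  if (is.list(x)) return(lapply(x, reclass_deep))
  x
}

unlist_or_null <- function(x) if (is.list(x)) unlist(x) else x

#' Read back a serialized analysis result
#'
#' @param path a `.json` file written by [write_results()].
#' @return the restored object, with its original class.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_format("results file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (is.null(payload$schema_version) || is.null(payload$type)) {
    stop_format("not a smctools results file (missing schema fields): ", path)
  }
  structure(reclass_deep(payload$data), class = payload$type)
}
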