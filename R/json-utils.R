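# Minimal JSON writer used for spectra containers and model archives.
# jsonlite's maximum-precision writer does not round-trip all doubles
# bit-exactly (e.g. pi); "%.17g" does, and the standard decimal parser on the
# read side restores the identical IEEE value. NA maps to null.

.jsonEscape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  gsub("\t", "\\t", s, fixed = TRUE)
}

.jsonNum <- function(x) {
  out <- sprintf("%.17g", x)
  bad <- is.nan(x) | is.infinite(x)
  if (any(bad, na.rm = TRUE))
    stop("non-finite value cannot be serialized", call. = FALSE)
  out[is.na(x)] <- "null"
  out
}

.jsonValue <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) {
      return(paste0("[", paste(vapply(x, .jsonValue, ""), collapse = ","), "]"))
    }
    pairs <- vapply(seq_along(x), function(i)
      paste0("\"", .jsonEscape(nm[i]), "\":", .jsonValue(x[[i]])), "")
    return(paste0("{", paste(pairs, collapse = ","), "}"))
  }
  if (is.character(x)) {
    items <- ifelse(is.na(x), "null",
                    paste0("\"", .jsonEscape(x), "\""))
  } else if (is.logical(x)) {
    items <- ifelse(is.na(x), "null", ifelse(x, "true", "false"))
  } else if (is.numeric(x)) {
    items <- .jsonNum(as.numeric(x))
  } else {
    stop("unserializable type: ", class(x)[1], call. = FALSE)
  }
  if (length(x) == 1L && is.null(dim(x))) items
  else paste0("[", paste(items, collapse = ","), "]")
}

.writeJSON <- function(x, path) {
  txt <- .jsonValue(x)
  con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeBin(charToRaw(paste0(txt, "\n")), con)
  invisible(path)
}

.readJSON <- function(path) {
  if (!file.exists(path))
    stop("file not found: '", path, "'", call. = FALSE)
  tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE),
           error = function(e) stop("corrupted or unreadable JSON in '", path,
                                    "': ", conditionMessage(e), call. = FALSE))
}

# arrays travel as {dim, data} with column-major data
.packMatrix <- function(m) list(dim = dim(m), data = as.numeric(m))

.unpackMatrix <- function(x) {
  if (is.null(x$dim) || is.null(x$data))
    stop("malformed matrix field in archive", call. = FALSE)
  matrix(as.numeric(x$data), nrow = x$dim[1], ncol = x$dim[2])
}

.packArray <- function(a) list(dim = dim(a), data = as.numeric(a))

.unpackArray <- function(x) {
  if (is.null(x$dim) || is.null(x$data))
    stop("malformed array field in archive", call. = FALSE)
  array(as.numeric(x$data), dim = as.integer(x$dim))
}
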