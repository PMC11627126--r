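#' @importFrom jsonlite toJSON fromJSON read_json write_json
NULL

# Canonical JSON I/O. Documents that must be byte-stable across runs
# (metadata.json, annotations.json, query.json, index.json) all go through
# write_canonical_json(): 2-space pretty printing, no digit truncation,
# scalars unboxed, NULLs preserved as JSON null.

read_json_doc <- function(path) {
  if (!file.exists(path)) {
    stop("JSON document not found: ", path, call. = FALSE)
  }
  out <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  out
}

to_canonical_json <- function(doc) {
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA,
                   null = "null", na = "null")
}

write_canonical_json <- function(doc, path) {
  txt <- to_canonical_json(doc)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, useBytes = TRUE)
  invisible(path)
}

# Atomic replacement: write to a temporary sibling, then rename over the
# target so concurrent readers see either the old or the new document.
write_canonical_json_atomic <- function(doc, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  write_canonical_json(doc, tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("failed to atomically replace ", path, call. = FALSE)
  }
  invisible(path)
}

# Scalars parsed from JSON arrive as length-1 lists/vectors; these helpers
# normalise without guessing at missing values.
json_scalar <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x) && length(x) == 1L) x <- x[[1L]]
  x
}

json_num_vec <- function(x) {
  if (is.null(x)) return(NULL)
  vapply(x, function(v) as.numeric(json_scalar(v)), numeric(1))
}
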