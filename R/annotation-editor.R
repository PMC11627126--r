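# Structured editing of an entry's annotations document.
#
# Nodes are addressed with RFC-6901 JSON pointers ("/descriptions/desc-x/name").
# All edit operations are pure: the input document is never modified, a new
# document is returned. Commit validates and atomically replaces
# annotations.json (write-temp-then-rename), so a concurrent reader sees
# either the old or the new document, never a partial one.

parse_pointer <- function(ptr) {
  if (identical(ptr, "") || identical(ptr, "/")) return(character())
  if (!startsWith(ptr, "/")) {
    stop("invalid JSON pointer (must start with '/'): ", ptr, call. = FALSE)
  }
  toks <- strsplit(substring(ptr, 2L), "/", fixed = TRUE)[[1L]]
  vapply(toks, function(t) gsub("~0", "~", gsub("~1", "/", t, fixed = TRUE),
                                fixed = TRUE), character(1), USE.NAMES = FALSE)
}

escape_token <- function(tok) {
  gsub("/", "~1", gsub("~", "~0", tok, fixed = TRUE), fixed = TRUE)
}

resolve_step <- function(node, tok, ptr) {
  if (is_json_object(node)) {
    if (!tok %in% names(node)) {
      stop("pointer not found: ", ptr, " (no member '", tok, "')",
           call. = FALSE)
    }
    return(match(tok, names(node)))
  }
  if (is.list(node)) {
    if (!grepl("^[0-9]+$", tok)) {
      stop("pointer not found: ", ptr, " (array index expected, got '", tok,
           "')", call. = FALSE)
    }
    i <- as.integer(tok) + 1L  # pointers index arrays from 0
    if (i < 1L || i > length(node)) {
      stop("pointer not found: ", ptr, " (index ", tok, " out of range)",
           call. = FALSE)
    }
    return(i)
  }
  stop("pointer not found: ", ptr, " (cannot descend into a scalar)",
       call. = FALSE)
}

#' Get the value at a JSON pointer
#' @param doc Parsed document.
#' @param ptr RFC-6901 JSON pointer string.
#' @return The value at the pointer.
#' @export
pointer_get <- function(doc, ptr) {
  toks <- parse_pointer(ptr)
  node <- doc
  for (tok in toks) node <- node[[resolve_step(node, tok, ptr)]]
  node
}

pointer_modify <- function(doc, toks, ptr, fn) {
  if (length(toks) == 0L) return(fn(doc))
  i <- resolve_step(doc, toks[[1L]], ptr)
  new <- pointer_modify(doc[[i]], toks[-1L], ptr, fn)
  if (is.null(new)) {
    doc[i] <- list(NULL)  # store a JSON null; do not delete the member
  } else {
    doc[[i]] <- new
  }
  doc
}

#' Replace the value at a JSON pointer
#'
#' The rest of the document is untouched; the result is re-validated when
#' it is an annotations document (callers that edit other documents can
#' skip validation).
#'
#' @param doc Parsed document.
#' @param ptr RFC-6901 pointer; must resolve.
#' @param value New value.
#' @param validate Re-validate the result with [validate_annotations()] and
#'   reject the edit on a regression.
#' @return The edited document.
#' @export
edit_at_pointer <- function(doc, ptr, value, validate = TRUE) {
  pointer_get(doc, ptr)  # existence check with a precise error
  out <- pointer_modify(doc, parse_pointer(ptr), ptr,
                        function(old) value)
  if (validate) {
    before <- length(validate_annotations(doc))
    after <- validate_annotations(out)
    if (length(after) > before) {
      stop("edit rejected, validation regression:\n  ",
           paste(after, collapse = "\n  "), call. = FALSE)
    }
  }
  out
}

.empty_values <- list(string = "", object = structure(list(), names = character()),
                      list = list(), number = 0, boolean = FALSE)

#' Change the type of the node at a pointer
#'
#' The node is replaced by the empty value of the requested kind
#' (`object` -> `{}`, `string` -> `""`, `list` -> `[]`, `number` -> `0`,
#' `boolean` -> `false`, `null` -> null).
#'
#' @param doc Parsed document.
#' @param ptr RFC-6901 pointer; must resolve.
#' @param kind One of `"string"`, `"object"`, `"list"`, `"number"`,
#'   `"boolean"`, `"null"`.
#' @return The edited document.
#' @export
retype_at_pointer <- function(doc, ptr, kind) {
  kind <- match.arg(kind, c("string", "object", "list", "number", "boolean",
                            "null"))
  pointer_get(doc, ptr)
  value <- if (kind == "null") NULL else .empty_values[[kind]]
  pointer_modify(doc, parse_pointer(ptr), ptr, function(old) value)
}

#' Append a new field to the object at a pointer
#'
#' @param doc Parsed document.
#' @param ptr Pointer to an object; must resolve.
#' @param key Field name; must not already exist.
#' @param value Field value.
#' @return The edited document.
#' @export
append_field <- function(doc, ptr, key, value) {
  node <- pointer_get(doc, ptr)
  if (!is_json_object(node)) {
    stop("pointer ", ptr, " does not resolve to an object", call. = FALSE)
  }
  if (key %in% names(node)) {
    stop("conflict: field '", key, "' already exists at ", ptr, call. = FALSE)
  }
  pointer_modify(doc, parse_pointer(ptr), ptr, function(old) {
    old[[key]] <- value
    old
  })
}

#' Search an annotations document
#'
#' Finds every node whose key or string value contains all
#' whitespace-separated keywords (case-insensitive substring match; numeric
#' and boolean leaves are not searched).
#'
#' @param doc Parsed document.
#' @param query Search string; keywords split on whitespace.
#' @return Character vector of JSON pointers, sorted.
#' @export
search_annotations <- function(doc, query) {
  keywords <- tolower(strsplit(trimws(query), "[[:space:]]+")[[1L]])
  keywords <- keywords[nzchar(keywords)]
  if (length(keywords) == 0L) return(character())
  hits <- character()
  matches <- function(s) {
    s <- tolower(s)
    all(vapply(keywords, function(k) grepl(k, s, fixed = TRUE), logical(1)))
  }
  walk <- function(node, path) {
    if (is_json_object(node)) {
      for (k in names(node)) {
        child_path <- paste0(path, "/", escape_token(k))
        if (matches(k)) hits <<- c(hits, child_path)
        walk(node[[k]], child_path)
      }
    } else if (is.list(node)) {
      for (i in seq_along(node)) {
        walk(node[[i]], paste0(path, "/", i - 1L))
      }
    } else if (is.character(node) && length(node) == 1L) {
      if (matches(node)) hits <<- c(hits, path)
    }
  }
  walk(doc, "")
  sort(unique(hits))
}

#' Commit an annotations document to the store
#'
#' Validates the document and atomically replaces the entry's
#' annotations.json; on validation failure nothing is written.
#'
#' @param db_root Database root.
#' @param key An [entry_key()].
#' @param doc Annotations document.
#' @return The annotations path, invisibly.
#' @export
commit_annotations <- function(db_root, key, doc) {
  viol <- validate_annotations(doc)
  if (length(viol) > 0L) {
    stop("refusing to commit invalid annotations:\n  ",
         paste(viol, collapse = "\n  "), call. = FALSE)
  }
  if (!entry_exists(db_root, key)) {
    stop("entry not found: ", format(key), " in ", db_root, call. = FALSE)
  }
  target <- file.path(entry_dir(db_root, key), "annotations.json")
  write_canonical_json_atomic(doc, target)
  invisible(target)
}
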