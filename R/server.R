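# Minimal read-only HTTP API over the store.
#
# Default settings bind 0.0.0.0:9000 with db_path "preprocessor/temp/test_db";
# all endpoints live under the /v1 prefix and a machine-readable API
# description is served at /docs. Every endpoint is a pure function of the
# store (handle_api_request below), so the routing logic is unit-testable
# without sockets; the httpuv wrapper only adapts request objects.
#
# Routes:
#   GET /v1/list_entries[/{source_db}]
#   GET /v1/{source_db}/{entry_id}/metadata
#   GET /v1/{source_db}/{entry_id}/annotations
#   GET /v1/{source_db}/{entry_id}/volume/{channel_id}/{time}[?max_points=N]
#   GET /v1/{source_db}/{entry_id}/segmentation/{segmentation_id}/{time}[?max_points=N]
#   GET /docs

.api_docs <- list(
  title = "voxseg entry-serving API",
  version = "v1",
  routes = list(
    list(method = "GET", path = "/v1/list_entries",
         description = "List all entries"),
    list(method = "GET", path = "/v1/list_entries/{source_db}",
         description = "List entries for one source database"),
    list(method = "GET", path = "/v1/{source_db}/{entry_id}/metadata",
         description = "Entry metadata.json, byte-equal to the store"),
    list(method = "GET", path = "/v1/{source_db}/{entry_id}/annotations",
         description = "Entry annotations.json, byte-equal to the store"),
    list(method = "GET",
         path = "/v1/{source_db}/{entry_id}/volume/{channel_id}/{time}",
         description = paste("Volume grid as an MRC body at the level chosen",
                             "by the max_points query parameter")),
    list(method = "GET",
         path = "/v1/{source_db}/{entry_id}/segmentation/{segmentation_id}/{time}",
         description = paste("Lattice segmentation grid as an MRC body at the",
                             "level chosen by the max_points query parameter"))))

api_json <- function(doc, status = 200L) {
  list(status = status, content_type = "application/json",
       body = as.character(to_canonical_json(doc)))
}

api_error <- function(status, message) {
  api_json(list(error = message), status = status)
}

api_file <- function(path, content_type) {
  list(status = 200L, content_type = content_type,
       body = readBin(path, "raw", n = file.size(path)))
}

serve_grid_payload <- function(db_root, key, role, id, time, max_points) {
  md <- read_entry_metadata(db_root, key)
  sampling <- if (role == "volume") {
    md$volumes$sampling_info
  } else {
    inv <- Filter(function(s) json_scalar(s$segmentation_id) == id,
                  md$segmentations$lattice %||% list())
    if (length(inv) == 0L) return(NULL)
    inv[[1L]]$sampling_info
  }
  if (is.null(sampling)) return(NULL)
  fac <- select_sampling_level(sampling, max_points)
  member <- file.path(role, id, time, paste0(fac, ".map"))
  ex <- tempfile("serve-")
  dir.create(ex)
  on.exit(unlink(ex, recursive = TRUE), add = TRUE)
  p <- tryCatch(extract_entry_payload(db_root, key, member, ex),
                error = function(e) NULL)
  if (is.null(p)) return(NULL)
  api_file(p, "application/octet-stream")
}

#' Handle one API request against a store
#'
#' The pure core of the HTTP server: same inputs, same response, no state
#' beyond the store directory.
#'
#' @param db_root Database root the server exposes.
#' @param method HTTP method.
#' @param path Request path (e.g. `"/v1/list_entries"`).
#' @param query Named list of query parameters (e.g. `max_points`).
#' @return List with `status`, `content_type`, `body` (character or raw).
#' @export
handle_api_request <- function(db_root, method, path, query = list()) {
  if (!identical(method, "GET")) {
    return(api_error(405L, "only GET is supported"))
  }
  path <- sub("/+$", "", path)
  if (path == "/docs") return(api_json(.api_docs))
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1L]]
  parts <- vapply(parts, utils::URLdecode, character(1), USE.NAMES = FALSE)
  if (length(parts) == 0L || parts[1L] != "v1") {
    return(api_error(404L, paste0("unknown path: ", path)))
  }
  parts <- parts[-1L]
  if (length(parts) >= 1L && parts[1L] == "list_entries") {
    src <- if (length(parts) >= 2L) parts[2L] else NULL
    listing <- suppressWarnings(list_entries(db_root, src))
    entries <- lapply(seq_len(nrow(listing)), function(i) {
      list(source_db = listing$source_db[i], entry_id = listing$entry_id[i])
    })
    return(api_json(list(entries = entries)))
  }
  if (length(parts) >= 3L) {
    key <- tryCatch(entry_key(parts[1L], parts[2L]), error = function(e) NULL)
    if (is.null(key)) return(api_error(404L, "invalid entry key"))
    if (!entry_exists(db_root, key)) {
      return(api_error(404L, paste0("entry not found: ", parts[1L], "/",
                                    parts[2L])))
    }
    ed <- entry_dir(db_root, key)
    if (length(parts) == 3L && parts[3L] == "metadata") {
      return(api_file(file.path(ed, "metadata.json"), "application/json"))
    }
    if (length(parts) == 3L && parts[3L] == "annotations") {
      return(api_file(file.path(ed, "annotations.json"), "application/json"))
    }
    if (length(parts) == 5L && parts[3L] %in% c("volume", "segmentation")) {
      role <- if (parts[3L] == "volume") "volume" else "lattice"
      max_points <- as.numeric(query$max_points %||% 1e12)
      res <- serve_grid_payload(db_root, key, role, parts[4L], parts[5L],
                                max_points)
      if (is.null(res)) {
        return(api_error(404L, paste0("payload not found: ", path)))
      }
      return(res)
    }
  }
  api_error(404L, paste0("unknown path: ", path))
}

parse_query_string <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  out <- list()
  for (kv in strsplit(qs, "&", fixed = TRUE)[[1L]]) {
    p <- strsplit(kv, "=", fixed = TRUE)[[1L]]
    if (length(p) == 2L) out[[utils::URLdecode(p[1L])]] <- utils::URLdecode(p[2L])
  }
  out
}

vs_server_app <- function(settings) {
  force(settings)
  list(call = function(req) {
    res <- tryCatch(
      handle_api_request(settings$db_path,
                         req$REQUEST_METHOD,
                         req$PATH_INFO,
                         parse_query_string(req$QUERY_STRING)),
      error = function(e) api_error(500L, conditionMessage(e)))
    list(status = res$status,
         headers = list("Content-Type" = res$content_type),
         body = res$body)
  })
}

#' Start the entry-serving HTTP API (non-blocking)
#'
#' @param settings A [server_settings()]; defaults bind 0.0.0.0:9000 over
#'   `preprocessor/temp/test_db`.
#' @return The `httpuv` server handle; stop it with
#'   [httpuv::stopServer()].
#' @export
start_vs_server <- function(settings = server_settings()) {
  httpuv::startServer(settings$host, settings$port, vs_server_app(settings))
}

#' Run the entry-serving HTTP API (blocking)
#'
#' @inheritParams start_vs_server
#' @return Does not return under normal operation.
#' @export
run_vs_server <- function(settings = server_settings()) {
  server <- start_vs_server(settings)
  on.exit(httpuv::stopServer(server), add = TRUE)
  message("serving ", settings$db_path, " at http://", settings$host, ":",
          settings$port, "/v1 (docs at /docs)")
  while (TRUE) {
    httpuv::service(250)
  }
}
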