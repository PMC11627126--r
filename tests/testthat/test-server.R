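# The routing core is a pure function of the store; most coverage runs
# without sockets. One test boots a real HTTP server in a background R
# process and talks to it over TCP.

make_served_db <- function(env = parent.frame()) {
  wd <- local_workdir(env)
  db <- file.path(wd, "db")
  key <- build_zarr_entry(db, wd)
  list(db = db, key = key)
}

test_that("list_entries endpoints mirror the store listing", {
  x <- make_served_db()
  res <- handle_api_request(x$db, "GET", "/v1/list_entries")
  expect_equal(res$status, 200L)
  doc <- jsonlite::fromJSON(res$body, simplifyVector = FALSE)
  expect_length(doc$entries, 1)
  expect_identical(doc$entries[[1]]$entry_id, x$key$entry_id)
  # oracle: the direct store call
  direct <- list_entries(x$db)
  expect_identical(vapply(doc$entries, function(e) e$entry_id, character(1)),
                   direct$entry_id)
  res2 <- handle_api_request(x$db, "GET", "/v1/list_entries/idr")
  expect_identical(res2$body, res$body)
  res3 <- handle_api_request(x$db, "GET", "/v1/list_entries/pdb")
  expect_length(jsonlite::fromJSON(res3$body, simplifyVector = FALSE)$entries, 0)
  # empty store
  empty <- file.path(tempfile(), "none")
  res4 <- handle_api_request(empty, "GET", "/v1/list_entries")
  expect_length(jsonlite::fromJSON(res4$body, simplifyVector = FALSE)$entries, 0)
})

test_that("metadata and annotations bodies are byte-equal to the store", {
  x <- make_served_db()
  for (doc in c("metadata", "annotations")) {
    res <- handle_api_request(x$db, "GET",
                              sprintf("/v1/idr/%s/%s", x$key$entry_id, doc))
    expect_equal(res$status, 200L)
    stored <- readBin(file.path(voxseg:::entry_dir(x$db, x$key),
                                paste0(doc, ".json")), "raw",
                      file.size(file.path(voxseg:::entry_dir(x$db, x$key),
                                          paste0(doc, ".json"))))
    expect_identical(res$body, stored)
  }
  nf <- handle_api_request(x$db, "GET", "/v1/idr/ghost/metadata")
  expect_equal(nf$status, 404L)
})

test_that("payload endpoints serve valid MRC bodies at the chosen level", {
  x <- make_served_db()
  path <- sprintf("/v1/idr/%s/volume/Hyb%%20probe/0", x$key$entry_id)
  res <- handle_api_request(x$db, "GET", path)
  expect_equal(res$status, 200L)
  tmp <- tempfile(fileext = ".map")
  writeBin(res$body, tmp)
  g <- read_map(tmp)  # body parses as a valid MRC map
  expect_equal(g$dims, c(48L, 48L, 8L))  # default budget -> factor 1
  # a tiny budget forces the coarser level
  res2 <- handle_api_request(x$db, "GET", path, query = list(max_points = "10"))
  writeBin(res2$body, tmp)
  g2 <- read_map(tmp)
  expect_equal(g2$dims, c(24L, 24L, 4L))  # factor 2
  # segmentation payloads work the same way
  res3 <- handle_api_request(
    x$db, "GET", sprintf("/v1/idr/%s/segmentation/cells/0", x$key$entry_id))
  expect_equal(res3$status, 200L)
  nf <- handle_api_request(x$db, "GET",
                           sprintf("/v1/idr/%s/volume/GFP/0", x$key$entry_id))
  expect_equal(nf$status, 404L)
})

test_that("responses are pure functions of the store", {
  x <- make_served_db()
  a <- handle_api_request(x$db, "GET", "/v1/list_entries")
  b <- handle_api_request(x$db, "GET", "/v1/list_entries")
  expect_identical(a, b)
  d1 <- handle_api_request(x$db, "GET", "/docs")
  expect_equal(d1$status, 200L)
  expect_match(d1$body, "/v1/list_entries")
})

test_that("default settings bind 0.0.0.0:9000 over the documented db path", {
  s <- server_settings()
  expect_identical(s$host, "0.0.0.0")
  expect_identical(s$port, 9000L)
  expect_identical(s$db_path, "preprocessor/temp/test_db")
  expect_error(server_settings(port = 70000))
})

test_that("a live server answers over TCP and restarting changes nothing", {
  skip_if_not_installed("callr")
  skip_if_not_installed("curl")
  x <- make_served_db()
  port <- 19000 + (Sys.getpid() %% 500)
  fetch <- function(path) {
    con <- curl::new_handle(timeout = 5)
    rawToChar(curl::curl_fetch_memory(
      sprintf("http://127.0.0.1:%d%s", port, path), con)$content)
  }
  boot <- function() {
    proc <- callr::r_bg(function(db, port) {
      voxseg::run_vs_server(voxseg::server_settings(host = "127.0.0.1",
                                                    port = port,
                                                    db_path = db))
    }, args = list(db = x$db, port = port))
    for (i in 1:50) {
      ok <- tryCatch({ fetch("/docs"); TRUE }, error = function(e) FALSE)
      if (ok) break
      Sys.sleep(0.2)
    }
    proc
  }
  proc <- boot()
  on.exit(proc$kill(), add = TRUE)
  body <- fetch("/v1/list_entries")
  expect_match(body, x$key$entry_id)
  md1 <- fetch(sprintf("/v1/idr/%s/metadata", x$key$entry_id))
  proc$kill()
  proc <- boot()
  md2 <- fetch(sprintf("/v1/idr/%s/metadata", x$key$entry_id))
  expect_identical(md1, md2)
})
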