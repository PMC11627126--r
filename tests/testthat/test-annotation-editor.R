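# Search and structured editing of annotations documents.

make_ann_db <- function(env = parent.frame()) {
  wd <- local_workdir(env)
  db <- file.path(wd, "db")
  key <- build_mask_entry(db, wd)
  list(db = db, key = key, doc = read_entry_annotations(db, key))
}

test_that("search finds a segmentation id in both annotation and description", {
  x <- make_ann_db()
  hits <- search_annotations(x$doc, "emd_1273_msk_1")
  expect_gte(length(hits), 2)
  expect_true(any(grepl("^/segment_annotations/", hits)))
  expect_true(any(grepl("^/descriptions/", hits)))
})

test_that("search equals an exhaustive tree-walk oracle", {
  x <- make_ann_db()
  oracle <- function(doc, keywords) {
    hits <- character()
    walk <- function(node, path) {
      if (is.list(node) && !is.null(names(node)) || (is.list(node) && length(node) == 0)) {
        for (k in names(node)) {
          p <- paste0(path, "/", k)
          if (all(vapply(keywords, function(kw)
            grepl(kw, tolower(k), fixed = TRUE), logical(1)))) hits <<- c(hits, p)
          walk(node[[k]], p)
        }
      } else if (is.list(node)) {
        for (i in seq_along(node)) walk(node[[i]], paste0(path, "/", i - 1))
      } else if (is.character(node) && length(node) == 1) {
        if (all(vapply(keywords, function(kw)
          grepl(kw, tolower(node), fixed = TRUE), logical(1)))) hits <<- c(hits, path)
      }
    }
    walk(doc, "")
    sort(unique(hits))
  }
  for (q in list("segment", "msk_2", "segment 1", "lattice msk")) {
    kws <- tolower(strsplit(q, " ")[[1]])
    expect_identical(search_annotations(x$doc, q), oracle(x$doc, kws),
                     info = q)
  }
  # multi-keyword queries require every keyword in the same node
  both <- search_annotations(x$doc, "desc msk_3")
  expect_true(all(grepl("msk_3", both)))
  expect_identical(search_annotations(list(), "anything"), character())
})

test_that("the name edit / retype / append workflow rebuilds markdown details", {
  x <- make_ann_db()
  ptr <- "/descriptions/desc-emd_1273_msk_1-1"
  doc <- edit_at_pointer(x$doc, paste0(ptr, "/name"),
                         "Microtubule (MT) network within the CTL")
  expect_identical(pointer_get(doc, paste0(ptr, "/name")),
                   "Microtubule (MT) network within the CTL")
  # null details -> {}
  doc <- retype_at_pointer(doc, paste0(ptr, "/details"), "object")
  expect_identical(pointer_get(doc, paste0(ptr, "/details")),
                   structure(list(), names = character()))
  doc <- append_field(doc, paste0(ptr, "/details"), "format", "markdown")
  doc <- append_field(doc, paste0(ptr, "/details"), "text",
                      "# Biological context\nThe **MTs** radiate out from *the polarized centrosomal area*...")
  expect_length(validate_annotations(doc), 0)
  expect_identical(pointer_get(doc, paste0(ptr, "/details/format")),
                   "markdown")
  # appending an existing key is a conflict
  expect_error(append_field(doc, paste0(ptr, "/details"), "format", "x"),
               "conflict")
})

test_that("edits are pure and set-then-set-back restores the document", {
  x <- make_ann_db()
  ptr <- "/descriptions/desc-emd_1273_msk_2-1/name"
  orig_json <- voxseg:::to_canonical_json(x$doc)
  old <- pointer_get(x$doc, ptr)
  doc2 <- edit_at_pointer(x$doc, ptr, "renamed")
  expect_identical(voxseg:::to_canonical_json(x$doc), orig_json)  # input untouched
  doc3 <- edit_at_pointer(doc2, ptr, old)
  expect_identical(voxseg:::to_canonical_json(doc3), orig_json)   # involution
})

test_that("random pointer edits agree with direct document surgery", {
  x <- make_ann_db()
  set.seed(30)
  for (i in 1:20) {
    k <- sample(seq_along(x$doc$descriptions), 1)
    id <- names(x$doc$descriptions)[k]
    value <- paste0("name-", i)
    via_ptr <- edit_at_pointer(x$doc, paste0("/descriptions/", id, "/name"),
                               value)
    via_surgery <- x$doc
    via_surgery$descriptions[[id]]$name <- value
    expect_identical(voxseg:::to_canonical_json(via_ptr),
                     voxseg:::to_canonical_json(via_surgery))
  }
})

test_that("unresolvable pointers and validation regressions are rejected", {
  x <- make_ann_db()
  expect_error(edit_at_pointer(x$doc, "/descriptions/ghost/name", "x"),
               "pointer not found")
  expect_error(retype_at_pointer(x$doc, "/nope", "object"), "pointer not found")
  expect_error(edit_at_pointer(x$doc, "/entry_id", "just-a-string"),
               "validation regression")
})

test_that("retype produces the empty value of each kind", {
  doc <- list(a = list(b = 5))
  expect_identical(pointer_get(retype_at_pointer(doc, "/a/b", "string"),
                               "/a/b"), "")
  expect_identical(pointer_get(retype_at_pointer(doc, "/a/b", "number"),
                               "/a/b"), 0)
  expect_identical(pointer_get(retype_at_pointer(doc, "/a/b", "list"),
                               "/a/b"), list())
  expect_null(pointer_get(retype_at_pointer(doc, "/a/b", "null"), "/a/b"))
  # same kind -> still the empty value
  expect_identical(pointer_get(retype_at_pointer(doc, "/a/b", "number"),
                               "/a/b"), 0)
})

test_that("commit validates, round-trips, and never writes a partial file", {
  x <- make_ann_db()
  doc <- edit_at_pointer(x$doc, "/descriptions/desc-emd_1273_msk_1-1/name",
                         "Microtubule (MT) network within the CTL")
  commit_annotations(x$db, x$key, doc)
  back <- read_entry_annotations(x$db, x$key)
  expect_identical(voxseg:::to_canonical_json(back),
                   voxseg:::to_canonical_json(doc))
  # invalid documents leave the store untouched
  bad <- doc; bad$entry_id <- NULL
  expect_error(commit_annotations(x$db, x$key, bad), "refusing to commit")
  expect_identical(voxseg:::to_canonical_json(read_entry_annotations(x$db, x$key)),
                   voxseg:::to_canonical_json(doc))
  # atomic replace: no temp debris, content is either old or new, never mixed
  files <- list.files(voxseg:::entry_dir(x$db, x$key))
  expect_false(any(grepl("tmp", files)))
})
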