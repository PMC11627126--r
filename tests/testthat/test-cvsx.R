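test_that("a minimal query expands to the entry's full inventory", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_zarr_entry(db, wd)
  md <- read_entry_metadata(db, key)
  sel <- resolve_query(list(entry_id = key$entry_id, source_db = "idr"), md)
  expect_identical(unlist(sel$channel_ids), c("DAPI", "Hyb probe"))
  expect_identical(unlist(sel$volume_time_frames), 0:2)
  expect_identical(vapply(sel$segmentations, function(s) s$kind, character(1)),
                   "lattice")
  expect_identical(sel$max_points, 1e12)
})

test_that("a channel + time query restricts volumes and segmentations", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_zarr_entry(db, wd)
  md <- read_entry_metadata(db, key)
  sel <- resolve_query(list(entry_id = key$entry_id, source_db = "idr",
                            channel_id = "Hyb probe", time = 1), md)
  expect_identical(unlist(sel$channel_ids), "Hyb probe")
  expect_identical(unlist(sel$volume_time_frames), 1L)
  expect_identical(unlist(sel$segmentations[[1]]$time_frame_indices), 1L)
})

test_that("queries naming unknown inventory fail listing valid values", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_zarr_entry(db, wd)
  md <- read_entry_metadata(db, key)
  expect_error(resolve_query(list(entry_id = key$entry_id, source_db = "idr",
                                  channel_id = "GFP"), md),
               "available: DAPI, Hyb probe")
  expect_error(resolve_query(list(entry_id = key$entry_id, source_db = "idr",
                                  time = 9), md), "available: 0, 1, 2")
  expect_error(resolve_query(list(entry_id = key$entry_id, source_db = "idr",
                                  segmentation_id = "nope"), md),
               "segmentation_id not found")
  expect_error(resolve_query(list(source_db = "idr"), md), "entry_id")
})

test_that("sampling-level selection brackets max_points and is monotone", {
  sampling <- list(`1` = list(dims = c(256, 256, 256)),
                   `2` = list(dims = c(128, 128, 128)),
                   `4` = list(dims = c(64, 64, 64)))
  # 16,777,216 voxels at factor 1; budget 10,000,000 -> factor 2 (2,097,152)
  expect_identical(select_sampling_level(sampling, 1e7), 2L)
  expect_identical(select_sampling_level(sampling, 1e12), 1L)  # default budget
  expect_identical(select_sampling_level(sampling, 10), 4L)    # coarsest fallback
  # bracketing: count(f) <= max_points < count(f/2) whenever f > 1
  counts <- c(`1` = 256^3, `2` = 128^3, `4` = 64^3)
  prev <- Inf
  for (mp in c(1e3, 1e5, 64^3, 64^3 + 1, 128^3, 2^24 - 1, 2^24, 1e9)) {
    f <- select_sampling_level(sampling, mp)
    if (f > 1 && mp >= counts[["4"]]) {
      expect_lte(counts[[as.character(f)]], mp)
      expect_gt(counts[[as.character(f / 2)]], mp)
    }
    expect_lte(f, prev)  # non-increasing as max_points grows
    prev <- f
  }
})

test_that("a minimal-query archive holds exactly the entry payloads + 4 JSON", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_map_sff_entry(db, wd)
  out <- file.path(wd, "emd-1832.cvsx")
  build_cvsx(db, list(entry_id = key$entry_id, source_db = "emdb"), out)
  members <- zip::zip_list(out)$filename
  expect_length(members, 6)  # 1 volume + 1 lattice + 4 JSON members
  expect_setequal(grep("\\.json$", members, value = TRUE),
                  c("index.json", "query.json", "annotations.json",
                    "metadata.json"))
})

test_that("round-trip reproduces exactly the resolved selection", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_zarr_entry(db, wd)
  out <- file.path(wd, "sel.cvsx")
  build_cvsx(db, list(entry_id = key$entry_id, source_db = "idr",
                      channel_id = "Hyb probe", time = 1), out)
  r <- read_cvsx(out)
  expect_identical(names(r$volumes), "Hyb probe/1")
  expect_length(r$lattices, 1)
  expect_match(names(r$lattices), "/1$")
  # payload grids equal the stored grids at the selected level
  e <- read_entry(db, key)
  hyb <- Filter(function(v) v$channel_id == "Hyb probe", e$volumes)[[1]]
  expect_lt(max(abs(r$volumes[[1]]$grid$values -
                    hyb$frames[["1"]][["1"]]$values)), 1e-6)
  # annotations and metadata are filtered to the selection
  expect_identical(unlist(r$metadata$volumes$channel_ids), "Hyb probe")
  expect_identical(unlist(r$query$volume_time_frames), 1L)
  expect_identical(r$query$requested$channel_id, "Hyb probe")
})

test_that("geometric-only queries pack one segmentation and all volume data", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_geometric_entry(db, wd)
  out <- file.path(wd, "ribo.cvsx")
  build_cvsx(db, list(entry_id = key$entry_id, source_db = "empiar",
                      segmentation_kind = "geometric-segmentation",
                      segmentation_id = "ribosomes", max_points = 1e7), out)
  r <- read_cvsx(out)
  expect_identical(names(r$geoms), "ribosomes")
  expect_length(r$geoms$ribosomes$frames[["0"]], 10)
  expect_length(r$lattices, 0)
  expect_length(r$volumes, 1)
})

test_that("output names without the .cvsx extension are rejected", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_mask_entry(db, wd, n_masks = 1)
  expect_error(build_cvsx(db, list(entry_id = key$entry_id,
                                   source_db = "emdb"),
                          file.path(wd, "x.zip")),
               "mandatory .cvsx extension")
  expect_error(build_cvsx(db, list(entry_id = "ghost", source_db = "emdb"),
                          file.path(wd, "g.cvsx")), "not found")
})

test_that("tampered archives fail validation naming the member", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_mask_entry(db, wd, n_masks = 1)
  out <- file.path(wd, "ok.cvsx")
  build_cvsx(db, list(entry_id = key$entry_id, source_db = "emdb"), out)
  expect_silent(read_cvsx(out))

  retamper <- function(mutate) {
    ex <- tempfile(); dir.create(ex)
    on.exit(unlink(ex, recursive = TRUE))
    zip::unzip(out, exdir = ex)
    mutate(ex)
    tam <- tempfile(fileext = ".cvsx")
    zip::zip(tam, sort(list.files(ex, recursive = TRUE)), root = ex,
             mode = "mirror")
    tam
  }
  # drop query.json
  t1 <- retamper(function(ex) unlink(file.path(ex, "query.json")))
  expect_error(read_cvsx(t1), "missing member query.json")
  # index lists a member absent from the archive
  t2 <- retamper(function(ex) {
    idx <- voxseg:::read_json_doc(file.path(ex, "index.json"))
    idx[[length(idx) + 1]] <- list(path = "volume/ghost/0/1.map",
                                   role = "volume", format = "mrc")
    voxseg:::write_canonical_json(idx, file.path(ex, "index.json"))
  })
  expect_error(read_cvsx(t2), "absent from archive: volume/ghost")
  # a member the index does not describe
  t3 <- retamper(function(ex) writeLines("x", file.path(ex, "stray.txt")))
  expect_error(read_cvsx(t3), "not described by index: stray.txt")
})
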