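test_that("a first write creates the root and source subdirectory", {
  wd <- local_workdir()
  db <- file.path(wd, "fresh", "db")
  expect_false(dir.exists(db))
  key <- build_mask_entry(db, wd, n_masks = 1)
  expect_true(dir.exists(file.path(db, "emdb")))
  expect_true(file.exists(file.path(db, "emdb", key$entry_id, "data.zip")))
  expect_true(file.exists(file.path(db, "emdb", key$entry_id,
                                    "annotations.json")))
  expect_true(file.exists(file.path(db, "emdb", key$entry_id,
                                    "metadata.json")))
})

test_that("written entries re-read equal to the in-memory entry", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_map_sff_entry(db, wd, dims = 32)
  e <- read_entry(db, key)
  # volume payload at factor 1 equals an independent re-read of the fixture
  src <- read_map(file.path(wd, "v.map"))
  expect_lt(max(abs(e$volumes[[1]]$frames[["0"]][["1"]]$values - src$values)),
            1e-6)
  # lattice labels are exact
  sff <- read_sff(file.path(wd, "emd_1832.hff"))
  expect_identical(e$lattices[[1]]$frames[["0"]][["1"]]$values,
                   sff$lattices[[1]]$frames[["0"]][["1"]]$values)
  # a second read gives the same result (lazy == eager)
  e2 <- read_entry(db, key)
  expect_identical(e$metadata, e2$metadata)
  expect_identical(e$lattices[[1]]$segment_ids, e2$lattices[[1]]$segment_ids)
})

test_that("the metadata inventory equals a direct scan of data.zip members", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  for (key in list(build_map_sff_entry(db, wd),
                   build_mask_entry(db, wd),
                   build_geometric_entry(db, wd))) {
    md <- read_entry_metadata(db, key)
    members <- list_entry_payloads(db, key)
    # channels x times x factors accounted for exactly
    expected <- character()
    for (ch in md$volumes$channel_ids) {
      for (tf in md$volumes$time_frame_indices) {
        for (fac in names(md$volumes$sampling_info)) {
          expected <- c(expected, sprintf("volume/%s/%s/%s.map",
                                          voxseg:::json_scalar(ch),
                                          voxseg:::json_scalar(tf), fac))
        }
      }
    }
    for (s in md$segmentations$lattice) {
      for (tf in s$time_frame_indices) {
        for (fac in names(s$sampling_info)) {
          expected <- c(expected, sprintf("lattice/%s/%s/%s.map",
                                          voxseg:::json_scalar(s$segmentation_id),
                                          voxseg:::json_scalar(tf), fac))
        }
      }
    }
    for (s in md$segmentations$geometric) {
      expected <- c(expected, sprintf("geometric/%s.json",
                                      voxseg:::json_scalar(s$segmentation_id)))
    }
    for (s in md$segmentations$mesh) {
      expected <- c(expected, sprintf("mesh/%s.json",
                                      voxseg:::json_scalar(s$segmentation_id)))
    }
    expect_setequal(members[!grepl("/$", members)], expected)
  }
})

test_that("writes with a mismatched inventory are refused", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- entry_key("custom", "bad")
  g <- volume_grid(array(0, c(4, 4, 4)))
  vol <- multiscale_volume("0", list(`0` = list(`1` = g)))
  md <- build_entry_metadata(key, volumes = list(vol))
  md$volumes$channel_ids <- list("0", "phantom")
  expect_error(write_entry(db, key, volumes = list(vol),
                           annotations = empty_annotations(key),
                           metadata = md),
               "channel inventory")
  expect_false(entry_exists(db, key))
})

test_that("metadata reads do not touch data.zip", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_mask_entry(db, wd, n_masks = 1)
  unlink(file.path(voxseg:::entry_dir(db, key), "data.zip"))
  md <- read_entry_metadata(db, key)  # still served from metadata.json alone
  expect_length(md$segmentations$lattice, 1)
  ann <- read_entry_annotations(db, key)
  expect_length(validate_annotations(ann), 0)
})

test_that("listing equals a directory scan, sorted, filtered, stable", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  build_mask_entry(db, wd, entry_id = "emd-9", n_masks = 1)
  build_mask_entry(db, wd, entry_id = "emd-1", n_masks = 1)
  wd2 <- local_workdir()
  k3 <- build_zarr_entry(db, wd2)
  listing <- list_entries(db)
  # directory-scan oracle
  oracle <- do.call(rbind, lapply(sort(list.files(db)), function(s) {
    data.frame(source_db = s, entry_id = sort(list.files(file.path(db, s))),
               stringsAsFactors = FALSE)
  }))
  expect_identical(listing$entry_id, oracle$entry_id)
  expect_identical(listing$source_db, oracle$source_db)
  expect_identical(list_entries(db), listing)  # stable under repetition
  only_emdb <- list_entries(db, "emdb")
  expect_identical(only_emdb$entry_id, c("emd-1", "emd-9"))
  expect_identical(list_entries(db, "idr")$entry_id, k3$entry_id)
  expect_warning(empty <- list_entries(file.path(wd, "nope")), "not exist")
  expect_identical(nrow(empty), 0L)
})
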