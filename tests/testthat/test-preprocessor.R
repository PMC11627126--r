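test_that("map + SFF inputs become a one-channel one-lattice entry", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_map_sff_entry(db, wd)
  md <- read_entry_metadata(db, key)
  expect_length(md$volumes$channel_ids, 1)
  expect_length(md$volumes$time_frame_indices, 1)
  expect_length(md$segmentations$lattice, 1)
  # SFF-provided name passes through, no placeholder
  ann <- read_entry_annotations(db, key)
  nms <- vapply(ann$descriptions, function(d) voxseg:::json_scalar(d$name),
                character(1))
  expect_true("CMG" %in% nms)
  expect_false(any(grepl("^Segment ", nms)))
})

test_that("five masks become five lattice segmentations with seeded names", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_mask_entry(db, wd)
  md <- read_entry_metadata(db, key)
  expect_length(md$segmentations$lattice, 5)
  ids <- vapply(md$segmentations$lattice, function(s)
    voxseg:::json_scalar(s$segmentation_id), character(1))
  expect_identical(sort(ids), sprintf("emd_1273_msk_%d", 1:5))
  ann <- read_entry_annotations(db, key)
  nms <- vapply(ann$descriptions, function(d) voxseg:::json_scalar(d$name),
                character(1))
  expect_true(all(nms == "Segment 1"))  # each mask holds a single segment
})

test_that("adding the same key twice fails and leaves the first entry intact", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_mask_entry(db, wd, n_masks = 1)
  before <- readLines(file.path(voxseg:::entry_dir(db, key), "metadata.json"))
  expect_error(build_mask_entry(db, wd, n_masks = 1), "already exists")
  after <- readLines(file.path(voxseg:::entry_dir(db, key), "metadata.json"))
  expect_identical(before, after)
})

test_that("extra-data voxel size overrides a broken header everywhere", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  key <- build_geometric_entry(db, wd)
  md <- read_entry_metadata(db, key)
  for (fac in names(md$volumes$sampling_info)) {
    expect_equal(num3(md$volumes$sampling_info[[fac]]$voxel_size),
                 c(7.84, 7.84, 7.84) * as.integer(fac))
  }
  expect_true(isTRUE(voxseg:::json_scalar(md$volumes$voxel_size_valid)))
})

test_that("custom segment id mappings rename seeded descriptions", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  mp <- file.path(wd, "TS_026.labels.map")
  make_mask_fixture(mp, dims = c(16, 16, 16), n_segments = 2, seed = 9)
  extra <- file.path(wd, "extra.json")
  voxseg:::write_canonical_json(
    list(segmentation = list(custom_segment_ids_mapping =
                               list(`TS_026.labels` = list(`1` = "cytoplasm",
                                                           `2` = "mitochondria")))),
    extra)
  key <- entry_key("empiar", "empiar-10988")
  preprocess_entry(list(input_spec(extra, "extra_data"),
                        input_spec(mp, "mask")), key, db_root = db)
  ann <- read_entry_annotations(db, key)
  nms <- vapply(ann$descriptions, function(d) voxseg:::json_scalar(d$name),
                character(1))
  expect_identical(unname(nms[["desc-TS_026.labels-2"]]), "mitochondria")
  expect_identical(unname(nms[["desc-TS_026.labels-1"]]), "cytoplasm")
})

test_that("an empty extra-data document leaves the entry byte-identical", {
  wd <- local_workdir()
  db1 <- file.path(wd, "db1"); db2 <- file.path(wd, "db2")
  mp <- file.path(wd, "m.map")
  make_mask_fixture(mp, n_segments = 2, seed = 10)
  extra <- file.path(wd, "empty.json")
  writeLines("{}", extra)
  key <- entry_key("custom", "e")
  preprocess_entry(list(input_spec(mp, "mask")), key, db_root = db1)
  preprocess_entry(list(input_spec(extra, "extra_data"),
                        input_spec(mp, "mask")), key, db_root = db2)
  for (f in c("metadata.json", "annotations.json")) {
    expect_identical(readLines(file.path(voxseg:::entry_dir(db1, key), f)),
                     readLines(file.path(voxseg:::entry_dir(db2, key), f)))
  }
})

test_that("extra_data inputs must come first and be unique", {
  ex <- input_spec("x.json", "extra_data")
  mp <- input_spec("m.map", "mask")
  expect_error(voxseg:::check_input_specs(list(mp, ex)), "first input file")
  expect_error(voxseg:::check_input_specs(list(ex, ex)), "at most one")
  expect_error(input_spec("x", "tomogram"), "unknown input kind")
})

test_that("preprocessing twice gives byte-identical metadata and annotations", {
  wd <- local_workdir()
  db1 <- file.path(wd, "a"); db2 <- file.path(wd, "b")
  k1 <- build_map_sff_entry(db1, wd, dims = 24)
  k2 <- build_map_sff_entry(db2, wd, dims = 24)
  for (f in c("metadata.json", "annotations.json")) {
    expect_identical(readLines(file.path(voxseg:::entry_dir(db1, k1), f)),
                     readLines(file.path(voxseg:::entry_dir(db2, k2), f)))
  }
})

test_that("a reader failure mid-run leaves the database without the entry", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  good <- file.path(wd, "good.map")
  make_volume_fixture(good, dims = c(8, 8, 8), seed = 1)
  bad <- file.path(wd, "bad.map")
  writeBin(raw(64), bad)  # truncated header
  key <- entry_key("custom", "atomic")
  expect_error(preprocess_entry(list(input_spec(good, "map"),
                                     input_spec(bad, "mask")),
                                key, db_root = db))
  expect_false(entry_exists(db, key))
  expect_length(list.files(file.path(db, "custom")), 0)
})

test_that("removing an entry leaves its siblings intact", {
  wd <- local_workdir()
  db <- file.path(wd, "db")
  k1 <- build_mask_entry(db, wd, entry_id = "emd-1", n_masks = 1)
  k2 <- build_mask_entry(db, wd, entry_id = "emd-2", n_masks = 1)
  remove_entry(db, k1)
  listing <- list_entries(db)
  expect_identical(listing$entry_id, "emd-2")
  expect_true(entry_exists(db, k2))
  expect_error(remove_entry(db, k1), "not found")
})
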