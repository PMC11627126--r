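test_that("seeded annotations documents validate cleanly", {
  wd <- local_workdir()
  mp <- file.path(wd, "m.map")
  make_mask_fixture(mp, n_segments = 2, seed = 7)
  seg <- read_mask(mp)
  ann <- seed_annotations(entry_key("custom", "x"), lattices = list(seg))
  expect_length(validate_annotations(ann), 0)
  # constructed by hand against the model
  expect_named(ann$descriptions,
               c("desc-m-1", "desc-m-2"))
  expect_equal(ann$descriptions[["desc-m-2"]]$name, "Segment 2")
})

test_that("markdown details objects are accepted, malformed ones rejected", {
  key <- entry_key("emdb", "e")
  ann <- empty_annotations(key)
  ann$descriptions[["d1"]] <- description_record(
    "d1", "lattice", segmentation_id = "s", segment_id = 1,
    name = "Microtubule (MT) network within the CTL",
    details = list(format = "markdown",
                   text = "# Biological context\nThe **MTs** radiate out..."))
  expect_length(validate_annotations(ann), 0)
  ann$descriptions[["d1"]]$details <- list(format = "markdown")  # no text
  viol <- validate_annotations(ann)
  expect_match(viol, "details", all = FALSE)
  ann$descriptions[["d1"]]$details <- list(format = "html", text = "x")
  expect_match(validate_annotations(ann), "format", all = FALSE)
})

test_that("an empty document reports the missing entry_id by path", {
  viol <- validate_annotations(list())
  expect_match(viol, "^/entry_id", all = FALSE)
})

test_that("segment annotation uniqueness and colour ranges are enforced", {
  key <- entry_key("emdb", "e")
  ann <- empty_annotations(key)
  sa <- segment_annotation_record("lattice", "s", 1, c(0.1, 0.2, 0.3, 1))
  ann$segment_annotations <- list(sa, sa)
  expect_match(validate_annotations(ann), "duplicate", all = FALSE)
  ann$segment_annotations <- list(
    segment_annotation_record("lattice", "s", 1, c(2, 0, 0, 1)))
  expect_match(validate_annotations(ann), "\\[0, 1\\]", all = FALSE)
})

test_that("extra-data validation accepts the documented forms", {
  expect_length(validate_extra_data(
    list(volume = list(voxel_size = c(7.84, 7.84, 7.84)))), 0)
  expect_length(validate_extra_data(list()), 0)  # all fields optional
  expect_length(validate_extra_data(
    list(segmentation = list(custom_segment_ids_mapping =
                               list(`TS_026.labels` = list(`2` = "mitochondria"))))), 0)
  expect_match(validate_extra_data(list(volume = list(voxel_size = list(7.84)))),
               "3 numeric components", all = FALSE)
  expect_match(validate_extra_data(list(volume = list(voxel_size = c(0, 1, 1)))),
               "> 0", all = FALSE)
})

test_that("query default resolution fills max_points and is idempotent", {
  q1 <- apply_query_defaults(list(entry_id = "emd-1832", source_db = "emdb"))
  expect_identical(q1$max_points, 1e12)
  expect_null(q1$channel_id)
  q2 <- apply_query_defaults(q1)
  expect_identical(unclass(q1), unclass(q2))
  expect_error(apply_query_defaults(list(source_db = "emdb")), "entry_id")
  expect_error(apply_query_defaults(
    list(entry_id = "x", source_db = "emdb", segmentation_kind = "spline")),
    "segmentation_kind")
})

test_that("palette colours are deterministic and cycle over ten entries", {
  expect_identical(palette_color(1), palette_color(11))
  expect_identical(palette_color(3), palette_color(3))
  cols <- vapply(1:10, function(i) paste(palette_color(i), collapse = ","),
                 character(1))
  expect_length(unique(cols), 10)
  expect_equal(hex_to_rgba("FFFF00"), c(1, 1, 0, 1))
  expect_equal(hex_to_rgba("#FF0000"), c(1, 0, 0, 1))
  expect_error(hex_to_rgba("GG0000"), "hex")
})
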