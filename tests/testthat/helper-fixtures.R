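# Shared fixture builders. Every helper is deterministic for a given seed
# and stages everything under tempdir().

local_workdir <- function(env = parent.frame()) {
  wd <- tempfile("voxseg-test-")
  dir.create(wd)
  withr::defer(unlink(wd, recursive = TRUE), envir = env)
  wd
}

# Single-channel map + SFF entry (one lattice segment named "CMG"), the
# small single-frame single-channel worked example.
build_map_sff_entry <- function(db, wd, entry_id = "emd-1832", dims = 48,
                                seed = 1) {
  vmap <- file.path(wd, "v.map")
  make_volume_fixture(vmap, dims = rep(dims, 3), voxel_size = c(5.4, 5.4, 5.4),
                      seed = seed)
  hff <- file.path(wd, "emd_1832.hff")
  make_sff_fixture(hff, dims = rep(dims, 3), segment_names = "CMG",
                   seed = seed)
  key <- entry_key("emdb", entry_id)
  preprocess_entry(list(input_spec(vmap, "map"), input_spec(hff, "sff")),
                   key, db_root = db)
  key
}

# Map + five single-segment masks, the five-lattice-segmentation scenario.
build_mask_entry <- function(db, wd, entry_id = "emd-1273", n_masks = 5,
                             dims = 24, seed = 2) {
  vmap <- file.path(wd, "emd_1273.map")
  make_volume_fixture(vmap, dims = rep(dims, 3), seed = seed)
  inputs <- list(input_spec(vmap, "map"))
  for (i in seq_len(n_masks)) {
    mp <- file.path(wd, sprintf("emd_1273_msk_%d.map", i))
    make_mask_fixture(mp, dims = rep(dims, 3), n_segments = 1,
                      seed = seed + i)
    inputs[[length(inputs) + 1L]] <- input_spec(mp, "mask")
  }
  key <- entry_key("emdb", entry_id)
  preprocess_entry(inputs, key, db_root = db)
  key
}

# Multi-channel multi-time OME-Zarr entry with a labels subgroup.
build_zarr_entry <- function(db, wd, entry_id = "idr-13457537", seed = 3) {
  zarr <- file.path(wd, "13457537.zarr")
  make_multiscale_fixture(zarr, shape = c(3, 2, 8, 48, 48), axes = "tczyx",
                          channel_labels = c("DAPI", "Hyb probe"),
                          scale_xyz = c(0.5, 0.5, 0.5), unit = "micrometer",
                          flavor = "omezarr", n_labels = 1, seed = seed)
  key <- entry_key("idr", entry_id)
  preprocess_entry(list(input_spec(zarr, "omezarr")), key, db_root = db)
  key
}

# Broken-header map + STAR-derived geometric segmentations + extra-data
# voxel-size override (the bin-4 tomogram scenario).
build_geometric_entry <- function(db, wd, entry_id = "empiar-11756",
                                  seed = 4) {
  vmap <- file.path(wd, "tomo.map")
  make_volume_fixture(vmap, dims = c(48, 48, 48), cella_zero = TRUE,
                      seed = seed)
  star <- file.path(wd, "rln_ribosome.star")
  make_star_fixture(star, n_rows = 10, seed = seed)
  geo1 <- file.path(wd, "geometric_segmentation_input_1.json")
  cfg <- star_parse_config(sphere_radius = 100.0, segmentation_id = "ribosomes",
                           sphere_color_hex = "FFFF00", pixel_size = 7.84,
                           star_file_coordinate_divisor = 4)
  parse_star_to_geometric(star, cfg, geo1)
  extra <- file.path(wd, "extra.json")
  voxseg:::write_canonical_json(
    list(volume = list(voxel_size = c(7.84, 7.84, 7.84))), extra)
  key <- entry_key("empiar", entry_id)
  preprocess_entry(list(input_spec(extra, "extra_data"),
                        input_spec(vmap, "map"),
                        input_spec(geo1, "geometric_segmentation")),
                   key, db_root = db)
  key
}

num3 <- function(x) voxseg:::json_num_vec(x)
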