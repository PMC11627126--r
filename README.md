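# voxseg

Server-side management of annotated volumetric imaging entries: convert
heterogeneous microscopy and cryo-EM inputs into a multiscale internal
database, query subsets of an entry into shareable CVSX (ZIP) archives,
edit segment annotations, and serve entries over a small HTTP API.

## Who it is for

Groups that host volumetric and segmentation data for interactive viewers:
cryo-EM/cryo-ET facilities with density maps and masks (MRC/CCP4), EMDB-SFF
segmentations (HDF5), light-microscopy time series in OME-Zarr or OME-TIFF,
and particle picks in RELION-style STAR tables. All of these become one
uniform on-disk representation that a viewer or downstream script can query.

## The core model

An **entry** (identified by source database and id, e.g. `emdb/emd-1273`)
holds:

* per-channel, per-time **downsampling pyramids** of scalar grids with voxel
  geometry in Å. Level factors are 1, 2, 4, …; level *f* has dims
  ⌈dims/f⌉. Scalar grids are reduced by 2×2×2 block means (which conserves
  the global mean exactly for even dims); label grids by block majority
  with ties to the smallest label;
* **segmentations** in three kinds: *lattice* (integer label grids),
  *geometric* (sphere primitives with centre/radius/colour), *mesh*
  (triangle meshes);
* schema-validated **annotations** (names, RGBA colours, plain or markdown
  descriptions, external references) and a **metadata** inventory that
  exactly reflects the stored payloads.

A **query** `{entry_id, source_db, [channel_id], [time],
[segmentation_kind], [segmentation_id], [max_points]}` expands absent
fields to the full inventory (`max_points` defaults to 1000000000000) and
selects the finest pyramid level whose voxel count per frame is at most
`max_points`. The selection is packed into a `.cvsx` ZIP archive holding
`index.json`, `query.json`, `annotations.json`, `metadata.json` and the
selected payloads. STAR particle tables convert to spheres with centre
`(coordinate / divisor) × pixel_size` Å; extra-data JSON can override a
broken map header's voxel size (e.g. 1.96 Å bin-1 pixels × 4 = 7.84 Å on a
bin-4 tomogram) and rename auto-seeded segments.

## Worked example

Five single-segment masks over one density map become an entry with five
lattice segmentations; a minimal query packs everything into an archive;
one seeded description is renamed and committed.

```r
library(voxseg)
wd <- tempfile("demo-"); dir.create(wd)
db <- file.path(wd, "db")

# 1. generate inputs: a density map and five single-segment masks
make_volume_fixture(file.path(wd, "emd_1273.map"), dims = c(24, 24, 24), seed = 1)
for (i in 1:5)
  make_mask_fixture(file.path(wd, sprintf("emd_1273_msk_%d.map", i)),
                    dims = c(24, 24, 24), n_segments = 1, seed = i)

# 2. preprocess into a database entry
inputs <- c(list(input_spec(file.path(wd, "emd_1273.map"), "map")),
            lapply(1:5, function(i)
              input_spec(file.path(wd, sprintf("emd_1273_msk_%d.map", i)), "mask")))
key <- entry_key("emdb", "emd-1273")
preprocess_entry(inputs, key, db_root = db)
md <- read_entry_metadata(db, key)
cat("channels:       ", length(md$volumes$channel_ids), "\n")
cat("lattice segs:   ", length(md$segmentations$lattice), "\n")

# 3. query everything into a CVSX archive
out <- file.path(wd, "emd-1273.cvsx")
build_cvsx(db, list(entry_id = "emd-1273", source_db = "emdb"), out)
r <- read_cvsx(out)
cat("archive members:", length(zip::zip_list(out)$filename), "\n")
cat("max_points used:", format(r$query$max_points[[1]], scientific = FALSE), "\n")

# 4. rename a seeded segment description and commit
ann <- read_entry_annotations(db, key)
search_annotations(ann, "emd_1273_msk_1")
ann <- edit_at_pointer(ann, "/descriptions/desc-emd_1273_msk_1-1/name",
                       "Microtubule (MT) network within the CTL")
commit_annotations(db, key, ann)
```

Output:

```
channels:        1
lattice segs:    5
archive members: 10
max_points used: 1000000000000
[1] "/descriptions/desc-emd_1273_msk_1-1"
[2] "/descriptions/desc-emd_1273_msk_1-1/id"
[3] "/descriptions/desc-emd_1273_msk_1-1/target/segmentation_id"
[4] "/segment_annotations/0/id"
[5] "/segment_annotations/0/segmentation_id"
```

The five masks each contain a single segment, so the entry metadata lists
five lattice segmentations whose seeded descriptions all start as
`Segment 1`; the archive's ten members are five lattice payloads, one
volume payload and the four JSON documents; the search finds the
segmentation id in both a description and a segment annotation, and the
edit replaces the placeholder name.

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/cli/voxseg`): `preprocess --mode add --input-path … --input-kind …
--entry-id … --db-path …`, `vs-toolkit --db_path … --out x.cvsx
--json-params-path q.json`, `parse-star`, `annotations`, `serve`, and
`fixtures`.

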