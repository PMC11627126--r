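---
title: "Managing multiscale volumetric and segmentation entries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing multiscale volumetric and segmentation entries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxseg)
```

## The problem this package addresses

Volumetric imaging repositories (EMDB, EMPIAR, IDR) and custom microscopy
pipelines produce data in many shapes: electron-density maps and masks
(MRC/CCP4), EMDB-SFF segmentation files (HDF5), OME-Zarr and OME-TIFF
multiscale images, and RELION-style STAR particle tables. Interactive
visualisation of such data needs a uniform server-side representation:
per-channel, per-time downsampling pyramids; segmentations in three kinds
(lattice label grids, sphere primitives, triangle meshes); and editable
annotations that attach names, colours, markdown descriptions and external
references to segments.

`voxseg` implements that server-side stack: a **preprocessor** that converts
any supported input into an internal database entry, a **query toolkit**
that packs a user-selected subset of an entry into a shareable CVSX (ZIP)
archive, an **annotation editor** backend, and a minimal read-only **HTTP
API** over the database.

## Conventions the whole package shares

* **Spatial unit.** Everything is Angstrom internally. Readers convert on
  ingestion (OME-NGFF micrometre scales are multiplied by 1e4, nanometres
  by 10). A single unit avoids silent mismatches between EMDB maps
  (Angstrom-native) and light-microscopy images.
* **Axis order.** In-memory grids are `values[x, y, z]` with x fastest —
  R's column-major layout makes the first index the fastest, so this is the
  natural choice. Every reader permutes into it: the MRC reader honours
  MAPC/MAPR/MAPS, the zarr reader reverses the C-order axis list, the TIFF
  reader transposes row-major planes.
* **Time and channels.** Time indices are 0-based consecutive integers;
  channel ids are always strings (a numeric channel index becomes `"0"`).
* **Deterministic ids.** Seeded descriptions and segment annotations use
  `desc-<segmentation>-<segment>` / `sa-<segmentation>-<segment>` rather
  than random UUIDs, so re-preprocessing an entry reproduces
  `annotations.json` byte for byte; tests rely on that.

## The downsampling pyramid

Sources only fix *that* entries carry a bounded multiscale pyramid, not the
kernel, so the package uses the simplest order-independent choices:

* **Scalar grids** — the arithmetic mean of each up-to-2×2×2 block. Edge
  blocks on odd axes average the voxels they actually contain, giving
  level-f dims of `ceiling(dims / f)`. For even-dimensioned grids this
  conserves the global mean exactly at every level, which the tests assert
  to 1e-12.
* **Label grids** — the most frequent label per block, ties broken toward
  the smallest label, with background 0 participating like any label. The
  tie rule makes the result independent of traversal order; the label set
  can only shrink at coarser levels (also asserted as a property).

Levels are factors 1, 2, 4, … up to `max_level_factor` (default 2^6),
stopping early once every axis is at most `stop_dim` voxels (default 32).
The defaults keep desk-scale entries to two or three levels; factor 1 is
always retained. OME-Zarr inputs are re-sampled from their
highest-resolution level only — source pyramids are not trusted, so one
downsampling rule governs every entry.

## Queries, level selection and CVSX archives

A query names an entry (`entry_id`, `source_db` — mandatory) and optionally
restricts `channel_id`, `time`, `segmentation_kind` (`lattice`, `mesh`,
`geometric-segmentation`) and `segmentation_id`. Absent fields expand to
the entry's full inventory; a given `time` restricts both volumes and
segmentations to that frame. `max_points` defaults to 1000000000000 — far
beyond any desk-scale grid, so by default the finest level ships.

Level selection picks the smallest factor whose per-frame voxel count does
not exceed `max_points`, falling back to the coarsest level when none
qualifies. It applies independently to volume and lattice grids; geometric
and mesh payloads are never downsampled.

The archive holds `index.json` (an inventory describing every other
member), `query.json` (the post-resolution selection plus the raw request
under `requested`, making archives self-documenting), filtered
`annotations.json` and `metadata.json`, and exactly the selected payloads.
The `.cvsx` extension is mandatory. Payload encoding mirrors the database
store — standard MRC grids and JSON sphere/mesh documents — because the
archive roles, not the payload dialect, are what the format fixes; standard
formats keep every member independently inspectable. Byte-level
compatibility with other CVSX-producing tools' internal chunk encodings is
a non-goal.

## Annotations and their validation

An annotations document carries entry identity, an optional entry name,
`descriptions` keyed by id (target kind `lattice` / `mesh` / `primitive` /
`entry`, an optional name, details as plain text or a
`{format: "text"|"markdown", text}` object, external references,
`is_hidden`, optional time) and `segment_annotations` (segment kind,
target, RGBA colour in [0, 1], optional time, unique per target/time). The
validator is structural and returns one violation per broken rule, each
naming the offending JSON-pointer path. Field names follow the narrative
model; exact parity with any external schema file is not claimed.

Masks carry no biology, so ingestion seeds generic names — `Segment 1`,
`Segment 2`, … — with a deterministic 10-colour palette indexed by
`(segment_id - 1) mod 10`. SFF-provided names and colours pass through
untouched. An extra-data document (always the *first* input when present)
can override the voxel size of a broken map header (e.g. 1.96 Å bin-1
pixels on a bin-4 tomogram give 7.84 Å) and rename seeded segments via
`custom_segment_ids_mapping`; unknown mapping targets warn rather than
fail.

Editing is GUI-free here: RFC-6901 pointers address any node;
`edit_at_pointer`, `retype_at_pointer` (a node becomes the empty value of
its new kind) and `append_field` are pure functions, and
`commit_annotations` validates then atomically replaces the stored file
(write-temp-then-rename). Because intermediate states of a retype/append
session need not validate (details as an empty object, for instance), the
CLI stages such edits in a working file and only `commit` touches the
store. Search splits the query on whitespace and matches every keyword
case-insensitively as a substring of a key or string leaf — numbers and
booleans are not searched, the least surprising reading of keyword search
over a JSON document.

## The database and the server

The database is a plain directory: one subdirectory per source database,
one per entry, each holding `data.zip`, `annotations.json` and
`metadata.json`. Payload paths inside the zip are
`volume/<channel>/<time>/<factor>.map`, `lattice/<id>/<time>/<factor>.map`,
`mesh/<id>.json`, `geometric/<id>.json`; members are written in sorted
order at deflate level 6. Entries are staged and renamed into place, so a
failing reader never leaves a partial entry; duplicate keys are refused.
The metadata inventory is checked against the payloads at write time, and
tests verify it equals a direct scan of the zip members.

The server defaults to `0.0.0.0:9000` over
`preprocessor/temp/test_db`, serves everything under `/v1`, and documents
itself at `/docs`. Routing is a pure function of the store
(`handle_api_request`), which is how most server tests run — sockets are
only exercised by one background-process test. Grid payloads are served as
MRC bodies at the level chosen by the same `max_points` rule the toolkit
uses. The route inventory beyond the `/v1` prefix and the defaults is this
package's own design; parity with other implementations is not claimed.

## What the synthetic fixtures emulate — and what they do not

All tests run offline on generated data. The generators reproduce the
*structural* conditions of the worked examples at desk scale:

* a single-channel map plus an SFF file holding one named, coloured
  segment (the small single-frame protein-complex entry);
* five single-segment masks over one map (the five-lattice organelle
  entry, whose seeded descriptions are each `Segment 1`);
* a 2-channel ("DAPI", "Hyb probe") × 3-frame OME-Zarr group with 0.5 µm
  scales and a labels subgroup (the multi-channel cell-imaging entry);
* an OME-TIFF series in `C{n}_TP{m}` files with embedded OME-XML (the
  time-series embryo entry);
* a CELLA-0 tomogram with STAR particle tables parsed at
  `sphere_radius 100.0`, colour `FFFF00`, `pixel_size 7.84`, divisor 4
  (the cryo-ET ribosome entry).

Grid sizes are 16–48 voxels per axis so the full suite runs in seconds;
the quantities checked (voxel-size propagation, default resolution, counts,
radii, port binding) do not depend on grid size. What passing tests do
*not* show: behaviour on cluster-scale tomograms (no out-of-core path),
real-world header pathologies beyond CELLA = 0, SFF files from arbitrary
producers (the reader consumes the narrative EMDB-SFF structure the fixture
writer emits), or rendering fidelity in any viewer.

## Numerical and degenerate-input choices

* Map modes 0/1/2/6, little-endian; mask values must be within 1e-6 of a
  non-negative integer.
* A voxel size of 0 is data, not an error — it is preserved and flagged
  invalid so extra data can repair it.
* All-zero masks, zero-segment SFF files and zero-row STAR tables produce
  empty results with warnings, not failures.
* 2D NGFF images get a z extent of 1; absent unit metadata is treated as
  Angstrom with a warning (fail-soft, visible).
* Downsampling limits are expressed as level *factors* (1, 2, 4, …), not
  level indices.
* Query `time` is a single integer, matching its declared type; ranges are
  not accepted.
* The STAR parser treats the user-supplied `pixel_size` as authoritative
  even when the target map carries its own voxel size — the override
  exists precisely because headers lie.

## Known limitations

Single-process ownership of the database (no concurrent writers); no
Amira/Segger/IMOD readers; no authentication or writes over HTTP; no
streaming archive reads; meshes are stored and served but never simplified
or downsampled.
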