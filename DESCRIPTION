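Package: voxseg
Title: Multiscale Volumetric and Segmentation Entry Store with Shareable
    CVSX Archives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Server-side toolkit for managing annotated volumetric imaging
    entries. A preprocessor converts heterogeneous inputs (MRC/CCP4 maps,
    integer label masks, EMDB-SFF segmentations, OME-Zarr and OME-TIFF
    images, RELION-style STAR particle tables, geometric-segmentation JSON)
    into an on-disk database of multiscale downsampling pyramids with
    schema-validated annotations and metadata. A query toolkit resolves
    user queries against entry inventories, selects downsampling levels by
    a point budget, and packs the selection into shareable CVSX (ZIP)
    archives. Includes structured annotation editing (search, JSON-pointer
    edits, atomic commit), a read-only HTTP entry-serving API, a unified
    command-line interface, and deterministic synthetic fixture generators
    for every supported input kind.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    zip,
    rhdf5,
    tiff,
    xml2,
    httpuv,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    callr,
    curl
Config/testthat/edition: 3
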