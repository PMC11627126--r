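# The preprocessor: converts parsed inputs into a complete database entry.
#
# Pipeline: parse inputs in order (extra_data, when present, must come
# first) -> build downsampling pyramids -> seed annotations -> apply
# extra-data overrides -> write the entry. All staging happens in a working
# folder; a failure anywhere leaves the database untouched.

.input_kinds <- c("map", "sff", "omezarr", "ometiff_image", "mask",
                  "geometric_segmentation", "extra_data")

#' Declare one preprocessor input
#'
#' @param path Path to the input file or directory.
#' @param kind One of `"map"`, `"sff"`, `"omezarr"`, `"ometiff_image"`,
#'   `"mask"`, `"geometric_segmentation"`, `"extra_data"`.
#' @return Object of class `input_spec`.
#' @export
input_spec <- function(path, kind) {
  if (!kind %in% .input_kinds) {
    stop("unknown input kind: ", kind, " (expected one of ",
         paste(.input_kinds, collapse = ", "), ")", call. = FALSE)
  }
  structure(list(path = path, kind = kind), class = "input_spec")
}

check_input_specs <- function(inputs) {
  if (length(inputs) == 0L) stop("no inputs given", call. = FALSE)
  kinds <- vapply(inputs, function(i) i$kind, character(1))
  n_extra <- sum(kinds == "extra_data")
  if (n_extra > 1L) stop("at most one extra_data input is allowed", call. = FALSE)
  if (n_extra == 1L && kinds[1L] != "extra_data") {
    stop("the extra_data input must be provided as the first input file",
         call. = FALSE)
  }
  invisible(kinds)
}

# Rebuild a pyramid for every frame of a multiscale volume / lattice
# segmentation from its factor-1 level.
pyramidise_volume <- function(vol, policy) {
  frames <- lapply(vol$frames, function(pyr) build_pyramid(pyr[["1"]], policy))
  multiscale_volume(vol$channel_id, frames)
}

pyramidise_lattice <- function(seg, policy) {
  frames <- lapply(seg$frames, function(pyr) build_pyramid(pyr[["1"]], policy))
  lattice_segmentation(seg$segmentation_id, frames)
}

#' Seed annotations for an entry in progress
#'
#' Every lattice segment lacking a source annotation receives a generic
#' description named `"Segment <label>"` and a segment annotation with a
#' deterministic palette colour; names and colours provided by the source
#' (e.g. an SFF file) pass through untouched. Each geometric segmentation
#' receives one description targeting the segmentation as a whole.
#'
#' @param key An [entry_key()].
#' @param lattices,geoms,meshes Parsed segmentations.
#' @param fragments List of annotation fragments from source files (each
#'   with `descriptions` and `segment_annotations`).
#' @return A validated annotations document.
#' @export
seed_annotations <- function(key, lattices = list(), geoms = list(),
                             meshes = list(), fragments = list()) {
  ann <- empty_annotations(key)
  for (fr in fragments) {
    for (id in names(fr$descriptions)) ann$descriptions[[id]] <- fr$descriptions[[id]]
    ann$segment_annotations <- c(ann$segment_annotations, fr$segment_annotations)
  }
  annotated <- vapply(ann$segment_annotations, function(sa) {
    paste(sa$segmentation_id, sa$segment_id)
  }, character(1))
  for (s in lattices) {
    for (lab in s$segment_ids) {
      if (paste(s$segmentation_id, lab) %in% annotated) next
      did <- paste0("desc-", s$segmentation_id, "-", lab)
      ann$descriptions[[did]] <- description_record(
        id = did, target_kind = "lattice",
        segmentation_id = s$segmentation_id, segment_id = lab,
        name = paste("Segment", lab))
      ann$segment_annotations[[length(ann$segment_annotations) + 1L]] <-
        segment_annotation_record("lattice", s$segmentation_id, lab,
                                  color = palette_color(lab))
    }
  }
  for (g in geoms) {
    did <- paste0("desc-", g$segmentation_id)
    if (is.null(ann$descriptions[[did]])) {
      ann$descriptions[[did]] <- description_record(
        id = did, target_kind = "primitive",
        segmentation_id = g$segmentation_id,
        name = g$segmentation_id)
    }
  }
  stopifnot(length(validate_annotations(ann)) == 0L)
  ann
}

#' Apply an extra-data document to an entry in progress
#'
#' A `volume$voxel_size` override replaces the header-derived voxel size on
#' every grid (scaled by the level factor on coarser levels).
#' `segmentation$custom_segment_ids_mapping` renames the seeded description
#' for each (segmentation_id, label) pair; unknown targets warn and are
#' skipped.
#'
#' @param entry List with `volumes`, `lattices`, `geoms`, `meshes`,
#'   `annotations` (an entry in progress).
#' @param extra Parsed extra-data document (must validate).
#' @return The modified entry.
#' @export
apply_extra_data <- function(entry, extra) {
  viol <- validate_extra_data(extra)
  if (length(viol) > 0L) {
    stop("extra-data document invalid:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  vs <- extra$volume$voxel_size
  if (!is.null(vs)) {
    vs <- json_num_vec(vs)
    override <- function(pyr) {
      for (fac in names(pyr)) {
        f <- as.integer(fac)
        pyr[[fac]]$voxel_size <- vs * f
        pyr[[fac]]$voxel_size_valid <- TRUE
      }
      pyr
    }
    entry$volumes <- lapply(entry$volumes, function(v) {
      v$frames <- lapply(v$frames, override)
      v
    })
    entry$lattices <- lapply(entry$lattices, function(s) {
      s$frames <- lapply(s$frames, override)
      s
    })
  }
  mapping <- extra$segmentation$custom_segment_ids_mapping
  if (!is.null(mapping)) {
    known_segs <- vapply(entry$lattices, function(s) s$segmentation_id,
                         character(1))
    for (sid in names(mapping)) {
      if (!sid %in% known_segs) {
        warning("custom_segment_ids_mapping references unknown segmentation ",
                sid, call. = FALSE)
        next
      }
      for (lab in names(mapping[[sid]])) {
        did <- paste0("desc-", sid, "-", lab)
        if (is.null(entry$annotations$descriptions[[did]])) {
          warning("custom_segment_ids_mapping references unknown segment ",
                  lab, " of ", sid, call. = FALSE)
          next
        }
        entry$annotations$descriptions[[did]]$name <-
          json_scalar(mapping[[sid]][[lab]])
      }
    }
  }
  entry
}

#' Preprocess inputs into a database entry
#'
#' Parses every input, builds downsampling pyramids, seeds annotations,
#' applies extra-data overrides, and writes the finished entry to the
#' database. A duplicate (source_db, entry_id) is refused; any failure
#' leaves the database without the new entry.
#'
#' @param inputs List of [input_spec()] (ordered; `extra_data` first when
#'   present).
#' @param key An [entry_key()].
#' @param db_root Database root directory (created on first use).
#' @param working_folder Staging directory for intermediate files.
#' @param policy A [pyramid_policy()].
#' @return The entry directory path, invisibly.
#' @export
preprocess_entry <- function(inputs, key, db_root,
                             working_folder = tempfile("voxseg-work-"),
                             policy = pyramid_policy()) {
  kinds <- check_input_specs(inputs)
  if (entry_exists(db_root, key)) {
    stop("entry ", format(key), " already exists in ", db_root,
         "; remove it first or use a different entry id", call. = FALSE)
  }
  dir.create(working_folder, recursive = TRUE, showWarnings = FALSE)

  volumes <- list(); lattices <- list(); geoms <- list(); meshes <- list()
  fragments <- list(); extra <- NULL
  map_count <- 0L
  for (inp in inputs) {
    switch(inp$kind,
      extra_data = {
        extra <- read_json_doc(inp$path)
        viol <- validate_extra_data(extra)
        if (length(viol) > 0L) {
          stop("extra-data document invalid:\n  ",
               paste(viol, collapse = "\n  "), call. = FALSE)
        }
      },
      map = {
        g <- read_map(inp$path)
        vol <- multiscale_volume(as.character(map_count),
                                 frames = list(`0` = list(`1` = g)))
        map_count <- map_count + 1L
        volumes[[length(volumes) + 1L]] <- vol
      },
      mask = {
        lattices[[length(lattices) + 1L]] <- read_mask(inp$path)
      },
      sff = {
        sf <- read_sff(inp$path)
        lattices <- c(lattices, sf$lattices)
        meshes <- c(meshes, sf$meshes)
        fragments[[length(fragments) + 1L]] <- sf$annotations
      },
      omezarr = {
        oz <- read_omezarr(inp$path)
        volumes <- c(volumes, oz$volumes)
        lattices <- c(lattices, oz$lattices)
      },
      ometiff_image = {
        volumes <- c(volumes, read_ometiff_series(inp$path))
      },
      geometric_segmentation = {
        geoms[[length(geoms) + 1L]] <- read_geometric_segmentation(inp$path)
      })
  }

  volumes <- lapply(volumes, pyramidise_volume, policy = policy)
  lattices <- lapply(lattices, pyramidise_lattice, policy = policy)

  entry <- list(volumes = volumes, lattices = lattices, geoms = geoms,
                meshes = meshes,
                annotations = seed_annotations(key, lattices, geoms, meshes,
                                               fragments))
  if (!is.null(extra)) entry <- apply_extra_data(entry, extra)

  metadata <- build_entry_metadata(key, entry$volumes, entry$lattices,
                                   entry$geoms, entry$meshes)
  write_entry(db_root, key, volumes = entry$volumes,
              lattices = entry$lattices, geoms = entry$geoms,
              meshes = entry$meshes, annotations = entry$annotations,
              metadata = metadata)
}
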