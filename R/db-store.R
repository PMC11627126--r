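# The on-disk internal database.
#
# Layout: <root>/<source_db>/<entry_id>/{data.zip, annotations.json,
# metadata.json}. Inside data.zip, payloads live at
#   volume/<channel_id>/<time>/<factor>.map
#   lattice/<segmentation_id>/<time>/<factor>.map
#   mesh/<segmentation_id>.json
#   geometric/<segmentation_id>.json
# Grid payloads are standard MRC maps so every member stays independently
# inspectable. Zip members are written in sorted path order at deflate
# level 6. Entries are staged in a sibling directory and renamed into place
# so a failed write never leaves a partial entry behind.

entry_dir <- function(db_root, key) {
  file.path(db_root, key$source_db, key$entry_id)
}

#' Does an entry exist in the database?
#' @param db_root Database root directory.
#' @param key An [entry_key()].
#' @return Logical.
#' @export
entry_exists <- function(db_root, key) {
  dir.exists(entry_dir(db_root, key)) &&
    file.exists(file.path(entry_dir(db_root, key), "metadata.json"))
}

#' Build the metadata document for an entry
#'
#' The metadata inventory (channels, time frames, sampling levels, grid
#' geometry, per-channel per-level value stats, segmentation inventory)
#' exactly reflects the payloads handed in.
#'
#' @param key An [entry_key()].
#' @param volumes List of [multiscale_volume()].
#' @param lattices List of [lattice_segmentation()] (with pyramids built).
#' @param geoms List of [geometric_segmentation()].
#' @param meshes List of [mesh_segmentation()].
#' @return Metadata document (plain list).
#' @export
build_entry_metadata <- function(key, volumes = list(), lattices = list(),
                                 geoms = list(), meshes = list()) {
  md <- list(entry_id = list(source_db = key$source_db,
                             entry_id = key$entry_id))
  if (length(volumes) > 0L) {
    ch_ids <- vapply(volumes, function(v) v$channel_id, character(1))
    times <- names(volumes[[1L]]$frames)
    pyr0 <- volumes[[1L]]$frames[[1L]]
    sampling <- lapply(pyr0, function(g) {
      list(dims = as.integer(g$dims), voxel_size = g$voxel_size)
    })
    stats <- lapply(volumes, function(v) {
      s <- lapply(v$frames[[1L]], function(g) g$stats)
      names(s) <- names(v$frames[[1L]])
      s
    })
    names(stats) <- ch_ids
    md$volumes <- list(channel_ids = as.list(ch_ids),
                       time_frame_indices = as.list(as.integer(times)),
                       origin = pyr0[[1L]]$origin,
                       voxel_size_valid = pyr0[[1L]]$voxel_size_valid,
                       sampling_info = sampling,
                       value_stats = stats)
  }
  seg_inv <- list()
  seg_inv$lattice <- lapply(lattices, function(s) {
    pyr0 <- s$frames[[1L]]
    list(segmentation_id = s$segmentation_id,
         time_frame_indices = as.list(as.integer(names(s$frames))),
         segment_ids = as.list(as.integer(s$segment_ids)),
         sampling_info = lapply(pyr0, function(g) {
           list(dims = as.integer(g$dims), voxel_size = g$voxel_size)
         }))
  })
  seg_inv$geometric <- lapply(geoms, function(s) {
    list(segmentation_id = s$segmentation_id,
         time_frame_indices = as.list(as.integer(names(s$frames))))
  })
  seg_inv$mesh <- lapply(meshes, function(s) {
    list(segmentation_id = s$segmentation_id,
         segment_ids = as.list(as.integer(names(s$segments))))
  })
  md$segmentations <- seg_inv
  md
}

mesh_to_doc <- function(mesh) {
  list(segmentation_id = mesh$segmentation_id,
       segments = lapply(mesh$segments, function(s) {
         list(vertices = unname(apply(s$vertices, 1L, as.list, simplify = FALSE)),
              triangles = unname(apply(s$triangles - 1L, 1L, as.list,
                                       simplify = FALSE)))
       }))
}

doc_to_mesh <- function(doc) {
  segs <- lapply(doc$segments, function(s) {
    nv <- length(s$vertices)
    verts <- if (nv) do.call(rbind, lapply(s$vertices, json_num_vec)) else
      matrix(numeric(), ncol = 3L)
    nt <- length(s$triangles)
    tris <- if (nt) do.call(rbind, lapply(s$triangles, function(x)
      as.integer(json_num_vec(x)))) + 1L else matrix(integer(), ncol = 3L)
    list(vertices = verts, triangles = tris)
  })
  names(segs) <- names(doc$segments)
  mesh_segmentation(json_scalar(doc$segmentation_id), segs)
}

geom_to_doc <- function(geom) {
  list(segmentation_id = geom$segmentation_id,
       time_frames = lapply(geom$frames, function(spheres) {
         lapply(spheres, function(s) {
           list(id = s$id, center = s$center, radius = s$radius,
                color = s$color)
         })
       }))
}

# consistency gate: metadata inventory must match the payloads
check_metadata_consistency <- function(metadata, volumes, lattices, geoms,
                                       meshes) {
  err <- function(...) stop("metadata inconsistent with payloads: ", ...,
                            call. = FALSE)
  ch_md <- vapply(metadata$volumes$channel_ids %||% list(), json_scalar,
                  character(1))
  ch_pl <- vapply(volumes, function(v) v$channel_id, character(1))
  if (!identical(sort(ch_md), sort(ch_pl))) {
    err("channel inventory (", paste(ch_md, collapse = ","),
        ") != payload channels (", paste(ch_pl, collapse = ","), ")")
  }
  ids <- function(entries) sort(vapply(entries, function(e)
    json_scalar(e$segmentation_id), character(1)))
  if (!identical(ids(metadata$segmentations$lattice %||% list()),
                 sort(vapply(lattices, function(s) s$segmentation_id,
                             character(1))))) {
    err("lattice segmentation inventory mismatch")
  }
  if (!identical(ids(metadata$segmentations$geometric %||% list()),
                 sort(vapply(geoms, function(s) s$segmentation_id,
                             character(1))))) {
    err("geometric segmentation inventory mismatch")
  }
  if (!identical(ids(metadata$segmentations$mesh %||% list()),
                 sort(vapply(meshes, function(s) s$segmentation_id,
                             character(1))))) {
    err("mesh segmentation inventory mismatch")
  }
  invisible(TRUE)
}

#' Write an entry into the database
#'
#' Creates the database root and source subdirectory as needed, stages all
#' payloads, and renames the finished entry directory into place.
#'
#' @param db_root Database root (created if absent).
#' @param key An [entry_key()].
#' @param volumes,lattices,geoms,meshes Entry payloads (see
#'   [build_entry_metadata()]).
#' @param annotations Annotations document; must validate.
#' @param metadata Metadata document; must be consistent with the payloads.
#' @param overwrite Replace an existing entry instead of refusing.
#' @return The entry directory path, invisibly.
#' @export
write_entry <- function(db_root, key, volumes = list(), lattices = list(),
                        geoms = list(), meshes = list(),
                        annotations, metadata, overwrite = FALSE) {
  viol <- validate_annotations(annotations)
  if (length(viol) > 0L) {
    stop("annotations document invalid:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  check_metadata_consistency(metadata, volumes, lattices, geoms, meshes)
  if (!overwrite && entry_exists(db_root, key)) {
    stop("entry ", format(key), " already exists in ", db_root,
         "; refusing to overwrite", call. = FALSE)
  }
  dir.create(file.path(db_root, key$source_db), recursive = TRUE,
             showWarnings = FALSE)
  stage <- file.path(db_root, key$source_db,
                     paste0(".staging-", key$entry_id, "-", Sys.getpid()))
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE), add = TRUE)

  payload_dir <- file.path(stage, "payload")
  dir.create(payload_dir)
  for (v in volumes) {
    for (tf in names(v$frames)) {
      for (fac in names(v$frames[[tf]])) {
        d <- file.path(payload_dir, "volume", v$channel_id, tf)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        write_mrc(v$frames[[tf]][[fac]], file.path(d, paste0(fac, ".map")))
      }
    }
  }
  for (s in lattices) {
    for (tf in names(s$frames)) {
      for (fac in names(s$frames[[tf]])) {
        d <- file.path(payload_dir, "lattice", s$segmentation_id, tf)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        write_mrc(s$frames[[tf]][[fac]], file.path(d, paste0(fac, ".map")),
                  mode = 1L)
      }
    }
  }
  if (length(geoms) + length(meshes) > 0L) {
    dir.create(file.path(payload_dir, "geometric"), showWarnings = FALSE)
    dir.create(file.path(payload_dir, "mesh"), showWarnings = FALSE)
    for (g in geoms) {
      write_canonical_json(geom_to_doc(g),
                           file.path(payload_dir, "geometric",
                                     paste0(g$segmentation_id, ".json")))
    }
    for (m in meshes) {
      write_canonical_json(mesh_to_doc(m),
                           file.path(payload_dir, "mesh",
                                     paste0(m$segmentation_id, ".json")))
    }
  }
  members <- sort(list.files(payload_dir, recursive = TRUE))
  zip::zip(file.path(stage, "data.zip"), members, root = payload_dir,
           compression_level = 6, mode = "mirror")
  unlink(payload_dir, recursive = TRUE)
  write_canonical_json(annotations, file.path(stage, "annotations.json"))
  write_canonical_json(metadata, file.path(stage, "metadata.json"))

  dest <- entry_dir(db_root, key)
  if (overwrite && dir.exists(dest)) unlink(dest, recursive = TRUE)
  if (!file.rename(stage, dest)) {
    stop("failed to move staged entry into place: ", dest, call. = FALSE)
  }
  ok <- TRUE
  invisible(dest)
}

#' Read an entry's metadata (without touching data.zip)
#' @inheritParams entry_exists
#' @return Metadata document.
#' @export
read_entry_metadata <- function(db_root, key) {
  if (!entry_exists(db_root, key)) {
    stop("entry not found: ", format(key), " in ", db_root, call. = FALSE)
  }
  read_json_doc(file.path(entry_dir(db_root, key), "metadata.json"))
}

#' Read an entry's annotations (without touching data.zip)
#' @inheritParams entry_exists
#' @return Annotations document.
#' @export
read_entry_annotations <- function(db_root, key) {
  if (!entry_exists(db_root, key)) {
    stop("entry not found: ", format(key), " in ", db_root, call. = FALSE)
  }
  read_json_doc(file.path(entry_dir(db_root, key), "annotations.json"))
}

#' List the members of an entry's data.zip
#' @inheritParams entry_exists
#' @return Character vector of member paths.
#' @export
list_entry_payloads <- function(db_root, key) {
  zp <- file.path(entry_dir(db_root, key), "data.zip")
  if (!file.exists(zp)) stop("entry has no data.zip: ", format(key),
                             call. = FALSE)
  sort(zip::zip_list(zp)$filename)
}

extract_entry_payload <- function(db_root, key, member, exdir) {
  zp <- file.path(entry_dir(db_root, key), "data.zip")
  listing <- zip::zip_list(zp)$filename
  if (!member %in% listing) {
    stop("format error in data.zip of ", format(key),
         ": missing member ", member, call. = FALSE)
  }
  zip::unzip(zp, files = member, exdir = exdir)
  file.path(exdir, member)
}

#' Read a full entry back from the database
#'
#' Reconstructs all payloads plus annotations and metadata. Results are
#' identical to what [write_entry()] stored.
#'
#' @inheritParams entry_exists
#' @return List with `volumes`, `lattices`, `geoms`, `meshes`,
#'   `annotations`, `metadata`.
#' @export
read_entry <- function(db_root, key) {
  metadata <- read_entry_metadata(db_root, key)
  annotations <- read_entry_annotations(db_root, key)
  zp <- file.path(entry_dir(db_root, key), "data.zip")
  ex <- tempfile("entry-read-")
  dir.create(ex)
  on.exit(unlink(ex, recursive = TRUE), add = TRUE)
  tryCatch(zip::unzip(zp, exdir = ex),
           error = function(e) stop("format error in data.zip of ",
                                    format(key), ": ", conditionMessage(e),
                                    call. = FALSE))
  read_pyramid <- function(dir, labels = FALSE) {
    frames <- list()
    for (tf in sort(as.integer(list.files(dir)))) {
      fdir <- file.path(dir, tf)
      pyr <- list()
      for (fac in sort(as.integer(sub("\\.map$", "", list.files(fdir))))) {
        g <- read_map(file.path(fdir, paste0(fac, ".map")))
        pyr[[as.character(fac)]] <- if (labels) {
          label_grid(g$values, voxel_size = g$voxel_size, origin = g$origin)
        } else g
      }
      frames[[as.character(tf)]] <- pyr
    }
    frames
  }
  volumes <- list()
  vdir <- file.path(ex, "volume")
  if (dir.exists(vdir)) {
    for (ch in sort(list.files(vdir))) {
      volumes[[length(volumes) + 1L]] <-
        multiscale_volume(ch, read_pyramid(file.path(vdir, ch)))
    }
  }
  lattices <- list()
  ldir <- file.path(ex, "lattice")
  if (dir.exists(ldir)) {
    for (sid in sort(list.files(ldir))) {
      lattices[[length(lattices) + 1L]] <-
        lattice_segmentation(sid, read_pyramid(file.path(ldir, sid),
                                               labels = TRUE))
    }
  }
  geoms <- list()
  gdir <- file.path(ex, "geometric")
  if (dir.exists(gdir)) {
    for (f in sort(list.files(gdir))) {
      geoms[[length(geoms) + 1L]] <-
        read_geometric_segmentation(file.path(gdir, f))
    }
  }
  meshes <- list()
  mdir <- file.path(ex, "mesh")
  if (dir.exists(mdir)) {
    for (f in sort(list.files(mdir))) {
      meshes[[length(meshes) + 1L]] <- doc_to_mesh(read_json_doc(file.path(mdir, f)))
    }
  }
  list(volumes = volumes, lattices = lattices, geoms = geoms,
       meshes = meshes, annotations = annotations, metadata = metadata)
}

#' List entries in the database
#'
#' @param db_root Database root.
#' @param source_db Optional source-database filter.
#' @return `data.frame` with columns `source_db` and `entry_id`, sorted and
#'   deduplicated. A missing root yields an empty listing with a warning.
#' @export
list_entries <- function(db_root, source_db = NULL) {
  empty <- data.frame(source_db = character(), entry_id = character(),
                      stringsAsFactors = FALSE)
  if (!dir.exists(db_root)) {
    warning("database root does not exist: ", db_root, call. = FALSE)
    return(empty)
  }
  sources <- sort(list.files(db_root))
  if (!is.null(source_db)) sources <- intersect(sources, source_db)
  out <- empty
  for (s in sources) {
    sdir <- file.path(db_root, s)
    if (!dir.exists(sdir)) next
    for (e in sort(list.files(sdir))) {
      if (startsWith(e, ".")) next
      if (file.exists(file.path(sdir, e, "metadata.json"))) {
        out <- rbind(out, data.frame(source_db = s, entry_id = e,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  unique(out[order(out$source_db, out$entry_id), , drop = FALSE])
}

#' Remove an entry from the database
#'
#' @inheritParams entry_exists
#' @return The removed entry's key, invisibly.
#' @export
remove_entry <- function(db_root, key) {
  if (!entry_exists(db_root, key)) {
    stop("entry not found: ", format(key), " in ", db_root, call. = FALSE)
  }
  unlink(entry_dir(db_root, key), recursive = TRUE)
  invisible(key)
}
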