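# EMDB-SFF segmentation files (HDF5).
#
# The reader consumes the subset of the EMDB-SFF model this package needs:
# a segment_list whose segments carry biological annotations (name,
# description), a colour, and either a three_d_volume reference into a
# lattice_list (lattice segments) or a mesh_list (mesh segments). Fixture
# files written by make_sff_fixture() follow exactly this structure;
# byte-level parity with sfftk-produced .hff files is not claimed.
#
# Layout read and written:
#   /version, /name
#   /segment_list/<id>/id
#   /segment_list/<id>/biological_annotation/{name, description}
#   /segment_list/<id>/colour                  float[4]
#   /segment_list/<id>/three_d_volume/{lattice_id, value}
#   /segment_list/<id>/mesh_list/<mid>/{vertices, triangles}
#   /lattice_list/<id>/{size, data}            data: int array, x fastest

h5_has <- function(listing, name) name %in% listing$name |
  name %in% paste0(listing$group, "/", listing$name)

h5_read_string <- function(file, path) {
  out <- tryCatch(rhdf5::h5read(file, path), error = function(e) NULL)
  if (is.null(out)) NULL else as.character(out)[1]
}

#' Read an EMDB-SFF segmentation file
#'
#' Volume (lattice) segments become lattice segmentations, mesh segments
#' become mesh segmentations, and per-segment biological names, descriptions
#' and colours become description / segment-annotation records that
#' preprocessing passes through untouched.
#'
#' @param path Path to an `.hff` HDF5 file.
#' @param voxel_size,origin Grid geometry to attach to lattice grids
#'   (SFF lattices carry no physical sampling of their own here).
#' @return List with elements `lattices` (list of [lattice_segmentation()]),
#'   `meshes` (list of [mesh_segmentation()]) and `annotations` (fragment
#'   with `descriptions` and `segment_annotations`).
#' @export
read_sff <- function(path, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls_all <- rhdf5::h5ls(path)
  roots <- ls_all$name[ls_all$group == "/"]
  if ("transform_list" %in% roots) {
    stop("unsupported feature in ", path,
         ": SFF transform_list is not supported", call. = FALSE)
  }
  if (!"segment_list" %in% roots) {
    stop("format error in ", path, ": missing segment_list", call. = FALSE)
  }
  stem <- tools::file_path_sans_ext(basename(path))
  seg_groups <- ls_all$name[ls_all$group == "/segment_list"]
  if (length(seg_groups) == 0L) {
    warning("SFF file ", path, " contains zero segments", call. = FALSE)
    return(list(lattices = list(), meshes = list(),
                annotations = list(descriptions = structure(list(), names = character()),
                                   segment_annotations = list())))
  }

  lattice_raw <- list()
  if ("lattice_list" %in% roots) {
    for (lid in ls_all$name[ls_all$group == "/lattice_list"]) {
      dat <- rhdf5::h5read(path, paste0("/lattice_list/", lid, "/data"))
      lattice_raw[[lid]] <- array(as.integer(dat), dim = dim(dat))
    }
  }

  lattice_segments <- list()  # lattice_id -> list of segment records
  meshes <- list()
  descriptions <- structure(list(), names = character())
  seg_annots <- list()
  mesh_stub <- list()         # segment id -> mesh data

  for (g in seg_groups) {
    base <- paste0("/segment_list/", g)
    sid <- as.integer(rhdf5::h5read(path, paste0(base, "/id")))
    nm <- h5_read_string(path, paste0(base, "/biological_annotation/name"))
    dsc <- h5_read_string(path, paste0(base, "/biological_annotation/description"))
    col <- tryCatch(as.numeric(rhdf5::h5read(path, paste0(base, "/colour"))),
                    error = function(e) NULL)
    sub <- ls_all$name[ls_all$group == base]
    if ("three_d_volume" %in% sub) {
      lid <- as.character(as.integer(
        rhdf5::h5read(path, paste0(base, "/three_d_volume/lattice_id"))))
      value <- as.integer(rhdf5::h5read(path, paste0(base, "/three_d_volume/value")))
      if (is.null(lattice_raw[[lid]])) {
        stop("format error in ", path, ": segment ", sid,
             " references unknown lattice ", lid, call. = FALSE)
      }
      lattice_segments[[lid]] <- c(lattice_segments[[lid]],
                                   list(list(sid = sid, value = value,
                                             name = nm, description = dsc,
                                             colour = col)))
    } else if ("mesh_list" %in% sub) {
      mg <- ls_all$name[ls_all$group == paste0(base, "/mesh_list")]
      verts <- NULL; tris <- NULL
      for (mid in mg) {
        vv <- rhdf5::h5read(path, paste0(base, "/mesh_list/", mid, "/vertices"))
        tt <- rhdf5::h5read(path, paste0(base, "/mesh_list/", mid, "/triangles"))
        off <- if (is.null(verts)) 0L else nrow(verts)
        verts <- rbind(verts, matrix(as.numeric(vv), ncol = 3L))
        tris <- rbind(tris, matrix(as.integer(tt), ncol = 3L) + 1L + off)
      }
      mesh_stub[[as.character(sid)]] <-
        list(sid = sid, vertices = verts, triangles = tris,
             name = nm, description = dsc, colour = col)
    } else {
      stop("format error in ", path, ": segment ", sid,
           " has neither three_d_volume nor mesh_list", call. = FALSE)
    }
  }

  lattices <- list()
  for (lid in names(lattice_segments)) {
    seg_id <- if (length(lattice_raw) == 1L) stem else paste0(stem, "_lattice_", lid)
    lg <- label_grid(lattice_raw[[lid]], voxel_size = voxel_size,
                     origin = origin)
    lattices[[length(lattices) + 1L]] <-
      lattice_segmentation(seg_id, frames = list(`0` = list(`1` = lg)))
    for (rec in lattice_segments[[lid]]) {
      did <- paste0("desc-", seg_id, "-", rec$value)
      descriptions[[did]] <- description_record(
        id = did, target_kind = "lattice", segmentation_id = seg_id,
        segment_id = rec$value, name = rec$name,
        details = rec$description)
      seg_annots[[length(seg_annots) + 1L]] <- segment_annotation_record(
        "lattice", seg_id, rec$value,
        color = rec$colour %||% palette_color(rec$value), time = 0L)
    }
  }

  mesh_objs <- list()
  if (length(mesh_stub) > 0L) {
    seg_id <- paste0(stem, "_meshes")
    segs <- lapply(mesh_stub, function(m) {
      list(vertices = m$vertices, triangles = m$triangles)
    })
    names(segs) <- vapply(mesh_stub, function(m) as.character(m$sid), character(1))
    mesh_objs[[1L]] <- mesh_segmentation(seg_id, segs)
    for (m in mesh_stub) {
      did <- paste0("desc-", seg_id, "-", m$sid)
      descriptions[[did]] <- description_record(
        id = did, target_kind = "mesh", segmentation_id = seg_id,
        segment_id = m$sid, name = m$name, details = m$description)
      seg_annots[[length(seg_annots) + 1L]] <- segment_annotation_record(
        "mesh", seg_id, m$sid, color = m$colour %||% palette_color(m$sid),
        time = 0L)
    }
  }

  list(lattices = lattices, meshes = mesh_objs,
       annotations = list(descriptions = descriptions,
                          segment_annotations = seg_annots))
}

# Write an SFF file in the dialect read_sff() consumes (synthetic fixture
# writer; see make_sff_fixture for the user-facing interface).
write_sff_file <- function(path, name, lattices = list(), segments = list(),
                           mesh_segments = list()) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write("0.8.0", path, "version")
  rhdf5::h5write(name, path, "name")
  rhdf5::h5createGroup(path, "segment_list")
  if (length(lattices) > 0L) {
    rhdf5::h5createGroup(path, "lattice_list")
    for (lid in names(lattices)) {
      grp <- paste0("lattice_list/", lid)
      rhdf5::h5createGroup(path, grp)
      arr <- lattices[[lid]]
      rhdf5::h5write(as.integer(dim(arr)), path, paste0(grp, "/size"))
      rhdf5::h5write(array(as.integer(arr), dim = dim(arr)), path,
                     paste0(grp, "/data"))
    }
  }
  for (s in segments) {
    grp <- paste0("segment_list/", s$id)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(as.integer(s$id), path, paste0(grp, "/id"))
    rhdf5::h5createGroup(path, paste0(grp, "/biological_annotation"))
    rhdf5::h5write(s$name, path, paste0(grp, "/biological_annotation/name"))
    if (!is.null(s$description)) {
      rhdf5::h5write(s$description, path,
                     paste0(grp, "/biological_annotation/description"))
    }
    rhdf5::h5write(as.numeric(s$colour), path, paste0(grp, "/colour"))
    rhdf5::h5createGroup(path, paste0(grp, "/three_d_volume"))
    rhdf5::h5write(as.integer(s$lattice_id), path,
                   paste0(grp, "/three_d_volume/lattice_id"))
    rhdf5::h5write(as.integer(s$value), path,
                   paste0(grp, "/three_d_volume/value"))
  }
  for (m in mesh_segments) {
    grp <- paste0("segment_list/", m$id)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(as.integer(m$id), path, paste0(grp, "/id"))
    rhdf5::h5createGroup(path, paste0(grp, "/biological_annotation"))
    rhdf5::h5write(m$name, path, paste0(grp, "/biological_annotation/name"))
    rhdf5::h5write(as.numeric(m$colour), path, paste0(grp, "/colour"))
    rhdf5::h5createGroup(path, paste0(grp, "/mesh_list"))
    rhdf5::h5createGroup(path, paste0(grp, "/mesh_list/0"))
    rhdf5::h5write(m$vertices, path, paste0(grp, "/mesh_list/0/vertices"))
    rhdf5::h5write(matrix(as.integer(m$triangles - 1L), ncol = 3L), path,
                   paste0(grp, "/mesh_list/0/triangles"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}
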