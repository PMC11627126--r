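# OME-Zarr (OME NGFF) ingestion.
#
# A minimal zarr v2 directory-store implementation: enough to write
# deterministic fixtures and to ingest multiscale images with t/c/z/y/x
# axes, omero channel labels, scale coordinate transformations, and an
# optional labels subgroup. Chunks are C-order raw bytes, optionally
# zlib-compressed. Only the highest-resolution dataset (level "0") is read:
# source pyramids are not trusted; the preprocessor rebuilds its own.

.zarr_dtypes <- list(
  `<f4` = list(what = "numeric", size = 4L),
  `<f8` = list(what = "numeric", size = 8L),
  `<i1` = list(what = "integer", size = 1L, signed = TRUE),
  `|i1` = list(what = "integer", size = 1L, signed = TRUE),
  `<i2` = list(what = "integer", size = 2L, signed = TRUE),
  `<i4` = list(what = "integer", size = 4L, signed = TRUE),
  `|u1` = list(what = "integer", size = 1L, signed = FALSE),
  `<u1` = list(what = "integer", size = 1L, signed = FALSE),
  `<u2` = list(what = "integer", size = 2L, signed = FALSE))

# Read a whole zarr v2 array (C-order on disk) into an R array whose axis
# order is the REVERSE of the zarr shape (so the last zarr axis, typically
# x, is the fastest-varying first R axis).
read_zarr_array <- function(dir) {
  meta_path <- file.path(dir, ".zarray")
  if (!file.exists(meta_path)) {
    stop("format error: ", dir, " is not a zarr array (no .zarray)",
         call. = FALSE)
  }
  meta <- read_json_doc(meta_path)
  shape <- as.integer(json_num_vec(meta$shape))
  chunks <- as.integer(json_num_vec(meta$chunks))
  dtype <- json_scalar(meta$dtype)
  if (!identical(json_scalar(meta$order), "C")) {
    stop("unsupported feature: zarr order ", json_scalar(meta$order),
         call. = FALSE)
  }
  dt <- .zarr_dtypes[[dtype]]
  if (is.null(dt)) stop("unsupported feature: zarr dtype ", dtype, call. = FALSE)
  comp <- meta$compressor
  comp_id <- if (is.null(comp)) NULL else json_scalar(comp$id)
  if (!is.null(comp_id) && comp_id != "zlib") {
    stop("unsupported feature: zarr compressor ", comp_id, call. = FALSE)
  }
  fill <- json_scalar(meta$fill_value) %||% 0
  nd <- length(shape)
  rdim <- rev(shape)
  out <- array(as.numeric(fill), dim = rdim)
  ngrid <- ceiling(shape / chunks)
  grid_idx <- as.matrix(do.call(expand.grid, lapply(ngrid, function(n) 0:(n - 1L))))
  for (r in seq_len(nrow(grid_idx))) {
    idx <- as.integer(grid_idx[r, ])
    cfile <- file.path(dir, paste(idx, collapse = "."))
    if (!file.exists(cfile)) next  # missing chunk = fill value
    raw <- readBin(cfile, "raw", n = file.size(cfile))
    if (identical(comp_id, "zlib")) raw <- memDecompress(raw, type = "gzip")
    nvals <- prod(chunks)
    vals <- if (dt$what == "numeric") {
      readBin(raw, "numeric", n = nvals, size = dt$size, endian = "little")
    } else {
      readBin(raw, "integer", n = nvals, size = dt$size, signed = dt$signed,
              endian = "little")
    }
    carr <- array(as.numeric(vals), dim = rev(chunks))  # C-order -> rev axes
    # clip chunk overhang at array edges, then place (reversed axis order)
    start <- idx * chunks + 1L
    stop_ <- pmin(start + chunks - 1L, shape)
    keep <- stop_ - start + 1L
    idx_list <- lapply(seq_len(nd), function(k) {
      rk <- nd - k + 1L  # reversed axis
      seq_len(keep[rk])
    })
    dst_list <- lapply(seq_len(nd), function(k) {
      rk <- nd - k + 1L
      seq.int(start[rk], stop_[rk])
    })
    out <- do.call(`[<-`, c(list(out), dst_list,
                            list(value = do.call(`[`, c(list(carr), idx_list)))))
  }
  out
}

write_zarr_array <- function(dir, arr_revaxes, zarr_shape, dtype = "<f4") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(chunks = as.list(zarr_shape), compressor = NULL,
               dtype = dtype, fill_value = 0, filters = NULL, order = "C",
               shape = as.list(zarr_shape), zarr_format = 2L)
  write_canonical_json(meta, file.path(dir, ".zarray"))
  dt <- .zarr_dtypes[[dtype]]
  v <- as.vector(arr_revaxes)  # first R axis fastest = last zarr axis fastest
  con <- file(file.path(dir, paste(rep("0", length(zarr_shape)), collapse = ".")),
              open = "wb")
  on.exit(close(con))
  if (dt$what == "numeric") {
    writeBin(as.numeric(v), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.integer(v), con, size = dt$size, endian = "little")
  }
  invisible(dir)
}

.axis_unit_to_angstrom <- function(unit) {
  switch(unit %||% "",
         angstrom = 1,
         nanometer = 10,
         micrometer = 1e4,
         millimeter = 1e7,
         NA_real_)
}

# Parse one NGFF multiscale group (image or label) at `path` into per-channel,
# per-time 3D arrays [x, y, z] plus geometry.
read_ngff_group <- function(path, what = "image") {
  attrs_path <- file.path(path, ".zattrs")
  if (!file.exists(attrs_path)) {
    stop("format error: ", path, " has no .zattrs", call. = FALSE)
  }
  attrs <- read_json_doc(attrs_path)
  ms <- attrs$multiscales
  if (is.null(ms) || length(ms) < 1L) {
    stop("format error: ", path, " has no multiscales metadata", call. = FALSE)
  }
  ms <- ms[[1L]]
  axes <- vapply(ms$axes, function(a) json_scalar(a$name), character(1))
  units <- vapply(ms$axes, function(a) json_scalar(a$unit) %||% NA_character_,
                  character(1))
  bad <- setdiff(axes, c("t", "c", "z", "y", "x"))
  if (length(bad) > 0L) {
    stop("unsupported feature: unknown axis name ", bad[1L], call. = FALSE)
  }
  ds <- ms$datasets[[1L]]  # highest-resolution level only
  lvl_path <- file.path(path, json_scalar(ds$path))
  scale <- rep(1, length(axes))
  for (ct in ds$coordinateTransformations) {
    if (identical(json_scalar(ct$type), "scale")) scale <- json_num_vec(ct$scale)
  }
  arr <- read_zarr_array(lvl_path)  # axes reversed: (x, y, z, c, t) subsets

  ax_rev <- rev(axes)
  pick <- function(ax) match(ax, ax_rev)  # position in R array, NA if absent
  nt <- if (is.na(pick("t"))) 1L else dim(arr)[pick("t")]
  nc <- if (is.na(pick("c"))) 1L else dim(arr)[pick("c")]

  # physical voxel size (Angstrom) along x, y, z
  vs <- c(1, 1, 1)
  for (k in 1:3) {
    ax <- c("x", "y", "z")[k]
    j <- match(ax, axes)
    if (!is.na(j)) {
      f <- .axis_unit_to_angstrom(units[j])
      if (is.na(f)) {
        warning("axis ", ax, " in ", path,
                " has no recognised unit; treating scale as Angstrom",
                call. = FALSE)
        f <- 1
      }
      vs[k] <- scale[j] * f
    }
  }

  slice_3d <- function(ci, ti) {
    idx <- lapply(seq_along(dim(arr)), function(k) seq_len(dim(arr)[k]))
    if (!is.na(pick("c"))) idx[[pick("c")]] <- ci
    if (!is.na(pick("t"))) idx[[pick("t")]] <- ti
    sub <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    d3 <- c(if (is.na(pick("x"))) 1L else dim(arr)[pick("x")],
            if (is.na(pick("y"))) 1L else dim(arr)[pick("y")],
            if (is.na(pick("z"))) 1L else dim(arr)[pick("z")])
    array(as.numeric(sub), dim = d3)  # (x, y, z) are the leading rev axes
  }

  chans <- lapply(seq_len(nc), function(ci) {
    frames <- lapply(seq_len(nt), function(ti) slice_3d(ci, ti))
    names(frames) <- as.character(seq_len(nt) - 1L)
    frames
  })
  list(channels = chans, voxel_size = vs, attrs = attrs,
       n_time = nt, n_channels = nc)
}

#' Read an OME-Zarr (OME NGFF) image group
#'
#' Parses the multiscales metadata (axes must be a subset of t, c, z, y, x),
#' converts scale coordinate transformations to an Angstrom voxel size, and
#' slices the highest-resolution level into one [multiscale_volume()] per
#' channel (single pyramid level; the preprocessor rebuilds coarser levels).
#' Channel ids come from omero channel labels when present, else the channel
#' index as a string. A `labels` subgroup yields one [lattice_segmentation()]
#' per label image.
#'
#' @param path Path to the `.zarr` directory.
#' @return List with elements `volumes` (list of [multiscale_volume()]) and
#'   `lattices` (list of [lattice_segmentation()]).
#' @export
read_omezarr <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
  img <- read_ngff_group(path, "image")
  labels <- NULL
  omero <- img$attrs$omero
  channel_labels <- NULL
  if (!is.null(omero) && !is.null(omero$channels)) {
    channel_labels <- vapply(omero$channels,
                             function(ch) json_scalar(ch$label) %||% NA_character_,
                             character(1))
  }
  volumes <- lapply(seq_len(img$n_channels), function(ci) {
    cid <- if (!is.null(channel_labels) && !is.na(channel_labels[ci])) {
      channel_labels[ci]
    } else {
      as.character(ci - 1L)
    }
    frames <- lapply(img$channels[[ci]], function(a) {
      list(`1` = volume_grid(a, voxel_size = img$voxel_size))
    })
    multiscale_volume(cid, frames)
  })

  lattices <- list()
  labels_dir <- file.path(path, "labels")
  if (dir.exists(labels_dir)) {
    lab_attrs <- read_json_doc(file.path(labels_dir, ".zattrs"))
    for (lname in vapply(lab_attrs$labels, json_scalar, character(1))) {
      lab <- read_ngff_group(file.path(labels_dir, lname), "label")
      frames <- lapply(lab$channels[[1L]], function(a) {
        list(`1` = label_grid(a, voxel_size = lab$voxel_size))
      })
      lattices[[length(lattices) + 1L]] <-
        lattice_segmentation(lname, frames = frames)
    }
  }
  list(volumes = volumes, lattices = lattices)
}

# Write a minimal OME-Zarr fixture group. `data` is an R array whose axes
# are the REVERSE of `axes` (x fastest); e.g. axes "tczyx" takes data with
# dim (nx, ny, nz, nc, nt).
write_omezarr_group <- function(path, data, axes, scale_xyz = c(1, 1, 1),
                                unit = "micrometer", channel_labels = NULL,
                                labels = NULL, dtype = "<f4") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_canonical_json(list(zarr_format = 2L), file.path(path, ".zgroup"))
  ax <- strsplit(axes, "")[[1L]]
  axis_meta <- lapply(ax, function(a) {
    switch(a,
           t = list(name = "t", type = "time"),
           c = list(name = "c", type = "channel"),
           list(name = a, type = "space", unit = unit))
  })
  scale <- vapply(ax, function(a) {
    switch(a, x = scale_xyz[1], y = scale_xyz[2], z = scale_xyz[3], 1)
  }, numeric(1))
  attrs <- list(multiscales = list(list(
    version = "0.4", name = basename(path), axes = axis_meta,
    datasets = list(list(path = "0",
                         coordinateTransformations = list(
                           list(type = "scale", scale = as.list(unname(scale)))))))))
  if (!is.null(channel_labels)) {
    attrs$omero <- list(channels = lapply(channel_labels,
                                          function(l) list(label = l)))
  }
  write_canonical_json(attrs, file.path(path, ".zattrs"))
  zarr_shape <- rev(dim(data))
  write_zarr_array(file.path(path, "0"), data, zarr_shape, dtype = dtype)
  if (!is.null(labels)) {
    labels_dir <- file.path(path, "labels")
    dir.create(labels_dir, showWarnings = FALSE)
    write_canonical_json(list(zarr_format = 2L), file.path(labels_dir, ".zgroup"))
    write_canonical_json(list(labels = as.list(names(labels))),
                         file.path(labels_dir, ".zattrs"))
    lab_axes <- paste(setdiff(ax, "c"), collapse = "")
    for (lname in names(labels)) {
      write_omezarr_group(file.path(labels_dir, lname), labels[[lname]],
                          axes = lab_axes, scale_xyz = scale_xyz, unit = unit,
                          dtype = "<i4")
    }
  }
  invisible(path)
}
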