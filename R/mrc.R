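# MRC/CCP4 map reading and writing.
#
# Implements the 1024-byte MRC2014 header with modes 0 (int8), 1 (int16),
# 2 (float32) and 6 (uint16), little-endian on disk. Axis order on disk is
# given by MAPC/MAPR/MAPS; values are permuted into the canonical in-memory
# order (x fastest). Voxel size is CELLA / (MX, MY, MZ); a CELLA of 0 yields
# a voxel size of 0 which is preserved and flagged invalid rather than
# rejected, so that an extra-data override can repair it downstream.

.mrc_modes <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Write a grid as an MRC/CCP4 map
#'
#' @param grid A [volume_grid()] or [label_grid()] (or bare 3D array).
#' @param path Output path.
#' @param mode MRC mode: 0 (int8), 1 (int16), 2 (float32), 6 (uint16).
#' @param cella_zero If `TRUE`, write CELLA as (0, 0, 0), emulating maps with
#'   broken headers whose voxel size cannot be derived.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(grid, path, mode = 2L, cella_zero = FALSE) {
  if (is.array(grid)) grid <- volume_grid(grid)
  values <- grid$values
  dims <- dim(values)
  voxel_size <- grid$voxel_size %||% c(1, 1, 1)
  origin <- grid$origin %||% c(0, 0, 0)
  mode <- as.integer(mode)
  if (!as.character(mode) %in% names(.mrc_modes)) {
    stop("unsupported MRC mode: ", mode, call. = FALSE)
  }
  cella <- if (cella_zero) c(0, 0, 0) else voxel_size * dims
  v <- as.numeric(values)
  con <- file(path, open = "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(dims)                      # NX NY NZ
  wi(mode)                      # MODE
  wi(c(0L, 0L, 0L))             # NXSTART NYSTART NZSTART
  wi(dims)                      # MX MY MZ
  wf(cella)                     # CELLA
  wf(c(90, 90, 90))             # CELLB
  wi(c(1L, 2L, 3L))             # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))                 # ISPG NSYMBT
  wi(integer(25L))              # EXTRA
  wf(origin)                    # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))              # RMS
  wi(0L)                        # NLABL
  writeBin(raw(800L), con)      # labels
  switch(.mrc_modes[[as.character(mode)]],
    int8    = writeBin(as.integer(v), con, size = 1L, endian = "little"),
    int16   = writeBin(as.integer(v), con, size = 2L, endian = "little"),
    float32 = writeBin(v, con, size = 4L, endian = "little"),
    uint16  = {
      iv <- as.integer(v)
      if (any(iv < 0L | iv > 65535L)) {
        stop("values out of uint16 range", call. = FALSE)
      }
      # writeBin has no unsigned 16-bit type; encode the two bytes directly
      writeBin(as.raw(rbind(iv %% 256L, iv %/% 256L)), con)
    })
  invisible(path)
}

read_mrc_header <- function(con, path) {
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) {
    stop("format error in ", path, ": truncated header (", length(hdr_raw),
         " of 1024 bytes)", call. = FALSE)
  }
  ri <- function(word, n = 1L) {
    readBin(hdr_raw[((word - 1L) * 4L + 1L):((word - 1L + n) * 4L)],
            "integer", n = n, size = 4L, endian = "little")
  }
  rf <- function(word, n = 1L) {
    readBin(hdr_raw[((word - 1L) * 4L + 1L):((word - 1L + n) * 4L)],
            "numeric", n = n, size = 4L, endian = "little")
  }
  map_tag <- rawToChar(hdr_raw[209:212])
  list(nxyz = ri(1L, 3L), mode = ri(4L), nstart = ri(5L, 3L),
       mxyz = ri(8L, 3L), cella = rf(11L, 3L),
       mapcrs = ri(17L, 3L), dmin = rf(20L), dmax = rf(21L), dmean = rf(22L),
       origin = rf(50L, 3L), map_tag = map_tag, rms = rf(55L))
}

#' Read an MRC/CCP4 map
#'
#' @param path Path to a `.map`/`.mrc` file.
#' @return A [volume_grid()]. A voxel size of 0 (CELLA = 0 in the header) is
#'   preserved with `voxel_size_valid = FALSE` so an extra-data override can
#'   supply the true value.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, open = "rb")
  on.exit(close(con))
  h <- read_mrc_header(con, path)
  if (!as.character(h$mode) %in% names(.mrc_modes)) {
    stop("format error in ", path, ": unsupported MODE ", h$mode, call. = FALSE)
  }
  if (any(h$nxyz < 1L)) {
    stop("format error in ", path, ": non-positive dimension in NX/NY/NZ",
         call. = FALSE)
  }
  if (!identical(sort(h$mapcrs), 1:3)) {
    stop("format error in ", path, ": MAPC/MAPR/MAPS must be a permutation of 1:3",
         call. = FALSE)
  }
  n <- prod(h$nxyz)
  type <- .mrc_modes[[as.character(h$mode)]]
  vals <- switch(type,
    int8    = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                      endian = "little"),
    int16   = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                      endian = "little"),
    float32 = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    uint16  = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                      endian = "little"))
  if (length(vals) < n) {
    stop("format error in ", path, ": truncated data section (",
         length(vals), " of ", n, " voxels)", call. = FALSE)
  }
  arr <- array(as.numeric(vals), dim = h$nxyz)
  perm <- order(h$mapcrs)                 # disk axes -> canonical x,y,z
  if (!identical(perm, 1:3)) arr <- aperm(arr, perm)
  # MX/MY/MZ and CELLA are expressed along cell (x, y, z) axes already
  voxel_size <- ifelse(h$mxyz > 0L & h$cella != 0, h$cella / h$mxyz, 0)
  origin <- h$origin
  if (all(origin == 0) && any(h$nstart != 0L)) {
    nstart_xyz <- h$nstart[perm]
    origin <- nstart_xyz * voxel_size
  }
  volume_grid(arr, voxel_size = voxel_size, origin = origin)
}

#' Read an integer mask map as a lattice segmentation
#'
#' The file must be an MRC map whose values are non-negative integers (within
#' 1e-6 of an integer). The segmentation id defaults to the file stem, e.g.
#' `emd_1273_msk_1` for `emd_1273_msk_1.map`.
#'
#' @param path Path to a mask `.map` file.
#' @param segmentation_id Segmentation id; default is the file stem.
#' @return A [lattice_segmentation()] with a single time frame (0) at level
#'   factor 1. An all-zero mask yields empty `segment_ids` with a warning.
#' @export
read_mask <- function(path, segmentation_id = NULL) {
  vg <- read_map(path)
  v <- as.numeric(vg$values)
  if (max(abs(v - round(v))) > 1e-6 || any(v < -1e-6)) {
    stop("format error in ", path,
         ": mask values must be non-negative integers", call. = FALSE)
  }
  if (is.null(segmentation_id)) {
    segmentation_id <- sub("\\.(map|mrc)$", "", basename(path),
                           ignore.case = TRUE)
  }
  lg <- label_grid(array(round(v), dim = vg$dims),
                   voxel_size = vg$voxel_size, origin = vg$origin)
  seg <- lattice_segmentation(segmentation_id,
                              frames = list(`0` = list(`1` = lg)))
  if (length(seg$segment_ids) == 0L) {
    warning("mask ", path, " contains no nonzero labels", call. = FALSE)
  }
  seg
}
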