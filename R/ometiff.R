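# OME-TIFF series ingestion.
#
# Reading goes through tiff::readTIFF for the pixel planes and xml2 for the
# embedded OME-XML dimension metadata (SizeX/Y/Z/C/T, channel names,
# physical sizes, TiffData file references for multi-file series). Writing
# (fixtures only) emits baseline little-endian TIFF directly — uncompressed
# float32 strips, one IFD per z-plane, OME-XML in the first IFD's
# ImageDescription — because the installed tiff package cannot write a
# description tag.

# --- minimal baseline TIFF writer ------------------------------------------

# slices: list of nx-by-ny matrices (canonical [x, y]); written row-major.
write_tiff_planes <- function(path, slices, description = NULL) {
  nx <- nrow(slices[[1L]]); ny <- ncol(slices[[1L]])
  npages <- length(slices)
  desc_raw <- if (is.null(description)) NULL else c(charToRaw(description), as.raw(0L))
  plane_bytes <- nx * ny * 4L
  # layout: header(8) | desc | planes | IFDs
  desc_off <- 8L
  desc_len <- if (is.null(desc_raw)) 0L else length(desc_raw)  # tag count incl. NUL
  desc_stored <- desc_len + desc_len %% 2L                     # pad to even offset
  if (!is.null(desc_raw) && desc_stored > desc_len) desc_raw <- c(desc_raw, as.raw(0L))
  data_off <- desc_off + desc_stored
  ifd_off <- data_off + plane_bytes * npages
  ifd_entry <- function(tag, type, count, value) {
    # type 3 = SHORT, 4 = LONG, 2 = ASCII
    v <- raw(4L)
    if (type == 3L) {
      v[1:2] <- writeBin(as.integer(value), raw(), size = 2L, endian = "little")
    } else {
      v[1:4] <- writeBin(as.integer(value), raw(), size = 4L, endian = "little")
    }
    c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
      writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
      writeBin(as.integer(count), raw(), size = 4L, endian = "little"),
      v)
  }
  ifds <- raw(0)
  ifd_sizes <- integer(npages)
  for (p in seq_len(npages)) {
    n_entries <- if (p == 1L && !is.null(desc_raw)) 11L else 10L
    ifd_sizes[p] <- 2L + n_entries * 12L + 4L
  }
  ifd_starts <- ifd_off + cumsum(c(0L, ifd_sizes))[seq_len(npages)]
  for (p in seq_len(npages)) {
    entries <- list(
      ifd_entry(256L, 4L, 1L, nx),            # ImageWidth
      ifd_entry(257L, 4L, 1L, ny),            # ImageLength
      ifd_entry(258L, 3L, 1L, 32L),           # BitsPerSample
      ifd_entry(259L, 3L, 1L, 1L),            # Compression = none
      ifd_entry(262L, 3L, 1L, 1L))            # Photometric = BlackIsZero
    if (p == 1L && !is.null(desc_raw)) {
      entries <- c(entries, list(ifd_entry(270L, 2L, desc_len, desc_off)))
    }
    entries <- c(entries, list(
      ifd_entry(273L, 4L, 1L, data_off + (p - 1L) * plane_bytes),  # StripOffsets
      ifd_entry(277L, 3L, 1L, 1L),            # SamplesPerPixel
      ifd_entry(278L, 4L, 1L, ny),            # RowsPerStrip (one strip)
      ifd_entry(279L, 4L, 1L, plane_bytes),   # StripByteCounts
      ifd_entry(339L, 3L, 1L, 3L)))           # SampleFormat = IEEE float
    nxt <- if (p < npages) ifd_starts[p + 1L] else 0L
    ifds <- c(ifds,
              writeBin(length(entries), raw(), size = 2L, endian = "little"),
              do.call(c, entries),
              writeBin(as.integer(nxt), raw(), size = 4L, endian = "little"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_starts[1L]), con, size = 4L, endian = "little")
  if (!is.null(desc_raw)) writeBin(desc_raw, con)
  for (p in seq_len(npages)) {
    writeBin(as.numeric(as.vector(slices[[p]])), con, size = 4L,
             endian = "little")
  }
  writeBin(ifds, con)
  invisible(path)
}

ome_unit_to_angstrom <- function(unit) {
  switch(unit %||% "µm",
         `µm` = 1e4, um = 1e4, micron = 1e4, micrometer = 1e4,
         nm = 10, nanometer = 10,
         `Å` = 1, A = 1, angstrom = 1, Angstrom = 1,
         mm = 1e7,
         NA_real_)
}

build_ome_xml <- function(name, nx, ny, nz, nc, nt, physical_xyz, unit,
                          channel_names, file_names = NULL) {
  ch <- paste0(vapply(seq_len(nc), function(c) {
    sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
            c - 1L, channel_names[c])
  }, character(1)), collapse = "")
  td <- if (is.null(file_names)) {
    sprintf('<TiffData IFD="0" PlaneCount="%d"/>', nz * nc * nt)
  } else {
    paste0(unlist(lapply(seq_len(nt), function(t) {
      vapply(seq_len(nc), function(c) {
        sprintf(paste0('<TiffData FirstZ="0" FirstC="%d" FirstT="%d" IFD="0" ',
                       'PlaneCount="%d"><UUID FileName="%s"/></TiffData>'),
                c - 1L, t - 1L, nz, file_names[[t]][[c]])
      }, character(1))
    })), collapse = "")
  }
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
         sprintf('<Image ID="Image:0" Name="%s">', name),
         sprintf(paste0('<Pixels ID="Pixels:0" DimensionOrder="XYZCT" Type="float" ',
                        'SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="%d" ',
                        'PhysicalSizeX="%g" PhysicalSizeY="%g" PhysicalSizeZ="%g" ',
                        'PhysicalSizeXUnit="%s" PhysicalSizeYUnit="%s" ',
                        'PhysicalSizeZUnit="%s">'),
                 nx, ny, nz, nc, nt,
                 physical_xyz[1], physical_xyz[2], physical_xyz[3],
                 unit, unit, unit),
         ch, td, '</Pixels></Image></OME>')
}

read_tiff_planes <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(m) t(m))  # readTIFF gives [row = y, col = x]
}

#' Read an OME-TIFF image series
#'
#' Channels and time frames are recovered from the OME-XML embedded in the
#' first file's ImageDescription. Multi-file series are resolved through the
#' OME-XML TiffData file references; when those are absent the reader falls
#' back to a `C{n}_TP{m}` filename pattern, and finally to treating the
#' single file as holding all planes in DimensionOrder.
#'
#' @param first_file Path to (the first file of) the `.ome.tif` series;
#'   companion files must live in the same directory.
#' @return List of [multiscale_volume()], one per channel, each with all
#'   time frames at pyramid level 1.
#' @export
read_ometiff_series <- function(first_file) {
  if (!file.exists(first_file)) {
    stop("file not found: ", first_file, call. = FALSE)
  }
  first_planes_raw <- tiff::readTIFF(first_file, all = TRUE, info = TRUE)
  if (!is.list(first_planes_raw)) first_planes_raw <- list(first_planes_raw)
  desc <- attr(first_planes_raw[[1L]], "description")
  if (is.null(desc) || !grepl("<OME", desc, fixed = TRUE)) {
    stop("format error in ", first_file, ": no OME-XML ImageDescription",
         call. = FALSE)
  }
  xml <- xml2::read_xml(desc)
  xml2::xml_ns_strip(xml)
  px <- xml2::xml_find_first(xml, ".//Pixels")
  sz <- function(a) as.integer(xml2::xml_attr(px, a))
  nx <- sz("SizeX"); ny <- sz("SizeY"); nz <- sz("SizeZ")
  nc <- sz("SizeC"); nt <- sz("SizeT")
  phys <- vapply(c("X", "Y", "Z"), function(a) {
    v <- suppressWarnings(as.numeric(xml2::xml_attr(px, paste0("PhysicalSize", a))))
    if (is.na(v)) 1 else v
  }, numeric(1))
  punit <- xml2::xml_attr(px, "PhysicalSizeXUnit")
  f <- ome_unit_to_angstrom(if (is.na(punit)) NULL else punit)
  if (is.na(f)) {
    warning("unrecognised physical size unit '", punit,
            "'; treating as Angstrom", call. = FALSE)
    f <- 1
  }
  voxel_size <- phys * f
  channel_names <- xml2::xml_attr(xml2::xml_find_all(px, ".//Channel"), "Name")
  if (length(channel_names) < nc || anyNA(channel_names)) {
    channel_names <- as.character(seq_len(nc) - 1L)
  }

  dirn <- dirname(first_file)
  tds <- xml2::xml_find_all(px, ".//TiffData")
  plane_source <- NULL  # function(c, t) -> list of [x, y] matrices (z slices)
  td_files <- list()
  for (td in tds) {
    fn <- xml2::xml_attr(xml2::xml_find_first(td, ".//UUID"), "FileName")
    if (is.na(fn)) next
    fc <- as.integer(xml2::xml_attr(td, "FirstC")); if (is.na(fc)) fc <- 0L
    ft <- as.integer(xml2::xml_attr(td, "FirstT")); if (is.na(ft)) ft <- 0L
    td_files[[paste(fc, ft)]] <- fn
  }
  if (length(td_files) > 0L) {
    plane_source <- function(c, t) {
      fn <- td_files[[paste(c - 1L, t - 1L)]]
      if (is.null(fn)) {
        stop("format error: OME-XML lists no file for channel ", c - 1L,
             ", time ", t - 1L, call. = FALSE)
      }
      fp <- file.path(dirn, fn)
      if (!file.exists(fp)) {
        stop("missing series file: ", fp, " (referenced from OME-XML)",
             call. = FALSE)
      }
      read_tiff_planes(fp)
    }
  } else if (nc * nt > 1L &&
             grepl("C[0-9]+_TP[0-9]+", basename(first_file))) {
    # filename-pattern fallback
    plane_source <- function(c, t) {
      fn <- sub("C[0-9]+_TP[0-9]+",
                sprintf("C%d_TP%d", c - 1L, t - 1L), basename(first_file))
      fp <- file.path(dirn, fn)
      if (!file.exists(fp)) {
        stop("missing series file: ", fp, " (expected by C{n}_TP{m} pattern)",
             call. = FALSE)
      }
      read_tiff_planes(fp)
    }
  } else {
    # all planes in this one file, DimensionOrder XYZCT
    all_planes <- lapply(first_planes_raw, function(m) t(m))
    if (length(all_planes) < nz * nc * nt) {
      stop("format error in ", first_file, ": ", length(all_planes),
           " planes for SizeZ*SizeC*SizeT = ", nz * nc * nt, call. = FALSE)
    }
    plane_source <- function(c, t) {
      base <- (t - 1L) * nc * nz + (c - 1L) * nz
      all_planes[base + seq_len(nz)]
    }
  }

  lapply(seq_len(nc), function(c) {
    frames <- lapply(seq_len(nt), function(t) {
      planes <- plane_source(c, t)
      arr <- array(0, dim = c(nx, ny, nz))
      for (z in seq_len(nz)) arr[, , z] <- planes[[z]]
      list(`1` = volume_grid(arr, voxel_size = voxel_size))
    })
    names(frames) <- as.character(seq_len(nt) - 1L)
    multiscale_volume(channel_names[c], frames)
  })
}

# Write an OME-TIFF fixture series: one file per (channel, time), each
# holding the z-stack, every file carrying the full-series OME-XML.
write_ometiff_series <- function(dir, stem, data, channel_names,
                                 physical_xyz = c(1, 1, 1), unit = "µm") {
  # data: array [x, y, z, c, t]
  d <- dim(data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nc <- d[4]; nt <- d[5]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file_names <- lapply(seq_len(nt), function(t) {
    lapply(seq_len(nc), function(c) {
      sprintf("%s_C%d_TP%d.ome.tif", stem, c - 1L, t - 1L)
    })
  })
  xml <- build_ome_xml(stem, nx, ny, nz, nc, nt, physical_xyz, unit,
                       channel_names, file_names)
  for (t in seq_len(nt)) {
    for (c in seq_len(nc)) {
      slices <- lapply(seq_len(nz), function(z) data[, , z, c, t])
      write_tiff_planes(file.path(dir, file_names[[t]][[c]]), slices,
                        description = xml)
    }
  }
  file.path(dir, file_names[[1L]][[1L]])
}
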