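# Deterministic synthetic fixtures.
#
# Every generator is a pure function of (parameters, seed): fixtures are
# byte-deterministic, so tests and worked examples are reproducible offline
# without downloading repository data. The generators emulate the structural
# features the readers care about (headers, axes, labels, particle tables),
# not the biological content of any real accession.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a volume map fixture
#'
#' @param out Output `.map` path.
#' @param dims Grid dims (length 3).
#' @param voxel_size Voxel size in Angstrom.
#' @param pattern `"gaussian-blob"` (smooth blob plus noise), `"gradient"`
#'   (linear ramp), or `"constant"`.
#' @param cella_zero Write CELLA = 0, emulating a broken header whose voxel
#'   size cannot be derived.
#' @param constant Value used by the `"constant"` pattern.
#' @param seed RNG seed.
#' @return `out`, invisibly.
#' @export
make_volume_fixture <- function(out, dims = c(32, 32, 32),
                                voxel_size = c(1, 1, 1),
                                pattern = c("gaussian-blob", "gradient",
                                            "constant"),
                                cella_zero = FALSE, constant = 1, seed = 0) {
  pattern <- match.arg(pattern)
  stopifnot(all(dims >= 1))
  arr <- with_seed(seed, {
    switch(pattern,
      `gaussian-blob` = {
        ctr <- dims / 2 + stats::runif(3, -dims / 8, dims / 8)
        sig <- max(dims) / 5
        g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                         z = seq_len(dims[3]))
        r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
        array(exp(-r2 / (2 * sig^2)) + stats::rnorm(nrow(g), sd = 0.02),
              dim = dims)
      },
      gradient = {
        g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                         z = seq_len(dims[3]))
        array((g$x + g$y + g$z) / sum(dims), dim = dims)
      },
      constant = array(constant, dim = dims))
  })
  write_mrc(volume_grid(arr, voxel_size = voxel_size), out,
            cella_zero = cella_zero)
  invisible(out)
}

#' Generate an integer mask fixture
#'
#' Places `n_segments` compact spherical blobs with labels 1..n, one per
#' slab along the x axis, so every label is guaranteed present.
#'
#' @param out Output `.map` path.
#' @param dims Grid dims.
#' @param n_segments Number of distinct nonzero labels (0 allowed).
#' @param seed RNG seed.
#' @return `out`, invisibly.
#' @export
make_mask_fixture <- function(out, dims = c(16, 16, 16), n_segments = 2,
                              seed = 0) {
  stopifnot(n_segments >= 0)
  if (n_segments > prod(dims)) {
    stop("n_segments (", n_segments, ") exceeds voxel count (", prod(dims),
         ")", call. = FALSE)
  }
  arr <- array(0L, dim = dims)
  if (n_segments > 0L) {
    arr <- with_seed(seed, {
      slab <- dims[1] / n_segments
      g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                       z = seq_len(dims[3]))
      for (i in seq_len(n_segments)) {
        ctr <- c((i - 0.5) * slab + stats::runif(1, -slab / 8, slab / 8),
                 dims[2] / 2 + stats::runif(1, -dims[2] / 8, dims[2] / 8),
                 dims[3] / 2 + stats::runif(1, -dims[3] / 8, dims[3] / 8))
        rad <- max(1, min(slab, dims[2], dims[3]) / 3)
        r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
        arr[r2 <= rad^2] <- i
        arr[round(pmin(pmax(ctr[1], 1), dims[1])),
            round(pmin(pmax(ctr[2], 1), dims[2])),
            round(pmin(pmax(ctr[3], 1), dims[3]))] <- i
      }
      arr
    })
  }
  write_mrc(label_grid(arr), out, mode = 1L)
  invisible(out)
}

#' Generate a STAR particle-table fixture
#'
#' @param out Output `.star` path.
#' @param n_rows Number of particle rows.
#' @param coord_range Coordinate range (inclusive) for X/Y/Z.
#' @param multiple_of Coordinates are drawn as multiples of this value
#'   (default 4, so bin-4 divisor arithmetic stays exact).
#' @param seed RNG seed.
#' @return `out`, invisibly.
#' @export
make_star_fixture <- function(out, n_rows = 10, coord_range = c(0, 4000),
                              multiple_of = 4, seed = 0) {
  stopifnot(n_rows >= 0)
  coords <- with_seed(seed, {
    lo <- ceiling(coord_range[1] / multiple_of)
    hi <- floor(coord_range[2] / multiple_of)
    matrix(sample(lo:hi, 3 * n_rows, replace = TRUE) * multiple_of,
           ncol = 3)
  })
  lines <- c("", "data_particles", "", "loop_",
             "_rlnCoordinateX #1", "_rlnCoordinateY #2", "_rlnCoordinateZ #3",
             "_rlnMicrographName #4")
  if (n_rows > 0L) {
    lines <- c(lines, vapply(seq_len(n_rows), function(i) {
      sprintf("%10.1f %10.1f %10.1f tomo_649.mrc",
              coords[i, 1], coords[i, 2], coords[i, 3])
    }, character(1)))
  }
  writeLines(lines, out)
  invisible(out)
}

#' Generate a multiscale image fixture (OME-Zarr or OME-TIFF series)
#'
#' @param out Output directory (omezarr flavor: the `.zarr` group; ometiff
#'   flavor: the series directory).
#' @param shape Named or positional extents in axes order; e.g.
#'   `c(t = 3, c = 2, z = 8, y = 16, x = 16)` for axes `"tczyx"`.
#' @param axes Axis names, a subset of `"tczyx"` (omezarr only; the TIFF
#'   flavor always writes the full 5D series).
#' @param channel_labels Channel labels (e.g. `c("DAPI", "Hyb probe")`).
#' @param scale_xyz Physical voxel size along x, y, z in `unit`.
#' @param unit Spatial unit (`"micrometer"` for zarr, `"µm"` for TIFF).
#' @param flavor `"omezarr"` or `"ometiff-series"`.
#' @param n_labels Number of distinct nonzero labels in the labels subgroup
#'   (omezarr only; 0 = no labels subgroup).
#' @param seed RNG seed.
#' @return Path to the group (omezarr) or first series file (ometiff).
#' @export
make_multiscale_fixture <- function(out, shape, axes = "tczyx",
                                    channel_labels = NULL,
                                    scale_xyz = c(1, 1, 1),
                                    unit = "micrometer",
                                    flavor = c("omezarr", "ometiff-series"),
                                    n_labels = 0, seed = 0) {
  flavor <- match.arg(flavor)
  ax <- strsplit(axes, "")[[1L]]
  stopifnot(length(shape) == length(ax))
  ext <- function(a, default = 1L) {
    i <- match(a, ax)
    if (is.na(i)) default else as.integer(shape[i])
  }
  nt <- ext("t"); nc <- ext("c"); nz <- ext("z"); ny <- ext("y"); nx <- ext("x")
  data <- with_seed(seed, {
    array(stats::rnorm(prod(as.integer(shape))), dim = rev(as.integer(shape)))
  })
  if (flavor == "omezarr") {
    labels <- NULL
    if (n_labels > 0L) {
      lab_dims <- rev(as.integer(shape))[setdiff(seq_along(ax),
                                                 length(ax) - match("c", ax) + 1L)]
      lab <- array(0L, dim = lab_dims)
      lab_arr <- with_seed(seed + 1L, {
        idx <- expand.grid(x = seq_len(nx), y = seq_len(ny))
        for (i in seq_len(n_labels)) {
          ctr <- c(stats::runif(1, 1, nx), stats::runif(1, 1, ny))
          rad <- min(nx, ny) / (2 * n_labels)
          sel_xy <- matrix((idx$x - ctr[1])^2 + (idx$y - ctr[2])^2 <= rad^2,
                           nx, ny)
          sel_xy[ceiling(ctr[1]), ceiling(ctr[2])] <- TRUE  # guarantee presence
          sel <- array(rep(as.vector(sel_xy), length.out = prod(lab_dims)),
                       dim = lab_dims)
          lab[sel] <- i
        }
        lab
      })
      labels <- list(cells = lab_arr)
    }
    write_omezarr_group(out, data, axes = axes, scale_xyz = scale_xyz,
                        unit = unit, channel_labels = channel_labels,
                        labels = labels)
    return(invisible(out))
  }
  # ometiff-series: full 5D (x, y, z, c, t)
  d5 <- array(0, dim = c(nx, ny, nz, nc, nt))
  d5[] <- data  # rev-axis data fills x fastest in both layouts here
  if (is.null(channel_labels)) channel_labels <- as.character(seq_len(nc) - 1L)
  first <- write_ometiff_series(out, basename(out), d5, channel_labels,
                                physical_xyz = scale_xyz,
                                unit = if (identical(unit, "micrometer")) "µm" else unit)
  invisible(first)
}

#' Generate an EMDB-SFF fixture
#'
#' Writes an HDF5 segmentation file in the structure [read_sff()] consumes:
#' a lattice with `n_segments` labelled regions (and optionally one
#' tetrahedral mesh segment), each with a biological name and colour.
#'
#' @param out Output `.hff` path.
#' @param dims Lattice dims.
#' @param segment_names Names for the lattice segments (labels 1..n).
#' @param with_mesh Also include one mesh segment (4 vertices, 4 triangles).
#' @param seed RNG seed.
#' @return `out`, invisibly.
#' @export
make_sff_fixture <- function(out, dims = c(24, 24, 24),
                             segment_names = "CMG", with_mesh = FALSE,
                             seed = 0) {
  n <- length(segment_names)
  tmp_mask <- tempfile(fileext = ".map")
  on.exit(unlink(tmp_mask), add = TRUE)
  make_mask_fixture(tmp_mask, dims = dims, n_segments = n, seed = seed)
  lat <- read_mask(tmp_mask)$frames[["0"]][["1"]]$values
  segments <- lapply(seq_len(n), function(i) {
    list(id = i, name = segment_names[i],
         description = paste0(segment_names[i], " (synthetic)"),
         colour = palette_color(i), lattice_id = 0L, value = i)
  })
  mesh_segments <- list()
  if (with_mesh) {
    mesh_segments <- list(list(
      id = n + 1L, name = "envelope", colour = palette_color(n + 1L),
      vertices = matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 0, 0, 10),
                        ncol = 3, byrow = TRUE),
      triangles = matrix(c(1, 2, 3, 1, 2, 4, 1, 3, 4, 2, 3, 4),
                         ncol = 3, byrow = TRUE)))
  }
  write_sff_file(out, name = tools::file_path_sans_ext(basename(out)),
                 lattices = list(`0` = lat), segments = segments,
                 mesh_segments = mesh_segments)
  invisible(out)
}
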