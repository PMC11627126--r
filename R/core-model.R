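# Core domain types.
#
# Entries are built from four payload kinds: per-channel multiscale volumes,
# lattice segmentations (integer label grids), geometric segmentations
# (sphere primitives), and mesh segmentations (triangle meshes). Annotations
# and metadata are plain R lists mirroring their JSON documents so that the
# JSON-pointer editing operations can treat them uniformly.

#' Entry key
#'
#' Identifies an entry inside the internal database: a lowercase source
#' database token (e.g. `"emdb"`, `"idr"`, `"custom"`) plus an entry id.
#'
#' @param source_db Lowercase source database token.
#' @param entry_id Entry id, e.g. `"emd-1832"`.
#' @param source_db_id Id of the entry in the source database (defaults to
#'   `entry_id`).
#' @param source_db_name Display name of the source database (defaults to
#'   `source_db`).
#' @return An object of class `entry_key`.
#' @export
entry_key <- function(source_db, entry_id, source_db_id = entry_id,
                      source_db_name = source_db) {
  stopifnot(is.character(source_db), nzchar(source_db),
            is.character(entry_id), nzchar(entry_id))
  if (source_db != tolower(source_db)) {
    stop("source_db must be a lowercase token: ", source_db, call. = FALSE)
  }
  structure(list(source_db = source_db, entry_id = entry_id,
                 source_db_id = source_db_id,
                 source_db_name = source_db_name),
            class = "entry_key")
}

#' @export
format.entry_key <- function(x, ...) paste0(x$source_db, "/", x$entry_id)

#' @export
print.entry_key <- function(x, ...) {
  cat("<entry_key>", format(x), "\n")
  invisible(x)
}

grid_stats <- function(values) {
  v <- as.numeric(values)
  list(min = min(v), max = max(v), mean = mean(v), sd = stats::sd(v))
}

#' Scalar volume grid
#'
#' A 3D scalar lattice with voxel geometry in Angstrom. The in-memory axis
#' convention is `values[x, y, z]` with x fastest (R column-major order);
#' all readers permute into it.
#'
#' @param values 3D numeric array.
#' @param voxel_size Numeric length-3 voxel size (Angstrom). Components of 0
#'   mark an invalid header pending an extra-data override.
#' @param origin Numeric length-3 grid origin (Angstrom).
#' @return Object of class `volume_grid` with fields `values`, `dims`,
#'   `voxel_size`, `origin`, `voxel_size_valid`, `stats`.
#' @export
volume_grid <- function(values, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size >= 0),
            length(origin) == 3L)
  structure(list(values = values,
                 dims = dim(values),
                 voxel_size = voxel_size,
                 origin = as.numeric(origin),
                 voxel_size_valid = all(voxel_size > 0),
                 stats = grid_stats(values)),
            class = "volume_grid")
}

#' Integer label grid
#'
#' Like [volume_grid()] but holding non-negative integer labels; 0 is
#' background.
#'
#' @inheritParams volume_grid
#' @return Object of class `label_grid`.
#' @export
label_grid <- function(values, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array", call. = FALSE)
  iv <- as.integer(round(values))
  if (max(abs(as.numeric(values) - iv)) > 1e-6) {
    stop("label grid holds non-integral values", call. = FALSE)
  }
  if (any(iv < 0L)) stop("label grid holds negative labels", call. = FALSE)
  arr <- array(iv, dim = dim(values))
  structure(list(values = arr,
                 dims = dim(arr),
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin),
                 voxel_size_valid = all(voxel_size > 0)),
            class = "label_grid")
}

#' Distinct nonzero labels of a label grid
#' @param grid A `label_grid`.
#' @return Sorted integer vector of segment ids.
#' @export
segment_ids <- function(grid) {
  u <- sort(unique(as.integer(grid$values)))
  u[u != 0L]
}

#' Multiscale volume for one channel
#'
#' @param channel_id Channel id (always a string, even when numeric).
#' @param frames Named list: time index (as character, 0-based) to pyramid;
#'   each pyramid is a named list level factor (as character) to
#'   [volume_grid()]. Factor 1 must be present.
#' @return Object of class `multiscale_volume`.
#' @export
multiscale_volume <- function(channel_id, frames) {
  stopifnot(is.character(channel_id), length(frames) >= 1L)
  factors <- lapply(frames, names)
  if (!all(vapply(factors, identical, logical(1), factors[[1]]))) {
    stop("level factors differ across time frames", call. = FALSE)
  }
  if (!"1" %in% factors[[1]]) stop("factor 1 missing from pyramid", call. = FALSE)
  structure(list(channel_id = channel_id, frames = frames),
            class = "multiscale_volume")
}

#' Lattice segmentation
#'
#' @param segmentation_id Segmentation id.
#' @param frames Named list time -> (named list factor -> [label_grid()]).
#' @return Object of class `lattice_segmentation` with `segment_ids` equal to
#'   the union of nonzero labels at factor 1.
#' @export
lattice_segmentation <- function(segmentation_id, frames) {
  stopifnot(is.character(segmentation_id), length(frames) >= 1L)
  ids <- sort(unique(unlist(lapply(frames, function(pyr) segment_ids(pyr[["1"]])))))
  structure(list(segmentation_id = segmentation_id, frames = frames,
                 segment_ids = as.integer(ids)),
            class = "lattice_segmentation")
}

#' Sphere primitive
#'
#' @param id Integer sphere id (unique within a frame).
#' @param center Numeric length-3 centre in Angstrom.
#' @param radius Radius in Angstrom, > 0.
#' @param color RGBA, components in `[0, 1]`.
#' @return Object of class `sphere_primitive`.
#' @export
sphere_primitive <- function(id, center, radius, color) {
  stopifnot(length(center) == 3L, radius > 0, length(color) == 4L,
            all(color >= 0 & color <= 1))
  structure(list(id = as.integer(id), center = as.numeric(center),
                 radius = as.numeric(radius), color = as.numeric(color)),
            class = "sphere_primitive")
}

#' Geometric segmentation (sphere primitives per time frame)
#'
#' @param segmentation_id Segmentation id.
#' @param frames Named list time -> list of [sphere_primitive()].
#' @return Object of class `geometric_segmentation`.
#' @export
geometric_segmentation <- function(segmentation_id, frames) {
  for (tf in names(frames)) {
    ids <- vapply(frames[[tf]], function(s) s$id, integer(1))
    if (anyDuplicated(ids)) {
      stop("duplicate sphere ids in time frame ", tf, call. = FALSE)
    }
  }
  structure(list(segmentation_id = segmentation_id, frames = frames),
            class = "geometric_segmentation")
}

#' Mesh segmentation
#'
#' @param segmentation_id Segmentation id.
#' @param segments Named list segment id -> list(vertices = n x 3 matrix
#'   (Angstrom), triangles = m x 3 integer matrix of 1-based vertex indices).
#' @return Object of class `mesh_segmentation`.
#' @export
mesh_segmentation <- function(segmentation_id, segments) {
  for (sid in names(segments)) {
    seg <- segments[[sid]]
    stopifnot(ncol(seg$vertices) == 3L, ncol(seg$triangles) == 3L)
    if (nrow(seg$triangles) > 0 && max(seg$triangles) > nrow(seg$vertices)) {
      stop("triangle index exceeds vertex count in segment ", sid, call. = FALSE)
    }
  }
  structure(list(segmentation_id = segmentation_id, segments = segments),
            class = "mesh_segmentation")
}

#' STAR parsing configuration
#'
#' Controls conversion of particle tables into sphere primitives: the sphere
#' centre in Angstrom is `(coordinate / star_file_coordinate_divisor) *
#' pixel_size`, componentwise.
#'
#' @param sphere_radius Sphere radius in Angstrom, > 0.
#' @param segmentation_id Id for the resulting geometric segmentation.
#' @param sphere_color_hex 6-hex-digit colour string.
#' @param pixel_size Pixel size in Angstrom applied to scaled coordinates.
#' @param star_file_coordinate_divisor Positive divisor applied to raw
#'   coordinates (e.g. 4 for bin-1 coordinates against a bin-4 map).
#' @return Object of class `star_parse_config`.
#' @export
star_parse_config <- function(sphere_radius, segmentation_id,
                              sphere_color_hex, pixel_size,
                              star_file_coordinate_divisor = 1) {
  stopifnot(sphere_radius > 0, star_file_coordinate_divisor > 0,
            pixel_size > 0)
  color <- hex_to_rgba(sphere_color_hex)  # validates the hex string
  structure(list(sphere_radius = as.numeric(sphere_radius),
                 segmentation_id = segmentation_id,
                 sphere_color_hex = sub("^#", "", sphere_color_hex),
                 color = color,
                 pixel_size = as.numeric(pixel_size),
                 star_file_coordinate_divisor =
                   as.numeric(star_file_coordinate_divisor)),
            class = "star_parse_config")
}

#' Server settings
#'
#' @param host Bind address, default `"0.0.0.0"`.
#' @param port TCP port, default 9000.
#' @param db_path Path to the internal database, default
#'   `"preprocessor/temp/test_db"`.
#' @return Object of class `server_settings`.
#' @export
server_settings <- function(host = "0.0.0.0", port = 9000,
                            db_path = "preprocessor/temp/test_db") {
  port <- as.integer(port)
  stopifnot(port >= 1L, port <= 65535L)
  structure(list(host = host, port = port, db_path = db_path),
            class = "server_settings")
}

# ---------------------------------------------------------------------------
# Annotation document construction

#' Create a description record
#'
#' @param id Description id (deterministic, e.g. `"desc-<segmentation>-<segment>"`).
#' @param target_kind One of `"lattice"`, `"mesh"`, `"primitive"`, `"entry"`.
#' @param segmentation_id,segment_id Target; both `NULL` for entry-wide
#'   descriptions, `segment_id` may be `NULL` for segmentation-wide ones.
#' @param name Display name or `NULL`.
#' @param details `NULL`, a plain string, or `list(format = "text"|"markdown",
#'   text = ...)`.
#' @param external_references List of reference records
#'   (`resource`/`accession`/`label`/`description`).
#' @param is_hidden Logical.
#' @param time Time index or `NULL`.
#' @return Plain list suitable for inclusion in an annotations document.
#' @export
description_record <- function(id, target_kind, segmentation_id = NULL,
                               segment_id = NULL, name = NULL, details = NULL,
                               external_references = list(),
                               is_hidden = FALSE, time = NULL) {
  target <- NULL
  if (!identical(target_kind, "entry")) {
    target <- list(segmentation_id = segmentation_id)
    if (!is.null(segment_id)) target$segment_id <- as.integer(segment_id)
  }
  rec <- list(id = id, target_kind = target_kind)
  if (!is.null(target)) rec$target <- target
  # keep name/details present (as JSON null) even when unset, so pointer
  # edits can retype them in place
  rec["name"] <- list(name)
  rec["details"] <- list(details)
  rec$external_references <- external_references
  rec$is_hidden <- is_hidden
  if (!is.null(time)) rec$time <- as.integer(time)
  rec
}

#' Create a segment annotation record
#'
#' @param segment_kind One of `"lattice"`, `"mesh"`, `"primitive"`.
#' @param segmentation_id,segment_id Target segment.
#' @param color RGBA in `[0, 1]`.
#' @param time Time index or `NULL`.
#' @return Plain list.
#' @export
segment_annotation_record <- function(segment_kind, segmentation_id,
                                      segment_id, color, time = NULL) {
  rec <- list(id = paste0("sa-", segmentation_id, "-", segment_id),
              segment_kind = segment_kind,
              segmentation_id = segmentation_id,
              segment_id = as.integer(segment_id),
              color = as.numeric(color))
  if (!is.null(time)) rec$time <- as.integer(time)
  rec
}

#' Create an empty annotations document for an entry
#'
#' @param key An [entry_key()].
#' @param name Entry display name or `NULL`.
#' @return Annotations document (plain list) with empty `descriptions` and
#'   `segment_annotations`.
#' @export
empty_annotations <- function(key, name = NULL) {
  list(entry_id = list(source_db_name = key$source_db_name,
                       source_db_id = key$source_db_id),
       name = name,
       descriptions = structure(list(), names = character()),
       segment_annotations = list(),
       volume_channels_annotations = list())
}
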