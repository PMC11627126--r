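# Query resolution, downsampling-level selection, CVSX packing and reading.
#
# A CVSX archive is a plain ZIP (mandatory .cvsx extension) holding
# index.json (contents inventory), query.json (the resolved selection plus
# the raw request), annotations.json and metadata.json (both filtered to
# the selection), and exactly the selected payload members at the selected
# downsampling level. Payload encoding mirrors the database store: MRC
# grids, JSON geometric/mesh segmentations.

#' Resolve a query against an entry's metadata
#'
#' Absent optional fields expand to the entry's full inventory; a given
#' `time` restricts volumes and segmentations to that frame; `max_points`
#' defaults to 1000000000000.
#'
#' @param raw Query document (plain list with at least `entry_id` and
#'   `source_db`).
#' @param metadata Entry metadata document.
#' @return Resolved selection: channels, volume time frames, per-kind
#'   segmentation selections, and `max_points`.
#' @export
resolve_query <- function(raw, metadata) {
  q <- apply_query_defaults(raw)
  inv_channels <- vapply(metadata$volumes$channel_ids %||% list(),
                         json_scalar, character(1))
  inv_times <- vapply(metadata$volumes$time_frame_indices %||% list(),
                      function(x) as.integer(json_scalar(x)), integer(1))

  channels <- inv_channels
  if (!is.null(q$channel_id)) {
    if (!q$channel_id %in% inv_channels) {
      stop("channel_id not found: ", q$channel_id, " (available: ",
           paste(inv_channels, collapse = ", "), ")", call. = FALSE)
    }
    channels <- q$channel_id
  }
  vol_times <- inv_times
  if (!is.null(q$time)) {
    seg_times_all <- unlist(lapply(
      c(metadata$segmentations$lattice, metadata$segmentations$geometric),
      function(s) vapply(s$time_frame_indices, function(x)
        as.integer(json_scalar(x)), integer(1))))
    valid_times <- sort(unique(c(inv_times, seg_times_all)))
    if (!q$time %in% valid_times) {
      stop("time frame not found: ", q$time, " (available: ",
           paste(valid_times, collapse = ", "), ")", call. = FALSE)
    }
    vol_times <- intersect(inv_times, q$time)
  }

  pick_segs <- function(kind) {
    inv <- metadata$segmentations[[kind]] %||% list()
    out <- list()
    for (s in inv) {
      sid <- json_scalar(s$segmentation_id)
      if (!is.null(q$segmentation_id) && sid != q$segmentation_id) next
      times <- if (kind == "mesh") NULL else
        vapply(s$time_frame_indices, function(x) as.integer(json_scalar(x)),
               integer(1))
      if (!is.null(q$time) && !is.null(times)) {
        times <- intersect(times, q$time)
        if (length(times) == 0L) next
      }
      rec <- list(kind = kind, segmentation_id = sid)
      if (!is.null(times)) rec$time_frame_indices <- as.list(times)
      if (!is.null(s$segment_ids)) rec$segment_ids <- s$segment_ids
      out[[length(out) + 1L]] <- rec
    }
    out
  }
  kinds <- c(lattice = "lattice", mesh = "mesh",
             `geometric-segmentation` = "geometric")
  wanted <- if (is.null(q$segmentation_kind)) unname(kinds) else
    unname(kinds[q$segmentation_kind])
  segmentations <- list()
  for (k in wanted) segmentations <- c(segmentations, pick_segs(k))
  if (!is.null(q$segmentation_id) && length(segmentations) == 0L) {
    all_ids <- unlist(lapply(unname(kinds), function(k) {
      vapply(metadata$segmentations[[k]] %||% list(), function(s)
        json_scalar(s$segmentation_id), character(1))
    }))
    stop("segmentation_id not found: ", q$segmentation_id, " (available: ",
         paste(all_ids, collapse = ", "), ")", call. = FALSE)
  }

  list(entry_id = q$entry_id, source_db = q$source_db,
       channel_ids = as.list(channels),
       volume_time_frames = as.list(as.integer(vol_times)),
       segmentations = segmentations,
       max_points = q$max_points)
}

#' Select the most suitable downsampling level
#'
#' Returns the smallest level factor (finest level) whose voxel count per
#' frame does not exceed `max_points`; when no level qualifies, the
#' coarsest available level.
#'
#' @param sampling_info Named list factor -> list(dims = ...), as stored in
#'   entry metadata.
#' @param max_points Point budget.
#' @return Integer level factor.
#' @export
select_sampling_level <- function(sampling_info, max_points) {
  factors <- sort(as.integer(names(sampling_info)))
  counts <- vapply(factors, function(f) {
    prod(json_num_vec(sampling_info[[as.character(f)]]$dims))
  }, numeric(1))
  ok <- factors[counts <= max_points]
  if (length(ok) > 0L) min(ok) else max(factors)
}

payload_member <- function(role, ...) file.path(role, ...)

#' Build a CVSX archive from a database entry
#'
#' @param db_root Database root.
#' @param query Query document (plain list) or path to a query JSON file.
#' @param out Output path; the `.cvsx` extension is mandatory.
#' @return The archive path, invisibly; the archive holds index.json,
#'   query.json, annotations.json, metadata.json and the selected payloads.
#' @export
build_cvsx <- function(db_root, query, out) {
  if (!grepl("\\.cvsx$", out)) {
    stop("output file name must carry the mandatory .cvsx extension: ", out,
         call. = FALSE)
  }
  raw <- if (is.character(query)) read_json_doc(query) else query
  q0 <- apply_query_defaults(raw)
  key <- entry_key(q0$source_db, q0$entry_id)
  if (!entry_exists(db_root, key)) {
    stop("entry not found: ", format(key), " in ", db_root, call. = FALSE)
  }
  metadata <- read_entry_metadata(db_root, key)
  annotations <- read_entry_annotations(db_root, key)
  sel <- resolve_query(raw, metadata)

  stage <- tempfile("cvsx-build-")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  index <- list()
  add_index <- function(path, role, ...) {
    rec <- c(list(path = path, role = role), list(...))
    index[[length(index) + 1L]] <<- rec
  }

  # volumes at the level chosen by the point budget
  vol_factor <- NULL
  if (length(sel$channel_ids) > 0L && length(sel$volume_time_frames) > 0L) {
    vol_factor <- select_sampling_level(metadata$volumes$sampling_info,
                                        sel$max_points)
    for (ch in sel$channel_ids) {
      for (tf in sel$volume_time_frames) {
        member <- payload_member("volume", ch, tf, paste0(vol_factor, ".map"))
        extract_entry_payload(db_root, key, member, stage)
        add_index(member, "volume", channel_id = ch, time = tf,
                  level_factor = vol_factor, format = "mrc")
      }
    }
  }

  lat_factors <- list()
  for (s in sel$segmentations) {
    if (s$kind == "lattice") {
      inv <- Filter(function(x) json_scalar(x$segmentation_id) ==
                      s$segmentation_id, metadata$segmentations$lattice)[[1L]]
      fac <- select_sampling_level(inv$sampling_info, sel$max_points)
      lat_factors[[s$segmentation_id]] <- fac
      for (tf in s$time_frame_indices) {
        member <- payload_member("lattice", s$segmentation_id, tf,
                                 paste0(fac, ".map"))
        extract_entry_payload(db_root, key, member, stage)
        add_index(member, "lattice", segmentation_id = s$segmentation_id,
                  time = tf, level_factor = fac, format = "mrc")
      }
    } else if (s$kind == "geometric") {
      member <- payload_member("geometric", paste0(s$segmentation_id, ".json"))
      p <- extract_entry_payload(db_root, key, member, stage)
      doc <- read_json_doc(p)
      keep <- as.character(unlist(s$time_frame_indices))
      doc$time_frames <- doc$time_frames[intersect(names(doc$time_frames), keep)]
      write_canonical_json(doc, p)
      add_index(member, "geometric", segmentation_id = s$segmentation_id,
                format = "json")
    } else {
      member <- payload_member("mesh", paste0(s$segmentation_id, ".json"))
      extract_entry_payload(db_root, key, member, stage)
      add_index(member, "mesh", segmentation_id = s$segmentation_id,
                format = "json")
    }
  }

  sel_seg_ids <- vapply(sel$segmentations, function(s) s$segmentation_id,
                        character(1))

  # annotations filtered to the selection
  ann <- annotations
  keep_desc <- vapply(ann$descriptions, function(d) {
    tk <- json_scalar(d$target_kind)
    if (identical(tk, "entry")) return(TRUE)
    sid <- json_scalar(d$target$segmentation_id)
    is.null(sid) || sid %in% sel_seg_ids
  }, logical(1))
  ann$descriptions <- ann$descriptions[keep_desc]
  ann$segment_annotations <- Filter(function(sa) {
    json_scalar(sa$segmentation_id) %in% sel_seg_ids
  }, ann$segment_annotations)
  sel_ch <- as.character(unlist(sel$channel_ids))
  if (!is.null(ann$volume_channels_annotations)) {
    ann$volume_channels_annotations <- Filter(function(ca) {
      json_scalar(ca$channel_id) %in% sel_ch
    }, ann$volume_channels_annotations)
  }

  # metadata filtered to the selection
  md <- metadata
  if (!is.null(md$volumes)) {
    md$volumes$channel_ids <- sel$channel_ids
    md$volumes$time_frame_indices <- sel$volume_time_frames
    if (!is.null(vol_factor)) {
      md$volumes$sampling_info <-
        md$volumes$sampling_info[as.character(vol_factor)]
      md$volumes$value_stats <- lapply(
        md$volumes$value_stats[sel_ch],
        function(s) s[as.character(vol_factor)])
    }
  }
  md$segmentations$lattice <- Filter(function(s)
    json_scalar(s$segmentation_id) %in% sel_seg_ids,
    md$segmentations$lattice %||% list())
  md$segmentations$lattice <- lapply(md$segmentations$lattice, function(s) {
    fac <- lat_factors[[json_scalar(s$segmentation_id)]]
    s$sampling_info <- s$sampling_info[as.character(fac)]
    sel_s <- Filter(function(x) x$segmentation_id ==
                      json_scalar(s$segmentation_id), sel$segmentations)[[1L]]
    s$time_frame_indices <- sel_s$time_frame_indices
    s
  })
  md$segmentations$geometric <- Filter(function(s)
    json_scalar(s$segmentation_id) %in% sel_seg_ids,
    md$segmentations$geometric %||% list())
  md$segmentations$mesh <- Filter(function(s)
    json_scalar(s$segmentation_id) %in% sel_seg_ids,
    md$segmentations$mesh %||% list())

  query_doc <- c(sel, list(requested = raw))
  write_canonical_json(query_doc, file.path(stage, "query.json"))
  write_canonical_json(ann, file.path(stage, "annotations.json"))
  write_canonical_json(md, file.path(stage, "metadata.json"))
  add_index("query.json", "query", format = "json")
  add_index("annotations.json", "annotations", format = "json")
  add_index("metadata.json", "metadata", format = "json")
  write_canonical_json(index, file.path(stage, "index.json"))

  members <- sort(list.files(stage, recursive = TRUE))
  out_abs <- normalizePath(out, mustWork = FALSE)
  zip::zip(out_abs, members, root = stage, compression_level = 6,
           mode = "mirror")
  invisible(out)
}

#' Read and validate a CVSX archive
#'
#' Validates that the four JSON members are present and that index.json
#' describes exactly the archive's members, then reconstructs every packed
#' payload.
#'
#' @param path Path to a `.cvsx` file.
#' @return List with `query`, `annotations`, `metadata`, `index`,
#'   `volumes`, `lattices`, `geoms`, `meshes`. Volume and lattice payloads
#'   are keyed by `channel/time` and `segmentation/time` with their level
#'   factor.
#' @export
read_cvsx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  listing <- zip::zip_list(path)$filename
  for (m in c("index.json", "query.json", "annotations.json", "metadata.json")) {
    if (!m %in% listing) {
      stop("CVSX validation error: missing member ", m, call. = FALSE)
    }
  }
  ex <- tempfile("cvsx-read-")
  dir.create(ex)
  on.exit(unlink(ex, recursive = TRUE), add = TRUE)
  zip::unzip(path, exdir = ex)
  index <- read_json_doc(file.path(ex, "index.json"))
  described <- vapply(index, function(r) json_scalar(r$path), character(1))
  if (anyDuplicated(described)) {
    stop("CVSX validation error: member described more than once: ",
         described[duplicated(described)][1L], call. = FALSE)
  }
  actual <- setdiff(listing, "index.json")
  missing_in_zip <- setdiff(described, listing)
  if (length(missing_in_zip) > 0L) {
    stop("CVSX validation error: index lists member absent from archive: ",
         missing_in_zip[1L], call. = FALSE)
  }
  undescribed <- setdiff(actual, described)
  if (length(undescribed) > 0L) {
    stop("CVSX validation error: archive member not described by index: ",
         undescribed[1L], call. = FALSE)
  }

  out <- list(query = read_json_doc(file.path(ex, "query.json")),
              annotations = read_json_doc(file.path(ex, "annotations.json")),
              metadata = read_json_doc(file.path(ex, "metadata.json")),
              index = index,
              volumes = list(), lattices = list(), geoms = list(),
              meshes = list())
  for (r in index) {
    role <- json_scalar(r$role)
    p <- file.path(ex, json_scalar(r$path))
    if (role == "volume") {
      keyname <- paste(json_scalar(r$channel_id), json_scalar(r$time), sep = "/")
      out$volumes[[keyname]] <- list(grid = read_map(p),
                                     level_factor = json_scalar(r$level_factor))
    } else if (role == "lattice") {
      keyname <- paste(json_scalar(r$segmentation_id), json_scalar(r$time),
                       sep = "/")
      g <- read_map(p)
      out$lattices[[keyname]] <- list(
        grid = label_grid(g$values, voxel_size = g$voxel_size,
                          origin = g$origin),
        level_factor = json_scalar(r$level_factor))
    } else if (role == "geometric") {
      out$geoms[[json_scalar(r$segmentation_id)]] <-
        read_geometric_segmentation(p)
    } else if (role == "mesh") {
      out$meshes[[json_scalar(r$segmentation_id)]] <-
        doc_to_mesh(read_json_doc(p))
    }
  }
  out
}
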