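# Structural validation for the annotations and extra-data documents.
#
# The validators implement the documents' data models directly (required
# fields, enums, arities, uniqueness) and return one character violation per
# broken rule, each prefixed with a JSON-pointer-style path to the offending
# node. An empty result means the document is valid.

is_json_object <- function(x) {
  is.list(x) && (length(x) == 0L || !is.null(names(x)))
}

is_json_array <- function(x) is.list(x) && is.null(names(x))

is_scalar_string <- function(x) {
  x <- json_scalar(x)
  is.character(x) && length(x) == 1L
}

is_scalar_int <- function(x) {
  x <- json_scalar(x)
  is.numeric(x) && length(x) == 1L && x == round(x)
}

is_scalar_bool <- function(x) {
  x <- json_scalar(x)
  is.logical(x) && length(x) == 1L
}

check_color <- function(x, path, violations) {
  v <- tryCatch(json_num_vec(x), error = function(e) NULL)
  if (is.null(v) || length(v) != 4L || anyNA(v)) {
    return(c(violations, paste0(path, ": color must be 4 numeric RGBA components")))
  }
  if (any(v < 0 | v > 1)) {
    return(c(violations, paste0(path, ": color components must lie in [0, 1]")))
  }
  violations
}

.description_target_kinds <- c("lattice", "mesh", "primitive", "entry")
.segment_kinds <- c("lattice", "mesh", "primitive")

validate_description <- function(d, path) {
  v <- character()
  if (!is_json_object(d)) {
    return(paste0(path, ": description must be an object"))
  }
  if (is.null(d$id) || !is_scalar_string(d$id)) {
    v <- c(v, paste0(path, "/id: required string"))
  }
  tk <- json_scalar(d$target_kind)
  if (is.null(tk) || !is_scalar_string(d$target_kind) ||
      !(tk %in% .description_target_kinds)) {
    v <- c(v, paste0(path, "/target_kind: must be one of ",
                     paste(.description_target_kinds, collapse = ", ")))
  } else if (tk != "entry") {
    if (is.null(d$target) || !is_json_object(d$target) ||
        is.null(d$target$segmentation_id)) {
      v <- c(v, paste0(path, "/target: required (with segmentation_id) unless target_kind is \"entry\""))
    }
  }
  if (!is.null(d$name) && !is_scalar_string(d$name)) {
    v <- c(v, paste0(path, "/name: must be a string when present"))
  }
  det <- d$details
  if (!is.null(det)) {
    if (is_json_object(det)) {
      fmt <- json_scalar(det$format)
      if (is.null(det$format) || is.null(det$text) ||
          !fmt %in% c("text", "markdown")) {
        v <- c(v, paste0(path, "/details: object form requires both format (\"text\"|\"markdown\") and text"))
      }
    } else if (!is_scalar_string(det)) {
      v <- c(v, paste0(path, "/details: must be null, a string, or {format, text}"))
    }
  }
  if (!is.null(d$external_references)) {
    if (!is_json_array(d$external_references)) {
      v <- c(v, paste0(path, "/external_references: must be a list"))
    } else {
      for (i in seq_along(d$external_references)) {
        r <- d$external_references[[i]]
        if (!is_json_object(r) || is.null(r$resource) || is.null(r$accession)) {
          v <- c(v, paste0(path, "/external_references/", i - 1L,
                           ": requires resource and accession"))
        }
      }
    }
  }
  if (!is.null(d$is_hidden) && !is_scalar_bool(d$is_hidden)) {
    v <- c(v, paste0(path, "/is_hidden: must be boolean"))
  }
  if (!is.null(d$time) && !is_scalar_int(d$time)) {
    v <- c(v, paste0(path, "/time: must be an integer"))
  }
  v
}

#' Validate an entry annotations document
#'
#' Checks a parsed annotations document against the entry-annotations data
#' model: entry identity, description records (target kind and target,
#' optional markdown details object, external references), segment
#' annotations (kind, target, RGBA colour, uniqueness), and optional volume
#' channel annotations.
#'
#' @param doc Parsed document (plain R list, as returned by
#'   [jsonlite::read_json()] with `simplifyVector = FALSE`).
#' @return Character vector of violations; empty when the document is valid.
#'   Each violation names the offending path and rule.
#' @export
validate_annotations <- function(doc) {
  if (!is.list(doc)) return("/: document must be a JSON object")
  if (is_json_array(doc) && length(doc) > 0L) {
    return("/: document must be a JSON object, not an array")
  }
  v <- character()
  eid <- doc$entry_id
  if (is.null(eid)) {
    v <- c(v, "/entry_id: required")
  } else if (!is_json_object(eid) || is.null(eid$source_db_name) ||
             is.null(eid$source_db_id)) {
    v <- c(v, "/entry_id: must be an object with source_db_name and source_db_id")
  }
  if (!is.null(doc$name) && !is_scalar_string(doc$name)) {
    v <- c(v, "/name: must be a string when present")
  }
  descs <- doc$descriptions
  if (!is.null(descs)) {
    if (!is_json_object(descs)) {
      v <- c(v, "/descriptions: must be an object keyed by description id")
    } else {
      if (anyDuplicated(names(descs))) {
        v <- c(v, "/descriptions: description ids must be unique")
      }
      for (id in names(descs)) {
        path <- paste0("/descriptions/", id)
        v <- c(v, validate_description(descs[[id]], path))
        did <- json_scalar(descs[[id]]$id)
        if (!is.null(did) && is.character(did) && !identical(did, id)) {
          v <- c(v, paste0(path, "/id: must equal its key (", id, ")"))
        }
      }
    }
  }
  sas <- doc$segment_annotations
  if (!is.null(sas)) {
    if (!is_json_array(sas)) {
      v <- c(v, "/segment_annotations: must be a list")
    } else {
      seen <- character()
      for (i in seq_along(sas)) {
        sa <- sas[[i]]
        path <- paste0("/segment_annotations/", i - 1L)
        if (!is_json_object(sa)) {
          v <- c(v, paste0(path, ": must be an object"))
          next
        }
        sk <- json_scalar(sa$segment_kind)
        if (is.null(sk) || !sk %in% .segment_kinds) {
          v <- c(v, paste0(path, "/segment_kind: must be one of ",
                           paste(.segment_kinds, collapse = ", ")))
        }
        if (is.null(sa$segmentation_id) || !is_scalar_string(sa$segmentation_id)) {
          v <- c(v, paste0(path, "/segmentation_id: required string"))
        }
        if (is.null(sa$segment_id) || !is_scalar_int(sa$segment_id)) {
          v <- c(v, paste0(path, "/segment_id: required integer"))
        }
        if (is.null(sa$color)) {
          v <- c(v, paste0(path, "/color: required"))
        } else {
          v <- check_color(sa$color, paste0(path, "/color"), v)
        }
        if (!is.null(sa$time) && !is_scalar_int(sa$time)) {
          v <- c(v, paste0(path, "/time: must be an integer"))
        }
        sig <- paste(json_scalar(sa$segment_kind), json_scalar(sa$segmentation_id),
                     json_scalar(sa$segment_id), json_scalar(sa$time) %||% "NA",
                     sep = "\r")
        if (sig %in% seen) {
          v <- c(v, paste0(path, ": duplicate (segment_kind, segmentation_id, segment_id, time)"))
        }
        seen <- c(seen, sig)
      }
    }
  }
  vca <- doc$volume_channels_annotations
  if (!is.null(vca)) {
    if (!is_json_array(vca)) {
      v <- c(v, "/volume_channels_annotations: must be a list")
    } else {
      for (i in seq_along(vca)) {
        ch <- vca[[i]]
        path <- paste0("/volume_channels_annotations/", i - 1L)
        if (!is_json_object(ch) || is.null(ch$channel_id)) {
          v <- c(v, paste0(path, ": requires channel_id"))
        } else if (!is.null(ch$color)) {
          v <- check_color(ch$color, paste0(path, "/color"), v)
        }
      }
    }
  }
  v
}

#' Validate an extra-data document
#'
#' Extra data supplements or overrides entry parameters during
#' preprocessing. All fields are optional; when present, `volume$voxel_size`
#' must be three positive numbers (Angstrom) and
#' `segmentation$custom_segment_ids_mapping` must map segmentation ids to
#' label-string -> name objects.
#'
#' @param doc Parsed document (plain R list).
#' @return Character vector of violations; empty when valid.
#' @export
validate_extra_data <- function(doc) {
  if (!is.list(doc)) return("/: document must be a JSON object")
  if (is_json_array(doc) && length(doc) > 0L) {
    return("/: document must be a JSON object, not an array")
  }
  v <- character()
  vol <- doc$volume
  if (!is.null(vol)) {
    if (!is_json_object(vol)) {
      v <- c(v, "/volume: must be an object")
    } else if (!is.null(vol$voxel_size)) {
      vs <- tryCatch(json_num_vec(vol$voxel_size), error = function(e) NULL)
      if (is.null(vs) || length(vs) != 3L || anyNA(vs)) {
        v <- c(v, "/volume/voxel_size: must have 3 numeric components")
      } else if (any(vs <= 0)) {
        v <- c(v, "/volume/voxel_size: components must be > 0")
      }
    }
  }
  seg <- doc$segmentation
  if (!is.null(seg)) {
    if (!is_json_object(seg)) {
      v <- c(v, "/segmentation: must be an object")
    } else if (!is.null(seg$custom_segment_ids_mapping)) {
      m <- seg$custom_segment_ids_mapping
      if (!is_json_object(m)) {
        v <- c(v, "/segmentation/custom_segment_ids_mapping: must be an object keyed by segmentation id")
      } else {
        for (sid in names(m)) {
          mm <- m[[sid]]
          path <- paste0("/segmentation/custom_segment_ids_mapping/", sid)
          if (!is_json_object(mm)) {
            v <- c(v, paste0(path, ": must map label strings to names"))
            next
          }
          bad <- names(mm)[!grepl("^[0-9]+$", names(mm))]
          for (b in bad) {
            v <- c(v, paste0(path, "/", b, ": key must be a label string (digits)"))
          }
        }
      }
    }
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply query-parameter defaults
#'
#' Fills in the documented defaults for absent optional query fields:
#' `max_points` becomes 1000000000000; absent `segmentation_kind`, `time`,
#' `channel_id` and `segmentation_id` stay unset, meaning "all available".
#' Resolution is idempotent.
#'
#' @param raw Query document as a plain list; must contain `entry_id` and
#'   `source_db`.
#' @return The query with defaults applied, class `query_params`.
#' @export
apply_query_defaults <- function(raw) {
  if (inherits(raw, "query_params")) raw <- unclass(raw)
  if (!is.list(raw)) stop("query must be a JSON object", call. = FALSE)
  for (f in c("entry_id", "source_db")) {
    if (is.null(raw[[f]]) || !nzchar(json_scalar(raw[[f]]))) {
      stop("mandatory query parameter missing: ", f, call. = FALSE)
    }
  }
  q <- list(entry_id = json_scalar(raw$entry_id),
            source_db = json_scalar(raw$source_db))
  if (!is.null(raw$segmentation_kind)) {
    sk <- json_scalar(raw$segmentation_kind)
    if (!sk %in% c("mesh", "lattice", "geometric-segmentation")) {
      stop("segmentation_kind must be one of mesh, lattice, geometric-segmentation",
           call. = FALSE)
    }
    q$segmentation_kind <- sk
  }
  if (!is.null(raw$time)) q$time <- as.integer(json_scalar(raw$time))
  if (!is.null(raw$channel_id)) q$channel_id <- as.character(json_scalar(raw$channel_id))
  if (!is.null(raw$segmentation_id)) q$segmentation_id <- as.character(json_scalar(raw$segmentation_id))
  q$max_points <- if (is.null(raw$max_points)) 1e12 else as.numeric(json_scalar(raw$max_points))
  structure(q, class = "query_params")
}
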