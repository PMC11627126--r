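# RELION-style STAR particle tables.
#
# Only the subset needed for particle positions is supported: the first
# data_ block containing a loop_ with _rlnCoordinateX/Y/Z columns (any
# leading prefix before "rlnCoordinate" is accepted). Rows are whitespace
# separated.

#' Read a STAR particle table
#'
#' @param path Path to a `.star` file.
#' @return A `data.frame` with one column per loop label (label names keep
#'   their leading underscore stripped).
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0L) {
    stop("format error in ", path, ": no loop_ block found", call. = FALSE)
  }
  i <- loop_at[1L] + 1L
  labels <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    lab <- sub("^_", "", strsplit(lines[i], "[[:space:]]+")[[1]][1])
    labels <- c(labels, lab)
    i <- i + 1L
  }
  if (length(labels) == 0L) {
    stop("format error in ", path, ": loop_ block has no column labels",
         call. = FALSE)
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (startsWith(ln, "data_") || ln == "loop_") break
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(fields) != length(labels)) {
      stop("format error in ", path, ": row ", length(rows) + 1L, " has ",
           length(fields), " fields, expected ", length(labels), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- fields
    i <- i + 1L
  }
  if (length(rows) == 0L) {
    df <- as.data.frame(matrix(character(), nrow = 0, ncol = length(labels)),
                        stringsAsFactors = FALSE)
    names(df) <- labels
    return(df)
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- labels
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  df
}

star_coordinate_column <- function(df, axis) {
  hit <- grep(paste0("rlnCoordinate", axis, "$"), names(df))
  if (length(hit) != 1L) {
    stop("format error: missing coordinate column rlnCoordinate", axis,
         call. = FALSE)
  }
  as.numeric(df[[hit]])
}

#' Convert a STAR particle table to a geometric-segmentation input document
#'
#' One sphere per particle row. The centre in Angstrom is
#' `(coordinate / star_file_coordinate_divisor) * pixel_size`,
#' componentwise; all spheres share the configured radius and colour
#' (hex colour, alpha 1).
#'
#' @param star_path Path to the `.star` file.
#' @param config A [star_parse_config()].
#' @param out_path Optional path; when given, the document is also written
#'   there as JSON (the preprocessor's geometric-segmentation input format).
#' @return The geometric-segmentation input document (plain list with
#'   `segmentation_id` and a `time_frames` map of sphere records).
#' @export
parse_star_to_geometric <- function(star_path, config, out_path = NULL) {
  stopifnot(inherits(config, "star_parse_config"))
  df <- read_star(star_path)
  n <- nrow(df)
  if (n == 0L) {
    warning("STAR table ", star_path, " has zero particle rows", call. = FALSE)
    spheres <- list()
  } else {
    xyz <- cbind(star_coordinate_column(df, "X"),
                 star_coordinate_column(df, "Y"),
                 star_coordinate_column(df, "Z"))
    centers <- (xyz / config$star_file_coordinate_divisor) * config$pixel_size
    spheres <- lapply(seq_len(n), function(i) {
      list(id = i - 1L,
           center = as.numeric(centers[i, ]),
           radius = config$sphere_radius,
           color = config$color)
    })
  }
  doc <- list(segmentation_id = config$segmentation_id,
              time_frames = list(`0` = spheres))
  if (!is.null(out_path)) write_canonical_json(doc, out_path)
  doc
}

#' Read a geometric-segmentation input document
#'
#' @param path Path to the JSON document produced by
#'   [parse_star_to_geometric()] (or authored by hand in the same shape).
#' @return A [geometric_segmentation()].
#' @export
read_geometric_segmentation <- function(path) {
  doc <- read_json_doc(path)
  sid <- json_scalar(doc$segmentation_id)
  if (is.null(sid)) {
    stop("format error in ", path, ": missing segmentation_id", call. = FALSE)
  }
  frames <- lapply(doc$time_frames, function(spheres) {
    lapply(spheres, function(s) {
      sphere_primitive(id = json_scalar(s$id),
                       center = json_num_vec(s$center),
                       radius = json_scalar(s$radius),
                       color = json_num_vec(s$color))
    })
  })
  names(frames) <- names(doc$time_frames)
  geometric_segmentation(sid, frames)
}
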