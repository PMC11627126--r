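# Deterministic segment colouring.
#
# Lattice segments that carry no source colour are assigned one of ten fixed,
# visually distinguishable RGBA colours, indexed by (segment_id - 1) mod 10.
# The palette is part of the package contract: re-preprocessing an entry must
# reproduce annotations byte-for-byte.

.voxseg_palette <- matrix(c(
  0.121, 0.466, 0.705, 1,  # blue
  1.000, 0.498, 0.054, 1,  # orange
  0.172, 0.627, 0.172, 1,  # green
  0.839, 0.152, 0.156, 1,  # red
  0.580, 0.403, 0.741, 1,  # purple
  0.549, 0.337, 0.294, 1,  # brown
  0.890, 0.466, 0.760, 1,  # pink
  0.498, 0.498, 0.498, 1,  # grey
  0.737, 0.741, 0.133, 1,  # olive
  0.090, 0.745, 0.811, 1   # cyan
), ncol = 4, byrow = TRUE)

#' Deterministic palette colour for a segment id
#'
#' @param segment_id Positive integer segment id.
#' @return Numeric RGBA vector, components in `[0, 1]`.
#' @export
palette_color <- function(segment_id) {
  stopifnot(is.numeric(segment_id), length(segment_id) == 1L, segment_id >= 1)
  idx <- ((as.integer(segment_id) - 1L) %% 10L) + 1L
  as.numeric(.voxseg_palette[idx, ])
}

#' Convert a 6-digit hex colour to RGBA
#'
#' @param hex 6-hex-digit string, with or without a leading `#`.
#' @param alpha Alpha component, default 1.
#' @return Numeric RGBA vector in `[0, 1]`.
#' @export
hex_to_rgba <- function(hex, alpha = 1) {
  h <- sub("^#", "", hex)
  if (!grepl("^[0-9a-fA-F]{6}$", h)) {
    stop("not a 6-hex-digit colour: ", hex, call. = FALSE)
  }
  comp <- strtoi(substring(h, c(1, 3, 5), c(2, 4, 6)), base = 16L)
  c(comp / 255, alpha)
}
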