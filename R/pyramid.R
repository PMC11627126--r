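# Multiscale downsampling pyramids.
#
# Each pyramid level halves every axis (level factors 1, 2, 4, ...). Scalar
# grids are reduced by the arithmetic mean of each up-to-2x2x2 block; label
# grids by the most frequent label in the block, ties broken by the smallest
# label, with background 0 participating like any other label. Edge blocks
# on odd-sized axes hold fewer than 8 voxels and are averaged over the
# voxels they actually contain, so level-f dims are ceil(dims / f).

#' Mean of one downsampling block
#'
#' @param block Numeric vector of up to 8 voxel values.
#' @return Arithmetic mean of the available voxels.
#' @export
downsample_block_mean <- function(block) {
  stopifnot(length(block) >= 1L)
  mean(as.numeric(block))
}

#' Majority label of one downsampling block
#'
#' @param block Integer vector of up to 8 labels (0 = background counts too).
#' @return Most frequent label; ties resolved to the smallest label.
#' @export
downsample_block_majority <- function(block) {
  stopifnot(length(block) >= 1L)
  tab <- table(as.integer(block))
  lab <- as.integer(names(tab))
  lab[order(-as.integer(tab), lab)][1L]
}

# Parent (coarse-grid) linear index for every voxel of a 3D array halved
# along each axis.
parent_index_vector <- function(dims) {
  pd <- ceiling(dims / 2)
  px <- ((seq_len(dims[1]) - 1L) %/% 2L) + 1L
  py <- ((seq_len(dims[2]) - 1L) %/% 2L) + 1L
  pz <- ((seq_len(dims[3]) - 1L) %/% 2L) + 1L
  ix <- rep.int(px, times = dims[2] * dims[3])
  iy <- rep.int(rep(py, each = dims[1]), times = dims[3])
  iz <- rep(pz, each = dims[1] * dims[2])
  list(pid = ix + (iy - 1L) * pd[1] + (iz - 1L) * pd[1] * pd[2], pdims = pd)
}

halve_mean <- function(arr) {
  d <- dim(arr)
  p <- parent_index_vector(d)
  sums <- rowsum(as.numeric(arr), p$pid)
  counts <- rowsum(rep(1, length(arr)), p$pid)
  array(as.numeric(sums / counts), dim = p$pdims)
}

halve_majority <- function(arr) {
  d <- dim(arr)
  p <- parent_index_vector(d)
  labels <- sort(unique(as.integer(arr)))
  nparent <- prod(p$pdims)
  counts <- matrix(0L, nrow = nparent, ncol = length(labels))
  av <- as.integer(arr)
  for (j in seq_along(labels)) {
    cj <- rowsum(as.integer(av == labels[j]), p$pid)
    counts[as.integer(rownames(cj)), j] <- cj[, 1L]
  }
  # columns are in ascending label order, so "first" max = smallest label
  winner <- labels[max.col(counts, ties.method = "first")]
  array(as.integer(winner), dim = p$pdims)
}

#' Pyramid construction policy
#'
#' @param min_level_factor,max_level_factor Powers of two bounding the levels
#'   kept (factor 1 is always retained).
#' @param stop_dim Stop adding coarser levels once every axis is at most this
#'   many voxels.
#' @return Object of class `pyramid_policy`.
#' @export
pyramid_policy <- function(min_level_factor = 1L, max_level_factor = 64L,
                           stop_dim = 32L) {
  is_pow2 <- function(x) x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
  stopifnot(is_pow2(min_level_factor), is_pow2(max_level_factor),
            min_level_factor <= max_level_factor, stop_dim >= 1L)
  structure(list(min_level_factor = as.integer(min_level_factor),
                 max_level_factor = as.integer(max_level_factor),
                 stop_dim = as.integer(stop_dim)),
            class = "pyramid_policy")
}

#' Build a downsampling pyramid
#'
#' Produces levels with factors 1, 2, 4, ... up to
#' `policy$max_level_factor`, stopping early once all dims of the newest
#' level are at most `policy$stop_dim`. Scalar grids use the block mean,
#' label grids the block majority. Level-f dims are `ceiling(dims / f)`.
#'
#' @param grid A [volume_grid()] or [label_grid()].
#' @param policy A [pyramid_policy()].
#' @return Named list level factor (as character) -> grid of the same class.
#' @export
build_pyramid <- function(grid, policy = pyramid_policy()) {
  is_labels <- inherits(grid, "label_grid")
  if (!is_labels && !inherits(grid, "volume_grid")) {
    stop("grid must be a volume_grid or label_grid", call. = FALSE)
  }
  pyr <- list(`1` = grid)
  factor <- 1L
  cur <- grid$values
  while (factor < policy$max_level_factor && !all(dim(cur) <= policy$stop_dim)) {
    factor <- factor * 2L
    cur <- if (is_labels) halve_majority(cur) else halve_mean(cur)
    lev <- if (is_labels) {
      label_grid(cur, voxel_size = grid$voxel_size * factor,
                 origin = grid$origin)
    } else {
      volume_grid(cur, voxel_size = grid$voxel_size * factor,
                  origin = grid$origin)
    }
    pyr[[as.character(factor)]] <- lev
  }
  if (policy$min_level_factor > 1L) {
    f <- as.integer(names(pyr))
    pyr <- pyr[f == 1L | f >= policy$min_level_factor]  # factor 1 always kept
  }
  pyr
}
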