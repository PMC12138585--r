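#' @keywords internal
region_labels <- function() c("IFG", "preSMA", "STN")

#' @keywords internal
tract_labels <- function() c("IFG-preSMA", "STN-IFG", "STN-preSMA")

#' Region and tract labels of the stopping network
#'
#' Three regions of interest (inferior frontal gyrus, presupplementary motor
#' area, subthalamic nucleus) and the three tracts connecting them.
#'
#' @return Character vector of the six target labels.
#' @export
stopping_network_targets <- function() c(region_labels(), tract_labels())

#' @keywords internal
mask_label <- function(target, hemisphere) paste(target, hemisphere, sep = "_")

#' Build a digital phantom layout
#'
#' Places one small cubic mask per (target, hemisphere) pair on a regular
#' grid: 3 regions x 2 hemispheres plus 3 tracts x 2 hemispheres = 12
#' pairwise-disjoint masks. The layout is a stand-in for subject-space
#' parcellation and tractography masks, sized so that whole-pipeline runs
#' take seconds.
#'
#' @param dim Grid shape, 3 integers (default `c(24, 24, 24)`).
#' @param voxel_mm Isotropic voxel size in mm (metadata only).
#' @param cube Edge length of each cubic mask in voxels (default 3, i.e.
#'   27 voxels per mask).
#'
#' @return An object of class `phantom_layout`: a list with `dim`,
#'   `voxel_mm` and `masks` (named list of logical arrays, names
#'   `"<target>_<L|R>"`).
#' @export
phantom_layout <- function(dim = c(24L, 24L, 24L), voxel_mm = 1,
                           cube = 3L) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < cube))
    stop("`dim` must be 3 integers, each >= `cube`")
  targets <- stopping_network_targets()
  labels <- as.vector(outer(targets, c("L", "R"), mask_label))

  # 4 x 3 grid of cube corners in the first two axes, fixed third axis
  spacing <- cube + 3L
  n_i <- 4L; n_j <- 3L
  need <- c(2L + (n_i - 1L) * spacing + cube, 2L + (n_j - 1L) * spacing + cube)
  if (dim[1] < need[1] || dim[2] < need[2])
    stop("grid too small for 12 masks of this cube size")
  z0 <- max(1L, dim[3] %/% 2L - cube %/% 2L)

  masks <- vector("list", length(labels))
  names(masks) <- labels
  idx <- 0L
  for (j in seq_len(n_j)) {
    for (i in seq_len(n_i)) {
      idx <- idx + 1L
      m <- array(FALSE, dim)
      x0 <- 2L + (i - 1L) * spacing
      y0 <- 2L + (j - 1L) * spacing
      m[x0:(x0 + cube - 1L), y0:(y0 + cube - 1L), z0:(z0 + cube - 1L)] <- TRUE
      masks[[idx]] <- m
    }
  }
  layout <- structure(list(dim = dim, voxel_mm = voxel_mm, masks = masks),
                      class = "phantom_layout")
  validate_layout(layout)
  layout
}

#' Validate a phantom layout
#'
#' Checks that every mask is non-empty, fits the grid, and that masks are
#' pairwise disjoint. Called before any synthesis.
#'
#' @param layout A `phantom_layout`.
#' @return The layout, invisibly, if valid; otherwise an error.
#' @export
validate_layout <- function(layout) {
  if (!is.list(layout) || is.null(layout$masks) || is.null(layout$dim))
    stop("not a phantom layout")
  if (length(layout$masks) == 0L) stop("layout has no masks")
  if (is.null(names(layout$masks)) || anyDuplicated(names(layout$masks)))
    stop("mask labels must be unique and named")
  counts <- integer(length(layout$masks))
  total <- array(0L, layout$dim)
  for (i in seq_along(layout$masks)) {
    m <- layout$masks[[i]]
    if (!is.logical(m) || !identical(dim(m), as.integer(layout$dim)))
      stop("mask '", names(layout$masks)[i], "' does not fit the grid")
    counts[i] <- sum(m)
    if (counts[i] == 0L)
      stop("mask '", names(layout$masks)[i], "' is empty")
    total <- total + m
  }
  if (any(total > 1L)) stop("masks overlap: layout masks must be disjoint")
  invisible(layout)
}
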