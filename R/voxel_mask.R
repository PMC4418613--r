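#' Voxel mask container
#'
#' A `voxel_mask` is a 3D binary occupancy grid together with its physical
#' voxel spacing in mm. It is the object all geometry operates on: the grid
#' holds the segmentation result (1 = tumor, 0 = background) and the spacing
#' converts voxel counts and face counts into physical volumes and areas.
#' The physical origin is carried through reads and writes but never enters
#' any geometric computation, since all shape features are
#' translation- and orientation-invariant.
#'
#' @param grid 3D array of 0/1 occupancy (any numeric array; values > 0 are
#'   coerced to foreground).
#' @param spacing numeric length-3, voxel edge lengths (sx, sy, sz) in mm;
#'   all strictly positive.
#' @param origin numeric length-3 physical offset in mm (metadata only).
#' @return An object of class `voxel_mask` with elements `grid` (integer
#'   0/1 array), `spacing` and `origin`.
#' @examples
#' m <- voxel_mask(array(1L, c(3, 3, 3)), spacing = c(1, 1, 1))
#' n_foreground(m)
#' @export
voxel_mask <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L)
    stop("mask grid must be a 3D array, got ", length(dim(grid)), " dimensions",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("spacing must be 3 positive voxel edge lengths in mm", call. = FALSE)
  if (anyNA(grid)) stop("mask grid contains NA", call. = FALSE)
  g <- array(as.integer(grid > 0), dim(grid))
  structure(list(grid = g, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels, spacing (%s) mm, %d foreground\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              n_foreground(x)))
  invisible(x)
}

#' Number of foreground voxels
#' @param mask a [voxel_mask()].
#' @return integer count of voxels with value 1.
#' @export
n_foreground <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$grid)
}

stop_if_empty <- function(mask, op) {
  if (n_foreground(mask) == 0L)
    stop(op, ": mask has no foreground voxels", call. = FALSE)
  invisible(TRUE)
}

#' Read a binary segmentation mask
#'
#' Reads a 3D mask from NIfTI-1 (`.nii`, `.nii.gz`) or NRRD (`.nrrd`).
#' Any stored value > 0 is treated as foreground, so label maps from
#' external segmentation tools are accepted as-is. Voxel spacing is taken
#' from the image header; the original orientation/space metadata is carried
#' in the `orientation` attribute but geometry is always computed in the
#' mask's own grid.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return a [voxel_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    nr <- read_nrrd(path)
    dims <- dim(nr$data)
    if (length(dims) != 3L)
      stop("expected a 3D image, got ", length(dims), "D: ", path, call. = FALSE)
    if (any(nr$spacing <= 0) || anyNA(nr$spacing))
      stop("non-positive voxel spacing in NRRD header: ", path, call. = FALSE)
    m <- voxel_mask(nr$data, nr$spacing, nr$origin)
    attr(m, "orientation") <- nr$space
    return(m)
  }
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("unsupported mask format (need .nii, .nii.gz or .nrrd): ", path,
         call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  dims <- dim(img)
  if (length(dims) != 3L)
    stop("expected a 3D image, got ", length(dims), "D: ", path, call. = FALSE)
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  if (anyNA(sp) || any(sp <= 0))
    stop("non-positive voxel spacing in NIfTI header: ", path, call. = FALSE)
  org <- tryCatch(RNifti::origin(img), error = function(e) c(0, 0, 0))
  m <- voxel_mask(as.array(img), sp, as.numeric(org)[seq_len(3L)])
  attr(m, "orientation") <- tryCatch(RNifti::orientation(img),
                                     error = function(e) NA_character_)
  m
}

#' Write a binary segmentation mask
#'
#' Writes the mask so that [read_mask()] round-trips the grid exactly and
#' the spacing to float32 header precision.
#'
#' @param mask a [voxel_mask()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(mask$grid, path, spacing = mask$spacing, origin = mask$origin)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(mask$grid)
    RNifti::pixdim(img) <- mask$spacing
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else {
    stop("unsupported mask format (need .nii, .nii.gz or .nrrd): ", path,
         call. = FALSE)
  }
  invisible(path)
}

# Label 26-connected components by breadth-first flood fill over linear
# indices of a zero-padded copy (padding keeps neighbour offsets from
# wrapping across grid faces). Returns an integer array, 0 = background,
# components numbered in discovery order.
label_components <- function(grid) {
  d <- dim(grid)
  dp <- d + 2L
  p <- array(FALSE, dp)
  p[1:d[1] + 1L, 1:d[2] + 1L, 1:d[3] + 1L] <- grid > 0
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  offsets <- off[, 1] + off[, 2] * dp[1] + off[, 3] * dp[1] * dp[2]
  lab_p <- integer(prod(dp))
  remaining <- which(p)
  p_vec <- as.vector(p)
  comp <- 0L
  while (length(remaining)) {
    comp <- comp + 1L
    frontier <- remaining[1L]
    p_vec[frontier] <- FALSE
    lab_p[frontier] <- comp
    while (length(frontier)) {
      cand <- unique(as.vector(outer(frontier, offsets, `+`)))
      cand <- cand[p_vec[cand]]
      p_vec[cand] <- FALSE
      lab_p[cand] <- comp
      frontier <- cand
    }
    remaining <- remaining[p_vec[remaining]]
  }
  lab <- array(lab_p, dp)[1:d[1] + 1L, 1:d[2] + 1L, 1:d[3] + 1L]
  array(lab, d)
}

#' Keep the largest 26-connected component
#'
#' Manual segmentations occasionally leave stray voxels; geometry is defined
#' on a single object, so multi-component masks are reduced to their largest
#' 26-connected component with a warning.
#'
#' @param mask a [voxel_mask()].
#' @return a [voxel_mask()] containing only the largest component.
#' @export
largest_component <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  stop_if_empty(mask, "largest_component")
  lab <- label_components(mask$grid)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    keep <- which.max(sizes)
    warning(sprintf("mask has %d connected components; keeping largest (%d of %d voxels)",
                    ncomp, sizes[keep], sum(sizes)), call. = FALSE)
    g <- array(as.integer(lab == keep), dim(mask$grid))
    return(voxel_mask(g, mask$spacing, mask$origin))
  }
  mask
}

#' Nearest-neighbour resample to an isotropic grid
#'
#' Discrete compactness is defined on unit cubes; anisotropic CT grids
#' (e.g. 0.7 mm in-plane, 2.5 mm slices) are resampled to the smallest
#' spacing component before face counting.
#'
#' @param mask a [voxel_mask()].
#' @param target target isotropic spacing in mm; defaults to `min(spacing)`.
#' @return a [voxel_mask()] with spacing `c(target, target, target)`.
#' @export
resample_isotropic <- function(mask, target = min(mask$spacing)) {
  stopifnot(inherits(mask, "voxel_mask"), target > 0)
  sp <- mask$spacing
  if (all(abs(sp - target) < 1e-9)) return(mask)
  d <- dim(mask$grid)
  # sample at physical centers of the new grid, nearest source voxel
  new_d <- pmax(1L, as.integer(round(d * sp / target)))
  ix <- pmin(d[1], pmax(1L, as.integer(ceiling((seq_len(new_d[1]) - 0.5) * target / sp[1]))))
  iy <- pmin(d[2], pmax(1L, as.integer(ceiling((seq_len(new_d[2]) - 0.5) * target / sp[2]))))
  iz <- pmin(d[3], pmax(1L, as.integer(ceiling((seq_len(new_d[3]) - 0.5) * target / sp[3]))))
  voxel_mask(mask$grid[ix, iy, iz, drop = FALSE], rep(target, 3), mask$origin)
}
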