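#' Build the default three-region block mask
#'
#' A simple voxel layout standing in for drawn VOIs: left striatum
#' (label 1) and right striatum (label 2) as lateral blocks in the upper
#' axial half, cerebellum (label 3) as a posterior block in the lower
#' half, background 0.
#'
#' @param dim Length-3 integer grid size (x, y, z), each >= 4.
#' @return Integer 3D array of labels.
#' @export
default_mask <- function(dim = c(16L, 16L, 8L)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 4L))
  m <- array(0L, dim)
  xh <- dim[1L] %/% 2
  yq <- max(2L, dim[2L] %/% 4)
  zh <- dim[3L] %/% 2
  m[2:(xh - 1), 2:(yq + 1), (zh + 1):(dim[3L] - 1)] <- 1L
  m[(xh + 2):(dim[1L] - 1), 2:(yq + 1), (zh + 1):(dim[3L] - 1)] <- 2L
  m[2:(dim[1L] - 1), (dim[2L] - yq):(dim[2L] - 1), 2:zh] <- 3L
  m
}

#' Generate a 4D activity phantom from per-region TACs
#'
#' Every voxel of a labelled region carries that region's frame value plus
#' zero-mean Gaussian noise whose SD mimics count statistics: `SD =
#' noise_cv * value / sqrt(w)` with frame weight `w = duration /
#' max(duration)`, so short early frames are noisier than the long late
#' frames and `noise_cv` is the coefficient of variation at the longest
#' frame. Negative draws are clipped to zero; background voxels are zero.
#'
#' @param scheme A [framing_scheme][build_framing].
#' @param tacs Named list of [tac] objects; names are the integer mask
#'   labels (e.g. `list("1" = left, "2" = right, "3" = cereb)`). One TAC
#'   per non-background label in `mask`.
#' @param mask Integer 3D label array; defaults to [default_mask()].
#' @param noise_cv Noise coefficient of variation, >= 0.
#' @param seed Integer seed for the noise draws.
#' @param spacing_mm Voxel spacing, mm (length 3).
#' @return A `phantom_4d`: list with `image` (4D array x,y,z,frame),
#'   `mask`, `scheme`, `spacing_mm`, `decay_corrected`.
#' @export
generate_phantom <- function(scheme, tacs, mask = default_mask(),
                             noise_cv = 0, seed = 1L,
                             spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(scheme, "framing_scheme"), is.list(tacs))
  if (!is.numeric(noise_cv) || noise_cv < 0)
    stop("noise_cv must be non-negative")
  labels <- sort(unique(as.integer(mask[mask != 0])))
  if (is.null(names(tacs)) || !all(as.character(labels) %in% names(tacs)))
    stop("tacs must be a named list covering every non-background label: ",
         paste(labels, collapse = ", "))
  nf <- nrow(scheme)
  for (lb in labels) {
    x <- tacs[[as.character(lb)]]
    stopifnot(inherits(x, "tac"))
    if (length(x$values) != nf)
      stop("TAC for label ", lb, " has ", length(x$values),
           " frames; scheme has ", nf)
  }
  set.seed(as.integer(seed))
  w <- scheme$duration_s / max(scheme$duration_s)
  img <- array(0, c(dim(mask), nf))
  nvox_total <- prod(dim(mask))
  for (lb in labels) {
    idx <- which(mask == lb)
    vals <- tacs[[as.character(lb)]]$values
    for (f in seq_len(nf)) {
      v <- vals[f]
      vox <- if (noise_cv > 0 && v != 0)
        pmax(0, v + rnorm(length(idx), 0, noise_cv * abs(v) / sqrt(w[f])))
      else rep(v, length(idx))
      img[idx + (f - 1L) * nvox_total] <- vox
    }
  }
  dc <- unique(vapply(tacs[as.character(labels)],
                      function(x) x$decay_corrected, logical(1L)))
  structure(
    list(image = img, mask = mask, scheme = scheme,
         spacing_mm = spacing_mm, decay_corrected = all(dc)),
    class = "phantom_4d"
  )
}

#' Write a phantom to NIfTI-1 files plus a frame-timing sidecar
#'
#' The 4D image and the integer label mask go to NIfTI-1; frame timing is
#' a TSV sidecar with columns `frame_index, start_s, duration_s`.
#'
#' @param phantom A [phantom_4d][generate_phantom].
#' @param image_path,mask_path,timing_path Output paths.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_phantom <- function(phantom, image_path, mask_path, timing_path) {
  stopifnot(inherits(phantom, "phantom_4d"))
  img <- RNifti::asNifti(phantom$image,
                         pixdim = c(phantom$spacing_mm, 1))
  RNifti::writeNifti(img, image_path)
  mask <- phantom$mask
  storage.mode(mask) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(mask, pixdim = phantom$spacing_mm,
                                     datatype = "int16"),
                     mask_path)
  write.table(
    data.frame(frame_index = phantom$scheme$frame,
               start_s = phantom$scheme$start_s,
               duration_s = phantom$scheme$duration_s),
    timing_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(image = image_path, mask = mask_path, timing = timing_path))
}

#' Read a phantom from NIfTI-1 image + mask + timing sidecar
#'
#' @param image_path 4D NIfTI-1 activity image.
#' @param mask_path 3D NIfTI-1 integer label mask on the same grid.
#' @param timing_path Frame-timing TSV (`frame_index, start_s,
#'   duration_s`).
#' @param decay_corrected Decay-correction state to record.
#' @return A `phantom_4d`.
#' @export
read_phantom <- function(image_path, mask_path, timing_path,
                         decay_corrected = TRUE) {
  img <- RNifti::readNifti(image_path)
  mask <- RNifti::readNifti(mask_path)
  timing <- read.table(timing_path, header = TRUE, sep = "\t")
  if (length(dim(img)) != 4L) stop("image must be 4D")
  if (!identical(dim(img)[1:3], dim(mask)[1:3]))
    stop("image and mask grids differ")
  scheme <- new_framing_scheme(timing$duration_s[order(timing$frame_index)])
  if (nrow(scheme) != dim(img)[4L])
    stop("timing sidecar has ", nrow(scheme), " frames; image has ",
         dim(img)[4L])
  mask_arr <- array(as.integer(round(as.array(mask))), dim(mask)[1:3])
  structure(
    list(image = array(as.numeric(img), dim(img)), mask = mask_arr,
         scheme = scheme,
         spacing_mm = attr(img, "pixdim")[1:3] %||% c(1, 1, 1),
         decay_corrected = decay_corrected),
    class = "phantom_4d"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
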