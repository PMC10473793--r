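#' Voxel-wise multiscale entropy map
#'
#' Applies [multiscale_entropy()] to the time series of every in-mask voxel
#' of a 4D BOLD image and returns the per-voxel MSE as a 3D map.  Voxels
#' outside the mask, and voxels whose entropy profile is undefined at every
#' scale, are `NA`.
#'
#' @param bold4d 4D numeric array (x, y, z, time) or an `RNifti` image.
#' @param mask 3D logical/numeric array congruent with the spatial grid of
#'   `bold4d`, or `NULL` to use all voxels with nonzero temporal variance.
#' @param params An [entropy_params()] object.
#' @return 3D numeric array of MSE values (`NA` outside the mask), carrying
#'   the input image's NIfTI metadata when present.
#' @export
voxelwise_mse <- function(bold4d, mask = NULL, params = entropy_params()) {
  arr <- as_array4d(bold4d)
  d <- dim(arr)
  if (d[4] < params$m + 2L) stop("time axis too short for sample entropy")
  if (!is.null(mask)) {
    mk <- as_array3d(mask)
    if (!identical(dim(mk), d[1:3]))
      stop("mask grid does not match the image grid")
    mk <- mk != 0 & !is.na(mk)
  } else {
    mk <- apply(arr, 1:3, function(v) stats::var(v) > 0)
  }
  out <- array(NA_real_, d[1:3])
  idx <- which(mk)
  if (length(idx)) {
    flat <- matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
    out[idx] <- vapply(idx, function(i) {
      prof <- tryCatch(suppressWarnings(multiscale_entropy(flat[i, ], params)),
                       error = function(e) NULL)
      if (is.null(prof)) NA_real_ else prof$mse
    }, numeric(1))
  }
  copy_nifti_meta(out, bold4d)
}

#' Average maps or entropy profiles across runs
#'
#' Element-wise arithmetic mean of a list of congruent numeric arrays (e.g.
#' per-run MSE maps) or of `entropy_profile` objects.  Undefined (`NA`)
#' entries are excluded pairwise; the number of contributing runs per element
#' is recorded in the `n_valid` attribute (for arrays) or by recomputing
#' `n_valid_scales` (for profiles).
#'
#' @param runs List of numeric arrays/vectors with identical dimensions, or
#'   list of `entropy_profile` objects with identical scale counts.
#' @return Object of the same type as the list elements.
#' @export
average_runs <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  if (inherits(runs[[1]], "entropy_profile")) {
    ns <- vapply(runs, function(p) length(p$sampen), integer(1))
    if (length(unique(ns)) != 1L) stop("profiles have different scale counts")
    sam <- do.call(rbind, lapply(runs, `[[`, "sampen"))
    se <- colMeans(sam, na.rm = TRUE)
    se[!is.finite(se)] <- NA_real_
    valid <- sum(!is.na(se))
    if (valid == 0L) stop("all scales undefined after averaging")
    return(structure(list(sampen = se, mse = mean(se, na.rm = TRUE),
                          n_valid_scales = valid,
                          scales = runs[[1]]$scales, params = runs[[1]]$params),
                     class = "entropy_profile"))
  }
  dims <- lapply(runs, function(x) dim(x) %||% length(x))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("run maps have mismatched dimensions")
  stack <- vapply(runs, function(x) as.numeric(x),
                  numeric(length(runs[[1]])))
  stack <- matrix(stack, ncol = length(runs))
  n_valid <- rowSums(!is.na(stack))
  avg <- rowMeans(stack, na.rm = TRUE)
  avg[n_valid == 0L] <- NA_real_
  out <- runs[[1]]
  out[] <- avg
  attr(out, "n_valid") <- {nv <- runs[[1]]; nv[] <- n_valid; nv}
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean map value within an atlas region
#'
#' @param map 3D numeric array (e.g. from [voxelwise_mse()]).
#' @param atlas 3D integer label array on the same grid.
#' @param roi_id Integer label to summarize.
#' @return Mean of the defined map values over voxels carrying `roi_id`;
#'   `NA` (with a warning) when every such voxel is undefined.
#' @export
roi_mean <- function(map, atlas, roi_id) {
  map <- as_array3d(map); atlas <- as_array3d(atlas)
  if (!identical(dim(map), dim(atlas)))
    stop("map and atlas grids do not match")
  sel <- which(atlas == roi_id)
  if (!length(sel)) stop(sprintf("ROI label %s absent from atlas", roi_id))
  vals <- map[sel]
  if (all(is.na(vals))) {
    warning(sprintf("ROI %s has no defined voxels", roi_id))
    return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}

as_array4d <- function(x) {
  a <- if (inherits(x, "niftiImage")) as.array(x) else x
  if (!is.array(a) || length(dim(a)) != 4L)
    stop("expected a 4D (x, y, z, time) image")
  a
}

as_array3d <- function(x) {
  a <- if (inherits(x, "niftiImage")) as.array(x) else x
  if (is.null(dim(a))) stop("expected a 3D volume")
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1L]
  if (length(dim(a)) != 3L) stop("expected a 3D volume")
  a
}

copy_nifti_meta <- function(out, template) {
  if (inherits(template, "niftiImage"))
    out <- RNifti::asNifti(out, reference = template)
  out
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti for the image formats the pipeline consumes:
#' 4D BOLD series, 3D label atlases, and 3D MSE maps (written with the
#' affine of a reference image when given).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param map 3D numeric array to write.
#' @param reference Optional `niftiImage` supplying grid metadata.
#' @return `read_nifti_volume` returns a `niftiImage`; `write_nifti_map`
#'   returns `path` invisibly.
#' @export
read_nifti_volume <- function(path) RNifti::readNifti(path)

#' @rdname read_nifti_volume
#' @export
write_nifti_map <- function(map, path, reference = NULL) {
  img <- if (!is.null(reference)) RNifti::asNifti(map, reference = reference)
         else RNifti::asNifti(map)
  RNifti::writeNifti(img, path)
  invisible(path)
}
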