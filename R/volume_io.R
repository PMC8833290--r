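#' Construct an image volume
#'
#' The shared spatial container consumed by every metric. Voxels are HU
#' values in a 3D array indexed `[row, col, slice]`; `spacing` gives the
#' physical size of one voxel along each of those axes in mm; `origin` is
#' the mm position of the centre of voxel `[1, 1, 1]`.
#'
#' @param voxels numeric array (a matrix is promoted to one slice).
#' @param spacing length-3 positive numeric, mm per voxel (row, col, slice).
#' @param origin length-3 numeric, mm offset of the first voxel centre.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (or a matrix)")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  if (any(dim(voxels) < 1L)) stop("all volume dimensions must be >= 1")
  if (!all(is.finite(voxels))) stop("HU values must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%g, %g, %g) mm\n",
              min(x$voxels), max(x$voxels),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Convert stored pixel values to HU
#'
#' Applies the linear rescale transform `HU = slope * stored + intercept`
#' used when importing scanner data whose pixel values are stored offset
#' (e.g. CT data stored unsigned with intercept -1024).
#'
#' @param stored numeric stored pixel values.
#' @param slope,intercept rescale slope and intercept.
#' @return numeric HU values.
#' @export
apply_rescale <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

#' Read an image volume
#'
#' @param path file path. For `nifti`, a `.nii`/`.nii.gz` file. For
#'   `raw_json`, the path of the JSON metadata file written by
#'   [write_volume()] (the voxel payload sits next to it).
#' @param format `"nifti"` or `"raw_json"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("nifti", "raw_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    vox <- array(as.numeric(img), dim = dim(img))
    if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
    if (length(dim(vox)) != 3L)
      stop("format error: expected a 3D NIfTI image, got ",
           length(dim(vox)), " dimensions")
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L) pd <- c(pd, rep(1, 3L - length(pd)))
    image_volume(vox, spacing = pd[1:3])
  } else {
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("dims", "spacing", "origin", "data_file")
    miss <- setdiff(need, names(meta))
    if (length(miss))
      stop("format error: raw_json metadata missing attribute(s): ",
           paste(miss, collapse = ", "))
    bin <- file.path(dirname(path), meta$data_file)
    if (!file.exists(bin)) stop("format error: voxel payload missing: ", bin)
    n <- prod(meta$dims)
    con <- file(bin, "rb")
    on.exit(close(con))
    vox <- readBin(con, "double", n = n, size = 8, endian = "little")
    if (length(vox) != n)
      stop("format error: payload has ", length(vox),
           " voxels, metadata promises ", n)
    image_volume(array(vox, dim = meta$dims),
                 spacing = meta$spacing, origin = meta$origin)
  }
}

#' Write an image volume
#'
#' `nifti` writes a NIfTI-1 file with the spacing in `pixdim`. `raw_json`
#' writes `<path>` as JSON metadata plus a little-endian float64 voxel
#' payload `<path>.bin` beside it.
#'
#' @param vol an [image_volume()].
#' @param path output path.
#' @param format `"nifti"` or `"raw_json"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("nifti", "raw_json")) {
  format <- match.arg(format)
  stopifnot(inherits(vol, "image_volume"))
  if (format == "nifti") {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else {
    bin_name <- paste0(basename(path), ".bin")
    meta <- list(dims = dim(vol$voxels), spacing = vol$spacing,
                 origin = vol$origin, datatype = "float64",
                 byte_order = "little", data_file = bin_name)
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
    con <- file(file.path(dirname(path), bin_name), "wb")
    on.exit(close(con))
    writeBin(as.numeric(vol$voxels), con, size = 8, endian = "little")
  }
  invisible(path)
}

# mm coordinates of pixel centres along rows / cols of a slice
row_coords <- function(vol) vol$origin[1] + (seq_len(dim(vol$voxels)[1]) - 1) * vol$spacing[1]
col_coords <- function(vol) vol$origin[2] + (seq_len(dim(vol$voxels)[2]) - 1) * vol$spacing[2]

#' Define a circular region of interest
#'
#' A pixel belongs to the ROI iff its centre lies strictly inside the
#' circle (the membership rule is fixed so that pixel counts are exactly
#' reproducible).
#'
#' @param slice_index 1-based slice index.
#' @param center length-2 numeric, (row, col) mm of the circle centre.
#' @param radius circle radius, mm (> 0).
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(slice_index, center, radius) {
  stopifnot(length(center) == 2L, is.finite(radius))
  if (radius <= 0) stop("`radius` must be > 0")
  structure(list(slice_index = as.integer(slice_index),
                 center = as.numeric(center), radius = as.numeric(radius)),
            class = "circular_roi")
}

#' Define a rectangular region of interest
#'
#' Membership: pixels whose centres lie in `[corner, corner + extent)`
#' along both axes.
#'
#' @param slice_index 1-based slice index.
#' @param corner length-2 numeric, (row, col) mm of the low corner.
#' @param extent length-2 positive numeric, (height, width) mm.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(slice_index, corner, extent) {
  stopifnot(length(corner) == 2L, length(extent) == 2L)
  if (any(extent <= 0)) stop("`extent` must be positive")
  structure(list(slice_index = as.integer(slice_index),
                 corner = as.numeric(corner), extent = as.numeric(extent)),
            class = "rect_roi")
}

# Logical membership matrix of an ROI on its slice.
roi_mask <- function(vol, roi) {
  d <- dim(vol$voxels)
  if (roi$slice_index < 1L || roi$slice_index > d[3])
    stop("bounds error: slice_index ", roi$slice_index, " outside volume")
  rr <- row_coords(vol)
  cc <- col_coords(vol)
  if (inherits(roi, "circular_roi")) {
    lo <- roi$center - roi$radius
    hi <- roi$center + roi$radius
    if (lo[1] < min(rr) - vol$spacing[1] / 2 || hi[1] > max(rr) + vol$spacing[1] / 2 ||
        lo[2] < min(cc) - vol$spacing[2] / 2 || hi[2] > max(cc) + vol$spacing[2] / 2)
      stop("bounds error: circular ROI extends outside the slice")
    outer((rr - roi$center[1])^2, (cc - roi$center[2])^2, `+`) < roi$radius^2
  } else if (inherits(roi, "rect_roi")) {
    hi <- roi$corner + roi$extent
    if (roi$corner[1] < min(rr) - vol$spacing[1] / 2 || hi[1] > max(rr) + vol$spacing[1] ||
        roi$corner[2] < min(cc) - vol$spacing[2] / 2 || hi[2] > max(cc) + vol$spacing[2])
      stop("bounds error: rectangular ROI extends outside the slice")
    outer(rr >= roi$corner[1] & rr < hi[1], cc >= roi$corner[2] & cc < hi[2], `&`)
  } else stop("unknown ROI class")
}

#' Mean and standard deviation over an ROI
#'
#' The SD is the population SD (divide by n); with the thousands of pixels
#' of a typical QA ROI the difference from the sample SD is negligible, but
#' the convention is fixed so results are exactly reproducible.
#'
#' @param vol an [image_volume()].
#' @param roi a [circular_roi()] or [rect_roi()].
#' @return list with `mean` (HU), `sd` (HU) and `n_pixels`.
#' @export
extract_roi_stats <- function(vol, roi) {
  m <- roi_mask(vol, roi)
  v <- vol$voxels[, , roi$slice_index][m]
  if (length(v) < 1L) stop("ROI contains no pixel centres")
  mu <- mean(v)
  structure(list(mean = mu,
                 sd = sqrt(mean((v - mu)^2)),
                 n_pixels = length(v)),
            class = "roi_stats")
}
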