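#' Difference image of two slices of a uniform module
#'
#' Voxelwise `a - b`. Differencing two statistically independent slices
#' removes the deterministic phantom structure while doubling the noise
#' variance; the factor 1/2 in the NPS estimator compensates. A warning
#' is raised when the slice separation is not four slice thicknesses,
#' the spacing used to avoid cross-correlation between the two noise
#' realizations.
#'
#' @param vol an [image_volume()].
#' @param slice_a,slice_b distinct slice indices.
#' @return Numeric matrix with attribute `spacing` (in-plane mm).
#' @export
build_difference_image <- function(vol, slice_a, slice_b) {
  d <- dim(vol$voxels)
  if (slice_a == slice_b) stop("slice indices must differ")
  if (slice_a < 1L || slice_b < 1L || slice_a > d[3] || slice_b > d[3])
    stop("bounds error: slice index outside volume")
  if (abs(slice_a - slice_b) != 4L)
    warning("slices are ", abs(slice_a - slice_b),
            " slice thicknesses apart; 4 is recommended to avoid ",
            "cross-correlation")
  out <- vol$voxels[, , slice_a] - vol$voxels[, , slice_b]
  attr(out, "spacing") <- vol$spacing[1:2]
  out
}

#' Place a uniform ensemble of square ROIs inside a mask
#'
#' Lays a regular (by default overlapping) grid of rectangular ROIs over
#' the mask bounding box and keeps those whose every pixel is masked. The
#' default 6 mm stride yields well over 200 ROIs of 5 x 5 cm2 inside a
#' 20 cm uniform disk.
#'
#' @param mask logical matrix (the uniform-module disk).
#' @param spacing length-2 in-plane pixel size, mm.
#' @param roi_size_mm ROI edge lengths `(height, width)`, mm.
#' @param stride_mm grid stride, mm.
#' @return data.frame of class `roi_ensemble` with pixel-index columns
#'   `row0`, `col0`, `nrow`, `ncol`; attribute `spacing`.
#' @export
place_roi_ensemble <- function(mask, spacing, roi_size_mm = c(50, 50),
                               stride_mm = 6) {
  if (length(roi_size_mm) == 1L) roi_size_mm <- rep(roi_size_mm, 2L)
  h <- round(roi_size_mm[1] / spacing[1])
  w <- round(roi_size_mm[2] / spacing[2])
  sr <- max(1L, round(stride_mm / spacing[1]))
  sc <- max(1L, round(stride_mm / spacing[2]))
  if (h > nrow(mask) || w > ncol(mask))
    stop("placement error: ROI larger than the mask bounding box")
  # integral image for O(1) full-coverage queries
  ii <- apply(apply(mask * 1, 2, cumsum), 1, cumsum)
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  rows <- seq(1L, nrow(mask) - h + 1L, by = sr)
  cols <- seq(1L, ncol(mask) - w + 1L, by = sc)
  grid <- expand.grid(row0 = rows, col0 = cols)
  covered <- ii[cbind(grid$row0 + h, grid$col0 + w)] -
    ii[cbind(grid$row0, grid$col0 + w)] -
    ii[cbind(grid$row0 + h, grid$col0)] +
    ii[cbind(grid$row0, grid$col0)]
  keep <- covered == h * w
  if (!any(keep)) stop("placement error: no ROI fits fully inside the mask")
  out <- data.frame(row0 = grid$row0[keep], col0 = grid$col0[keep],
                    nrow = h, ncol = w)
  attr(out, "spacing") <- spacing
  class(out) <- c("roi_ensemble", "data.frame")
  out
}

#' 2D noise power spectrum from an ROI ensemble
#'
#' Each ROI of the difference image is offset-corrected with its own mean
#' CT-number, discrete-Fourier-transformed, and the squared moduli are
#' ensemble-averaged and scaled by `dx*dy/(Nx*Ny)`; the final factor 1/2
#' compensates the noise doubling of the difference-image approach. No
#' windowing or detrending beyond the mean subtraction is applied.
#'
#' @param diff_image matrix from [build_difference_image()].
#' @param rois a [place_roi_ensemble()] result (all ROIs of one size).
#' @param spacing in-plane pixel size, mm; defaults to the `spacing`
#'   attribute of `diff_image` or `rois`.
#' @return An object of class `nps_result`: `nps2d` (fftshifted,
#'   HU^2 mm^2), `fx`/`fy` (cycles/mm, centred), `n_roi`, `nx`, `ny`,
#'   `spacing`, `nyquist`.
#' @export
nps_2d <- function(diff_image, rois, spacing = NULL) {
  if (is.null(spacing))
    spacing <- attr(diff_image, "spacing") %||% attr(rois, "spacing")
  if (is.null(spacing)) stop("pixel spacing unknown")
  if (length(unique(rois$nrow)) != 1L || length(unique(rois$ncol)) != 1L)
    stop("heterogeneous ROI shapes")
  nx <- rois$nrow[1]
  ny <- rois$ncol[1]
  acc <- matrix(0, nx, ny)
  for (i in seq_len(nrow(rois))) {
    sub <- diff_image[rois$row0[i]:(rois$row0[i] + nx - 1L),
                      rois$col0[i]:(rois$col0[i] + ny - 1L)]
    acc <- acc + Mod(fft(sub - mean(sub)))^2
  }
  nps <- acc / nrow(rois) * (spacing[1] * spacing[2]) / (nx * ny) / 2
  shift <- function(m) {
    # reorder so frequencies ascend and DC lands at index floor(n/2) + 1
    idx <- function(n) c((floor(n / 2) + 1 + n %% 2):n, 1:(floor(n / 2) + n %% 2))
    m[idx(nrow(m)), idx(ncol(m))]
  }
  fx <- (seq_len(nx) - 1 - floor(nx / 2)) / (nx * spacing[1])
  fy <- (seq_len(ny) - 1 - floor(ny / 2)) / (ny * spacing[2])
  structure(list(nps2d = shift(nps), fx = fx, fy = fy,
                 n_roi = nrow(rois), nx = nx, ny = ny, spacing = spacing,
                 nyquist = 1 / (2 * spacing[1])),
            class = "nps_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Radial 1D NPS and integrated noise magnitude
#'
#' Radially averages the 2D NPS in annular bins one frequency sample
#' wide (unweighted mean over the pixels of each annulus) and integrates
#' the result to the total noise magnitude
#' `sigma_NPS = sqrt(sum_k NPS1D(f_k) * A_k)`, where `A_k` is the exact
#' discrete area of annulus k on the frequency grid (`n_k * dfx * dfy`,
#' which equals `2 pi f_k df` for annuli fully inside the grid). Using
#' the discrete areas conserves total spectral power on the square
#' frequency support, so the radial route reproduces the direct 2D
#' integral.
#'
#' @param nps an `nps_result` from [nps_2d()] (square grid required).
#' @return list: `fr` (bin-centre frequencies, cycles/mm), `nps1d`,
#'   `sigma_nps` (HU), `sigma_nps_2d` (direct 2D-integral route, HU).
#' @export
radial_average_and_integrate <- function(nps) {
  stopifnot(inherits(nps, "nps_result"))
  if (nps$nx != nps$ny || abs(nps$spacing[1] - nps$spacing[2]) > 1e-9)
    stop("square frequency grid required")
  df <- 1 / (nps$nx * nps$spacing[1])
  fr <- sqrt(outer(nps$fx^2, nps$fy^2, `+`))
  bin <- round(fr / df)
  k <- sort(unique(as.vector(bin)))
  nps1d <- vapply(k, function(b) mean(nps$nps2d[bin == b]), 0)
  nk <- vapply(k, function(b) sum(bin == b), 0)
  sigma2 <- sum(nps1d * nk * df^2)
  list(fr = k * df, nps1d = nps1d, counts = nk,
       sigma_nps = sqrt(sigma2),
       sigma_nps_2d = sqrt(sum(nps$nps2d) * df^2))
}

#' Full NPS pipeline on a uniform-module volume
#'
#' Difference image, ROI ensemble placement within the phantom mask, 2D
#' NPS, radial reduction and integrated noise magnitude.
#'
#' @param vol an [image_volume()] of the uniform module.
#' @param slice_a,slice_b slice pair for the difference image.
#' @param roi_size_mm,stride_mm passed to [place_roi_ensemble()].
#' @param mask optional phantom mask; default thresholds slice `slice_a`
#'   against air, eroded by half the ROI diagonal is not needed because
#'   full ROI coverage is enforced.
#' @return list with `nps` (`nps_result`), `radial` (radial reduction),
#'   `sigma_nps`, `n_roi`.
#' @export
nps_pipeline <- function(vol, slice_a, slice_b, roi_size_mm = c(50, 50),
                         stride_mm = 6, mask = NULL) {
  diff <- build_difference_image(vol, slice_a, slice_b)
  if (is.null(mask)) mask <- phantom_mask(vol$voxels[, , slice_a])
  rois <- place_roi_ensemble(mask, vol$spacing[1:2], roi_size_mm, stride_mm)
  nps <- nps_2d(diff, rois, vol$spacing[1:2])
  rad <- radial_average_and_integrate(nps)
  list(nps = nps, radial = rad, sigma_nps = rad$sigma_nps,
       n_roi = nps$n_roi)
}

#' Convert an integrated noise magnitude to a reference dose
#'
#' Quantum-limited scaling `sigma(ref) = sigma(D) * sqrt(D / ref)`:
#' noise varies inversely with the square root of dose, so a measurement
#' at `cbdi_w` mGy is expressed at a 1 mGy reference by multiplying with
#' `sqrt(cbdi_w)`. This is an assumption of the report layer, not a
#' measured property.
#'
#' @param sigma_nps measured noise magnitude, HU.
#' @param cbdi_w dose index of the scan, mGy.
#' @param reference_mgy reference dose, mGy.
#' @return Noise magnitude at the reference dose, HU.
#' @export
noise_at_reference_dose <- function(sigma_nps, cbdi_w, reference_mgy = 1) {
  sigma_nps * sqrt(cbdi_w / reference_mgy)
}
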