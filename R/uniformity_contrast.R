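#' CT-number accuracy and linearity over phantom inserts
#'
#' Measures the mean CT-number in a circular ROI centred within each
#' insert and regresses the measured means on the nominal HU values by
#' ordinary least squares. By default the ROI radius is 60% of the insert
#' radius to stay clear of partial-volume rims.
#'
#' @param vol an [image_volume()].
#' @param slice_index slice carrying the insert module.
#' @param inserts data.frame with columns `name`, `nominal_hu`, `row`,
#'   `col` (mm, absolute slice coordinates) and `radius` (insert radius,
#'   mm); at least three rows with distinct nominals.
#' @param roi_fraction ROI radius as a fraction of the insert radius.
#' @return An object of class `linearity_result`: `per_insert`
#'   (name, nominal, measured mean and SD), `slope`, `intercept`,
#'   `r_squared`.
#' @export
ct_number_linearity <- function(vol, slice_index, inserts,
                                roi_fraction = 0.6) {
  need <- c("name", "nominal_hu", "row", "col", "radius")
  if (!all(need %in% names(inserts)))
    stop("`inserts` needs columns ", paste(need, collapse = ", "))
  if (length(unique(inserts$nominal_hu)) < 2L)
    stop("degenerate-fit error: identical nominal HU values")
  if (nrow(inserts) < 2L) stop("need at least two inserts")
  st <- lapply(seq_len(nrow(inserts)), function(i)
    extract_roi_stats(vol, circular_roi(slice_index,
                                        c(inserts$row[i], inserts$col[i]),
                                        inserts$radius[i] * roi_fraction)))
  per <- data.frame(name = inserts$name, nominal_hu = inserts$nominal_hu,
                    measured_mean = vapply(st, `[[`, 0, "mean"),
                    measured_sd = vapply(st, `[[`, 0, "sd"))
  fit <- lm(measured_mean ~ nominal_hu, data = per)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((per$measured_mean - mean(per$measured_mean))^2)
  structure(list(per_insert = per,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "linearity_result")
}

# Default phantom mask: material versus air, halfway on the HU scale.
phantom_mask <- function(slice, threshold_hu = -500) slice > threshold_hu

#' Edge-versus-centre uniformity of a homogeneous phantom slice
#'
#' A band of `band_width` image rows (direction `"lateral"`, profile along
#' columns) or columns (direction `"ap"`, profile along rows) centred on
#' the phantom is averaged into a mean CT-number profile. The profile is
#' restricted to the masked phantom extent along the direction; the
#' "profile edges" are the points at 5% and 95% of that extent and the
#' centre at 50%, each obtained by linear interpolation. The
#' non-uniformity is the edge-minus-centre difference of largest absolute
#' value, kept signed (negative means the centre reads higher than the
#' edges, the signature of cupping-free but rim-smeared images; positive
#' means cupping-elevated edges).
#'
#' @param vol an [image_volume()].
#' @param slice_index slice to analyse.
#' @param direction `"lateral"` or `"ap"`.
#' @param band_width number of rows/columns averaged (default 10).
#' @param mask optional logical matrix marking the uniform disk; default
#'   thresholds material against air at -500 HU.
#' @return An object of class `uniformity_result`: `direction`,
#'   `positions`/`profile`, `edge_positions` (mm at 5% and 95%),
#'   `edge_values`, `center_value`, `nonuniformity` (signed HU).
#' @export
uniformity_profile <- function(vol, slice_index = 1L,
                               direction = c("lateral", "ap"),
                               band_width = 10L, mask = NULL) {
  direction <- match.arg(direction)
  img <- vol$voxels[, , slice_index]
  if (is.null(mask)) mask <- phantom_mask(img)
  # profile axis: lateral -> along columns (avg over rows);
  # ap -> along rows (avg over columns)
  if (direction == "ap") {
    img <- t(img)
    mask <- t(mask)
    ax_spacing <- vol$spacing[1]
    ax_coord <- row_coords(vol)
    band_coord <- col_coords(vol)
  } else {
    ax_spacing <- vol$spacing[2]
    ax_coord <- col_coords(vol)
    band_coord <- row_coords(vol)
  }
  ctr_band <- sum(band_coord * rowSums(mask)) / sum(mask)  # mask centroid
  i0 <- which.min(abs(band_coord - ctr_band))
  half <- band_width %/% 2
  band <- max(1L, i0 - half + 1L):min(nrow(img), i0 + (band_width - half))
  sub <- img[band, , drop = FALSE]
  subm <- mask[band, , drop = FALSE]
  keep <- colSums(subm) > 0
  if (sum(keep) < 20L)
    stop("profile error: masked extent shorter than 20 pixels")
  prof <- colSums(sub * subm)[keep] / colSums(subm)[keep]
  pos <- ax_coord[keep]
  L <- max(pos) - min(pos)
  xq <- min(pos) + c(0.05, 0.50, 0.95) * L
  vq <- approx(pos, prof, xout = xq)$y
  d <- c(vq[1] - vq[2], vq[3] - vq[2])
  nonunif <- d[which.max(abs(d))]
  structure(list(direction = direction, positions = pos, profile = prof,
                 edge_positions = xq[c(1, 3)], center_position = xq[2],
                 edge_values = vq[c(1, 3)], center_value = vq[2],
                 nonuniformity = nonunif),
            class = "uniformity_result")
}

#' Uniformity as a function of longitudinal phantom offset
#'
#' Applies [uniformity_profile()] in both directions to a series of
#' volumes acquired with the phantom displaced along the gantry's
#' rotational axis, and reports the spread (max minus min) of the
#' non-uniformities per direction across offsets.
#'
#' @param vols list of [image_volume()] objects.
#' @param offsets numeric vector of longitudinal offsets, mm (same
#'   length as `vols`).
#' @param slice_index,band_width passed to [uniformity_profile()].
#' @return list with `table` (offset, direction, nonuniformity), `spread`
#'   (named per direction) and `max_spread`.
#' @export
uniformity_vs_longitudinal <- function(vols, offsets, slice_index = 1L,
                                       band_width = 10L) {
  stopifnot(length(vols) == length(offsets), length(vols) >= 2L)
  rows <- do.call(rbind, lapply(seq_along(vols), function(i) {
    do.call(rbind, lapply(c("lateral", "ap"), function(d) {
      u <- uniformity_profile(vols[[i]], slice_index, d, band_width)
      data.frame(offset_mm = offsets[i], direction = d,
                 nonuniformity = u$nonuniformity)
    }))
  }))
  spread <- tapply(rows$nonuniformity, rows$direction,
                   function(v) max(v) - min(v))
  list(table = rows, spread = spread, max_spread = max(spread))
}

#' Contrast-to-noise ratio between an insert and adjacent background
#'
#' `CNR = (mean_bkg - mean_insert) / sqrt((sd_bkg^2 + sd_insert^2) / 2)`.
#' The sign follows background minus insert: inserts denser than
#' background give negative CNR.
#'
#' @param insert_stats,background_stats ROI statistics from
#'   [extract_roi_stats()] (any list with `mean` and `sd`).
#' @param name optional insert label.
#' @return An object of class `cnr_result` with `cnr`, `insert_stats`,
#'   `background_stats`.
#' @export
cnr <- function(insert_stats, background_stats, name = NULL) {
  s2 <- (background_stats$sd^2 + insert_stats$sd^2) / 2
  if (s2 <= 0)
    stop("undefined-CNR error: both ROI standard deviations are zero")
  structure(list(name = name,
                 cnr = (background_stats$mean - insert_stats$mean) / sqrt(s2),
                 insert_stats = insert_stats,
                 background_stats = background_stats),
            class = "cnr_result")
}

#' CNR of an insert with automatic adjacent background ROI
#'
#' Places the background ROI at the same distance from the phantom centre
#' as the insert, rotated to the azimuth farthest from all listed insert
#' positions.
#'
#' @param vol an [image_volume()].
#' @param slice_index slice of the insert module.
#' @param insert one row of the insert table (`row`, `col`, `radius`, mm,
#'   absolute coordinates).
#' @param all_inserts table of every insert position (to keep the
#'   background ROI insert-free).
#' @param phantom_center (row, col) mm of the phantom centre.
#' @param roi_fraction ROI radius as fraction of insert radius.
#' @param name insert label.
#' @return A `cnr_result`.
#' @export
cnr_insert <- function(vol, slice_index, insert, all_inserts,
                       phantom_center, roi_fraction = 0.6, name = NULL) {
  rel <- c(insert$row, insert$col) - phantom_center
  rad <- sqrt(sum(rel^2))
  az_ins <- atan2(all_inserts$col - phantom_center[2],
                  all_inserts$row - phantom_center[1])
  cand <- seq(0, 2 * pi, length.out = 181)[-181]
  gap <- vapply(cand, function(a) {
    d <- abs(((a - az_ins + pi) %% (2 * pi)) - pi)
    min(d)
  }, 0)
  best <- cand[which.max(gap)]
  bkg_center <- phantom_center + rad * c(cos(best), sin(best))
  r_roi <- insert$radius * roi_fraction
  cnr(extract_roi_stats(vol, circular_roi(slice_index,
                                          c(insert$row, insert$col), r_roi)),
      extract_roi_stats(vol, circular_roi(slice_index, bkg_center, r_roi)),
      name = name)
}
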