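#' Describe a synthetic QA phantom module
#'
#' Emulates the modules of a CatPhan-style QA phantom: a uniform disk
#' (uniformity / noise module), an insert module carrying low/high-density
#' cylindrical inserts plus four fidelity rods on the corners of an
#' axis-aligned 50 mm square, and a slanted-edge module for resolution.
#' Positions are mm relative to the phantom centre, (row, col).
#'
#' @param module one of `"uniform"`, `"insert"`, `"edge"`.
#' @param diameter phantom disk diameter, mm.
#' @param background_hu HU of the disk material.
#' @param inserts data.frame with columns `name`, `row`, `col`,
#'   `radius`, `hu` (mm / HU), or `NULL`.
#' @param rods data.frame with columns `row`, `col`, `radius`, `hu`;
#'   defaults (insert module) to four 3 mm-radius rods at the corners of a
#'   50 mm square centred on the phantom.
#' @param edge for the edge module: list with `angle` (degrees the edge is
#'   tilted away from the column axis), `low_hu`, `high_hu`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(module = c("uniform", "insert", "edge"),
                         diameter = 200, background_hu = 0,
                         inserts = NULL, rods = NULL, edge = NULL) {
  module <- match.arg(module)
  R <- diameter / 2
  if (module == "insert" && is.null(rods))
    rods <- data.frame(row = c(-25, -25, 25, 25), col = c(-25, 25, -25, 25),
                       radius = 3, hu = background_hu + 900)
  if (module == "edge" && is.null(edge))
    edge <- list(angle = 3, low_hu = 0, high_hu = 1000)
  for (df in list(inserts, rods)) {
    if (!is.null(df)) {
      if (!all(c("row", "col", "radius", "hu") %in% names(df)))
        stop("spec error: inserts/rods need columns row, col, radius, hu")
      if (any(sqrt(df$row^2 + df$col^2) + df$radius >= R))
        stop("spec error: insert/rod extends outside the phantom disk")
    }
  }
  structure(list(module = module, diameter = diameter,
                 background_hu = background_hu, inserts = inserts,
                 rods = rods, edge = edge),
            class = "phantom_spec")
}

#' Describe phenomenological image degradations
#'
#' The generator reproduces the qualitative artefacts seen on CBCT QA
#' scans rather than modelling their physics: additive white or
#' low-frequency-weighted noise, a Gaussian blur, a radial parabolic
#' cupping field (edge minus centre equals `cupping_amplitude`), a
#' rim-smearing deficit emulating detector-saturation handling, and an
#' additive ghost contour just inside the rim emulating the double
#' contours produced by scan-to-scan geometric instability.
#'
#' @param noise_sigma additive noise SD, HU (>= 0).
#' @param noise_color_exponent 0 = white; > 0 weights low spatial
#'   frequencies as `f^(-exponent/2)` before rescaling to `noise_sigma`.
#' @param blur_sigma Gaussian PSF sigma, mm.
#' @param cupping_amplitude HU; positive means edges read higher than the
#'   centre.
#' @param edge_smear length-2 `c(width, depth)`: a linear HU ramp of the
#'   given depth over `width` mm at the phantom rim.
#' @param double_contour length-2 `c(offset, fraction)`: ghost rim contour
#'   displaced `offset` mm inward, scaled by `fraction` of the rim
#'   contrast.
#' @param seed integer RNG seed; identical spec + seed gives identical
#'   voxels.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(noise_sigma = 0, noise_color_exponent = 0,
                             blur_sigma = 0, cupping_amplitude = 0,
                             edge_smear = c(width = 0, depth = 0),
                             double_contour = c(offset = 0, fraction = 0),
                             seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  structure(list(noise_sigma = noise_sigma,
                 noise_color_exponent = noise_color_exponent,
                 blur_sigma = blur_sigma,
                 cupping_amplitude = cupping_amplitude,
                 edge_smear = unname(edge_smear),
                 double_contour = unname(double_contour),
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

# Anti-aliased disk coverage: fraction of each pixel inside the circle,
# estimated on a sub x sub grid of sample points per pixel. Only pixels
# straddling the boundary are subsampled.
disk_coverage <- function(rr, cc, center, radius, spacing, sub = 4L) {
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, `+`)
  half_diag <- sqrt(sum((spacing[1:2] / 2)^2))
  d <- sqrt(d2)
  cov <- matrix(0, length(rr), length(cc))
  cov[d <= radius - half_diag] <- 1
  idx <- which(abs(d - radius) < half_diag, arr.ind = TRUE)
  if (nrow(idx)) {
    off_r <- ((seq_len(sub) - 0.5) / sub - 0.5) * spacing[1]
    off_c <- ((seq_len(sub) - 0.5) / sub - 0.5) * spacing[2]
    pr <- outer(rr[idx[, 1]], off_r, `+`)  # n x sub
    pc <- outer(cc[idx[, 2]], off_c, `+`)
    acc <- numeric(nrow(idx))
    for (a in seq_len(sub)) for (b in seq_len(sub)) {
      acc <- acc + ((pr[, a] - center[1])^2 + (pc[, b] - center[2])^2 <= radius^2)
    }
    cov[idx] <- acc / (sub * sub)
  }
  cov
}

# Colored (or white) noise field of a given sample SD target.
noise_field <- function(nr, nc, sigma, exponent) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  if (exponent == 0 || sigma == 0) return(w * sigma)
  fr <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  fc <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  f <- sqrt(outer(fr^2, fc^2, `+`))
  f[1, 1] <- min(f[f > 0])  # keep DC finite; it is rescaled away below
  shape <- f^(-exponent / 2)
  x <- Re(fft(fft(w) * shape, inverse = TRUE)) / (nr * nc)
  x <- x - mean(x)
  x * sigma / sqrt(mean(x^2))
}

gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  EBImage::gblur(mat, sigma = sigma_px)
}

#' Render a synthetic phantom volume
#'
#' Builds the ideal HU map (air at -1000 outside the disk; inserts and
#' rods rendered with analytic area-fraction anti-aliasing so noiseless
#' centroids are sub-pixel accurate), then applies degradations in a fixed
#' order: blur, cupping, rim smear, double contour, noise. Noise is drawn
#' independently per slice. The ground truth (spec, degradations, phantom
#' centre and radius in mm) is attached as attribute `"ground_truth"`.
#'
#' @param spec a [phantom_spec()].
#' @param degrade a [degradation_spec()].
#' @param spacing length-3 voxel spacing mm (row, col, slice).
#' @param dims length-3 integer volume dimensions.
#' @return An [image_volume()] with a `ground_truth` attribute.
#' @export
render_phantom <- function(spec, degrade = degradation_spec(),
                           spacing = c(0.4, 0.4, 1), dims = c(512L, 512L, 1L)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(degrade, "degradation_spec"))
  R <- spec$diameter / 2
  fov <- (dims[1:2] - 1) * spacing[1:2]
  if (any(fov < spec$diameter))
    stop("grid does not cover the phantom diameter")
  rr <- (seq_len(dims[1]) - 1) * spacing[1]
  cc <- (seq_len(dims[2]) - 1) * spacing[2]
  ctr <- c(mean(range(rr)), mean(range(cc)))

  base <- matrix(-1000, dims[1], dims[2])
  disk <- disk_coverage(rr, cc, ctr, R, spacing)
  base <- base + disk * (spec$background_hu + 1000)
  objs <- rbind(spec$inserts[c("row", "col", "radius", "hu")],
                spec$rods[c("row", "col", "radius", "hu")])
  if (!is.null(objs) && nrow(objs)) {
    for (k in seq_len(nrow(objs))) {
      cov <- disk_coverage(rr, cc, ctr + c(objs$row[k], objs$col[k]),
                           objs$radius[k], spacing)
      base <- base + cov * (objs$hu[k] - spec$background_hu)
    }
  }
  if (spec$module == "edge") {
    e <- spec$edge
    th <- e$angle * pi / 180
    dmat <- outer(-(rr - ctr[1]) * sin(th), (cc - ctr[2]) * cos(th), `+`)
    base <- ifelse(disk > 0,
                   e$low_hu + (e$high_hu - e$low_hu) * (dmat >= 0) +
                     (dmat == 0) * (e$low_hu - e$high_hu) / 2,
                   base)
  }

  dmask <- sqrt(outer((rr - ctr[1])^2, (cc - ctr[2])^2, `+`))
  inside <- dmask <= R
  sl <- base
  if (degrade$blur_sigma > 0)
    sl <- gaussian_blur(sl, degrade$blur_sigma / mean(spacing[1:2]))
  if (degrade$cupping_amplitude != 0)
    sl <- sl + ifelse(inside, degrade$cupping_amplitude * (dmask / R)^2, 0)
  if (degrade$edge_smear[1] > 0 && degrade$edge_smear[2] != 0) {
    w <- degrade$edge_smear[1]
    ramp <- pmax(0, 1 - (R - dmask) / w)
    sl <- sl + ifelse(inside, degrade$edge_smear[2] * ramp, 0)
  }
  if (degrade$double_contour[1] > 0 && degrade$double_contour[2] != 0) {
    off <- degrade$double_contour[1]
    ghost_w <- mean(spacing[1:2])
    ghost <- exp(-((dmask - (R - off))^2) / (2 * ghost_w^2))
    sl <- sl + degrade$double_contour[2] * (spec$background_hu + 1000) *
      ifelse(inside, ghost, 0)
  }

  vox <- array(0, dims)
  with_seed(degrade$seed, {
    for (k in seq_len(dims[3])) {
      n <- if (degrade$noise_sigma > 0)
        noise_field(dims[1], dims[2], degrade$noise_sigma,
                    degrade$noise_color_exponent)
      else 0
      vox[, , k] <- sl + n
    }
  })
  vol <- image_volume(vox, spacing = spacing)
  gt <- list(spec = spec, degrade = degrade, center_mm = ctr, radius_mm = R)
  if (!is.null(spec$rods))
    gt$rod_centers_mm <- cbind(row = ctr[1] + spec$rods$row,
                               col = ctr[2] + spec$rods$col)
  attr(vol, "ground_truth") <- gt
  vol
}

#' Render a slanted-edge test image
#'
#' The edge passes through the grid centre, tilted `angle` degrees away
#' from the column (vertical) axis. The profile perpendicular to the edge
#' is the analytic Gaussian-convolved step sampled at pixel centres
#' (Gaussian CDF of the signed distance), so the noiseless ESF is exact;
#' noise is added afterwards.
#'
#' @param edge list with `angle` (degrees), `low_hu`, `high_hu`.
#' @param blur_sigma Gaussian PSF sigma, mm.
#' @param noise_sigma additive white noise SD, HU.
#' @param spacing,dims grid geometry as in [render_phantom()].
#' @param seed RNG seed for the noise.
#' @return An [image_volume()] with a `ground_truth` attribute.
#' @export
render_edge <- function(edge = list(angle = 3, low_hu = 0, high_hu = 1000),
                        blur_sigma = 0.5, noise_sigma = 0,
                        spacing = c(0.4, 0.4, 1), dims = c(512L, 512L, 1L),
                        seed = 1L) {
  if (edge$angle == 0)
    warning("edge angle 0: no sub-pixel phase diversity for oversampling")
  th <- edge$angle * pi / 180
  rr <- (seq_len(dims[1]) - 1) * spacing[1]
  cc <- (seq_len(dims[2]) - 1) * spacing[2]
  ctr <- c(mean(range(rr)), mean(range(cc)))
  # signed perpendicular distance to the edge line
  d <- outer(-(rr - ctr[1]) * sin(th), (cc - ctr[2]) * cos(th), `+`)
  esf <- if (blur_sigma > 0) pnorm(d / blur_sigma) else (d > 0) + 0.5 * (d == 0)
  sl <- edge$low_hu + (edge$high_hu - edge$low_hu) * esf
  vox <- array(0, dims)
  with_seed(seed, {
    for (k in seq_len(dims[3])) {
      n <- if (noise_sigma > 0) matrix(rnorm(dims[1] * dims[2], 0, noise_sigma),
                                       dims[1], dims[2]) else 0
      vox[, , k] <- sl + n
    }
  })
  vol <- image_volume(vox, spacing = spacing)
  attr(vol, "ground_truth") <- list(edge = edge, blur_sigma = blur_sigma,
                                    noise_sigma = noise_sigma, center_mm = ctr)
  vol
}
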