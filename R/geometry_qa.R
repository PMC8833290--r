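#' Gantry angle schedule of a calibration procedure
#'
#' Inclusive arithmetic sequence of projection-view angles. The default
#' calibration orbit of 520 degrees sampled in 10-degree steps yields 53
#' views. If `step` does not divide `range`, the last view sits at the
#' largest multiple of `step` not exceeding `range` and a warning is
#' raised.
#'
#' @param start first angle, degrees.
#' @param range angular range, degrees (>= 0).
#' @param step step between views, degrees (> 0).
#' @return Numeric vector of angles, `floor(range/step) + 1` values.
#' @export
calibration_schedule <- function(start = 0, range = 520, step = 10) {
  if (step <= 0) stop("`step` must be > 0")
  if (range < 0) stop("`range` must be >= 0")
  n <- floor(range / step + 1e-9) + 1
  if (abs(range / step - round(range / step)) > 1e-9)
    warning("step does not divide range; last view at ",
            start + (n - 1) * step, " degrees")
  start + (seq_len(n) - 1) * step
}

#' Reproducibility statistics of repeated calibrations
#'
#' Quantifies run-to-run stability of the nine gantry-angle-dependent
#' corrections over an ensemble of calibration runs:
#' \itemize{
#'   \item `overall`: per correction and rotation direction, the mean and
#'     SD over the pooled (angle, run) samples — i.e. over the entire
#'     orbit and all runs (`pool = "run_means"` instead takes the SD over
#'     per-run orbit means).
#'   \item `per_angle_sd`: per direction, the sample SD (n - 1) across
#'     runs of each correction at each angle.
#'   \item `summary`: max, mean and SD of the per-angle SDs.
#'   \item `hysteresis`: per angle, the absolute value of the CW - CCW
#'     difference first computed per run and then averaged over runs
#'     (absolute value taken after averaging). Present when both rotation
#'     directions are supplied.
#' }
#'
#' @param records list of [calibration_record()] objects sharing one angle
#'   grid; at least two runs.
#' @param pool `"samples"` (default) or `"run_means"`, see above.
#' @return An object of class `calibration_stats`.
#' @export
calibration_stats <- function(records, pool = c("samples", "run_means")) {
  pool <- match.arg(pool)
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, TRUE, "calibration_record")))
  angles <- records[[1]]$angles
  for (r in records)
    if (!isTRUE(all.equal(r$angles, angles)))
      stop("alignment error: calibration records use different angle grids")
  dirs <- vapply(records, `[[`, "", "direction")
  runs <- vapply(records, function(r) as.character(r$run_id), "")
  if (length(unique(paste(runs, dirs))) < length(records))
    stop("duplicate (run_id, direction) records")
  if (min(table(dirs)) < 2L && length(unique(dirs)) == 1L && length(records) < 2L)
    stop("need >= 2 runs")

  per_dir <- function(d) {
    recs <- records[dirs == d]
    arr <- simplify2array(lapply(recs, `[[`, "corrections"))  # angle x 9 x run
    overall <- data.frame(
      correction = CORRECTION_NAMES, direction = d,
      mean = apply(arr, 2, mean),
      sd = if (pool == "samples") apply(arr, 2, sd)
           else apply(apply(arr, c(2, 3), mean), 1, sd),
      row.names = NULL)
    sd_ang <- apply(arr, c(1, 2), sd)  # angle x 9, n-1 across runs
    list(overall = overall, per_angle_sd = sd_ang,
         summary = data.frame(
           correction = CORRECTION_NAMES, direction = d,
           max_angle_sd = apply(sd_ang, 2, max),
           mean_angle_sd = apply(sd_ang, 2, mean),
           sd_angle_sd = apply(sd_ang, 2, sd), row.names = NULL))
  }
  present <- unique(dirs)
  if (any(table(dirs)[present] < 2L))
    stop("need >= 2 runs per rotation direction")
  parts <- lapply(present, per_dir)
  names(parts) <- present

  hyst <- NULL
  if (all(c("cw", "ccw") %in% present)) {
    cw <- records[dirs == "cw"]
    ccw <- records[dirs == "ccw"]
    cw <- cw[order(vapply(cw, function(r) as.character(r$run_id), ""))]
    ccw <- ccw[order(vapply(ccw, function(r) as.character(r$run_id), ""))]
    ids_cw <- vapply(cw, function(r) as.character(r$run_id), "")
    ids_ccw <- vapply(ccw, function(r) as.character(r$run_id), "")
    common <- intersect(ids_cw, ids_ccw)
    if (length(common)) {
      diffs <- simplify2array(lapply(common, function(id) {
        cw[[match(id, ids_cw)]]$corrections - ccw[[match(id, ids_ccw)]]$corrections
      }))
      hyst <- abs(apply(diffs, c(1, 2), mean))  # |mean over runs|, per angle
      dimnames(hyst) <- list(NULL, CORRECTION_NAMES)
    }
  }
  structure(list(angles = angles,
                 overall = do.call(rbind, lapply(parts, `[[`, "overall")),
                 per_angle_sd = lapply(parts, `[[`, "per_angle_sd"),
                 summary = do.call(rbind, lapply(parts, `[[`, "summary")),
                 hysteresis = hyst, n_records = length(records),
                 pool = pool),
            class = "calibration_stats")
}

#' Read / write calibration runs as CSV
#'
#' Long format with columns `run_id`, `direction`, `angle_deg` and the
#' nine corrections `tSx ... rz`.
#'
#' @param records list of [calibration_record()] objects.
#' @param path CSV path.
#' @return `read_calibration_csv` returns a list of records;
#'   `write_calibration_csv` returns `path` invisibly.
#' @export
write_calibration_csv <- function(records, path) {
  rows <- lapply(records, function(r)
    data.frame(run_id = r$run_id, direction = r$direction,
               angle_deg = r$angles, r$corrections, check.names = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("run_id", "direction", "angle_deg", CORRECTION_NAMES)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("calibration CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  keys <- unique(df[c("run_id", "direction")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$run_id == keys$run_id[i] & df$direction == keys$direction[i], ]
    sub <- sub[order(sub$angle_deg), ]
    m <- as.matrix(sub[CORRECTION_NAMES])
    dimnames(m) <- list(NULL, CORRECTION_NAMES)
    calibration_record(keys$run_id[i], keys$direction[i], sub$angle_deg, m)
  })
}

#' Detect cylindrical rods on a phantom slice
#'
#' Threshold-based detection: the background level is estimated as the
#' slice median (the phantom is assumed to fill most of the field of
#' view), the rod plateau as an extreme quantile, and the threshold is set
#' halfway between the two. Connected components above threshold are
#' labelled; the `n_rods` largest by area are kept and their
#' intensity-weighted centroids returned in mm.
#'
#' @param vol an [image_volume()].
#' @param slice_index slice to analyse.
#' @param polarity `"bright"` for rods denser than background, `"dark"`
#'   otherwise.
#' @param n_rods number of rods expected.
#' @return Numeric matrix `n_rods x 2` of (row, col) centroids in mm,
#'   ordered by row then column.
#' @export
detect_rods <- function(vol, slice_index = 1L,
                        polarity = c("bright", "dark"), n_rods = 4L) {
  polarity <- match.arg(polarity)
  img <- vol$voxels[, , slice_index]
  if (polarity == "dark") img <- -img
  bkg <- median(img)
  plateau <- quantile(img, 0.999, names = FALSE)
  thr <- (bkg + plateau) / 2
  bw <- img > thr
  labels <- EBImage::bwlabel(bw)
  n_comp <- max(labels)
  if (n_comp < n_rods)
    stop("detection error: found ", n_comp, " component(s), expected ",
         n_rods, " rods")
  areas <- tabulate(labels[labels > 0], nbins = n_comp)
  keep <- order(areas, decreasing = TRUE)[seq_len(n_rods)]
  rr <- row_coords(vol)
  cc <- col_coords(vol)
  centers <- t(vapply(keep, function(lb) {
    idx <- which(labels == lb, arr.ind = TRUE)
    w <- pmax(img[idx] - bkg, 0)
    c(sum(rr[idx[, 1]] * w), sum(cc[idx[, 2]] * w)) / sum(w)
  }, numeric(2)))
  colnames(centers) <- c("row", "col")
  centers[order(centers[, "row"], centers[, "col"]), , drop = FALSE]
}

#' Imaging fidelity from rod centres
#'
#' Compares the six pairwise Euclidean distances between the four rod
#' centres (four sides and two diagonals of the nominal square) with
#' their nominal values. Measured and nominal distances are matched by
#' rank order, which is unambiguous for the two distinct nominal lengths
#' of a square layout.
#'
#' @param centers numeric `4 x 2` matrix of (row, col) rod centres, mm.
#' @param nominal six nominal pair distances in mm; default the 50 mm
#'   square (four sides, two diagonals).
#' @return An object of class `fidelity_result` with fields `rod_centers`,
#'   `pair_distances` (data.frame of measured and matched nominal),
#'   `mean_abs_error` and `sd_abs_error` (mm).
#' @export
imaging_fidelity <- function(centers,
                             nominal = c(rep(50, 4), rep(50 * sqrt(2), 2))) {
  centers <- as.matrix(centers)
  if (nrow(centers) != 4L || ncol(centers) != 2L)
    stop("exactly four (row, col) centres required")
  if (length(nominal) != 6L) stop("six nominal pair distances required")
  pairs <- t(combn(4L, 2L))
  d <- sqrt(rowSums((centers[pairs[, 1], ] - centers[pairs[, 2], ])^2))
  ord_m <- order(d)
  ord_n <- order(nominal)
  # rank matching requires the distinct nominal lengths to separate cleanly
  sn <- sort(nominal)
  gaps <- diff(sn)
  if (any(gaps > 0 & gaps < 1e-9))
    stop("matching error: degenerate nominal layout")
  err <- abs(d[ord_m] - sn)
  structure(list(rod_centers = centers,
                 pair_distances = data.frame(
                   pair = paste(pairs[ord_m, 1], pairs[ord_m, 2], sep = "-"),
                   measured = d[ord_m], nominal = sn, abs_error = err),
                 mean_abs_error = mean(err),
                 sd_abs_error = sd(err)),
            class = "fidelity_result")
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat(sprintf("<fidelity_result> mean |error| %.4f mm (SD %.4f mm) over 6 rod pairings\n",
              x$mean_abs_error, x$sd_abs_error))
  invisible(x)
}
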