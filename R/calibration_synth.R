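# Names of the nine gantry-angle-dependent geometric corrections:
# translations of the focal spot (tS*) and detector midpoint (tC*) in mm,
# and Euler rotations of the detector row/column vectors in degrees.
CORRECTION_NAMES <- c("tSx", "tSy", "tSz", "tCx", "tCy", "tCz",
                      "rx", "ry", "rz")

expand9 <- function(x, what) {
  if (is.null(names(x)) && length(x) == 1L) x <- rep(x, 9L)
  out <- setNames(numeric(9L), CORRECTION_NAMES)
  if (is.null(names(x))) {
    if (length(x) != 9L) stop(what, " must have 9 values or be named")
    out[] <- x
  } else {
    bad <- setdiff(names(x), CORRECTION_NAMES)
    if (length(bad)) stop(what, ": unknown correction(s) ", paste(bad, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

#' Describe a simulated geometric-calibration ensemble
#'
#' Emulates repeated flexmap calibrations of a ring-gantry CBCT scanner:
#' each of the nine corrections has a systematic offset, a smooth
#' (sinusoidal, 360-degree period) angular modulation, run-to-run Gaussian
#' fluctuation at every angle, and a clockwise/counter-clockwise
#' hysteresis split evenly between the two rotation directions. Defaults
#' reflect the magnitudes reported for a mobile ring-gantry unit:
#' systematic offsets up to 11.5 mm (tCz) and 0.64 deg (rx), per-angle
#' fluctuation SDs of 0.6 (tSy) to 3.0 mm (tSz), and direction hysteresis
#' up to 4.6 mm (tSz).
#'
#' @param n_runs number of calibration repetitions (>= 1).
#' @param angle_start,angle_stop,angle_step gantry schedule in degrees;
#'   defaults give the 520-degree orbit sampled in 10-degree steps.
#' @param offsets,mod_amplitude,fluct_sd,hysteresis length-9 (or named
#'   partial) numeric vectors over
#'   `tSx, tSy, tSz, tCx, tCy, tCz, rx, ry, rz`; mm for translations,
#'   degrees for rotations.
#' @param seed integer RNG seed.
#' @return An object of class `calibration_sim_spec`.
#' @export
calibration_sim_spec <- function(n_runs = 8L, angle_start = 0,
                                 angle_stop = 520, angle_step = 10,
                                 offsets = c(tSx = 2.0, tSy = 0.5, tSz = 6.0,
                                             tCx = 3.0, tCy = 0, tCz = 11.5,
                                             rx = 0.64, ry = 0.2, rz = 0.05),
                                 mod_amplitude = c(tSx = 0.5, tSy = 0.3,
                                                   tSz = 1.0, tCx = 0.5,
                                                   tCy = 0.3, tCz = 1.0,
                                                   rx = 0.05, ry = 0.05,
                                                   rz = 0.01),
                                 fluct_sd = c(tSx = 1.0, tSy = 0.6, tSz = 3.0,
                                              tCx = 1.0, tCy = 0.8, tCz = 2.1,
                                              rx = 0.06, ry = 0.23, rz = 0.039),
                                 hysteresis = c(tSx = 0.5, tSy = 0.3, tSz = 4.6,
                                                tCx = 0.5, tCy = 0.3, tCz = 3.1,
                                                rx = 0.05, ry = 0.3, rz = 0.02),
                                 seed = 1L) {
  fl <- expand9(fluct_sd, "fluct_sd")
  if (any(fl < 0)) stop("fluctuation SDs must be >= 0")
  structure(list(n_runs = as.integer(n_runs), angle_start = angle_start,
                 angle_stop = angle_stop, angle_step = angle_step,
                 offsets = expand9(offsets, "offsets"),
                 mod_amplitude = expand9(mod_amplitude, "mod_amplitude"),
                 fluct_sd = fl,
                 hysteresis = expand9(hysteresis, "hysteresis"),
                 seed = as.integer(seed)),
            class = "calibration_sim_spec")
}

#' Construct a calibration record
#'
#' One flexmap calibration run for one gantry rotation direction: the nine
#' corrections tabulated per gantry angle.
#'
#' @param run_id identifier of the run.
#' @param direction `"cw"` or `"ccw"`.
#' @param angles strictly increasing gantry angles, degrees.
#' @param corrections numeric matrix `length(angles) x 9` with columns
#'   `tSx, tSy, tSz, tCx, tCy, tCz, rx, ry, rz`.
#' @return An object of class `calibration_record`.
#' @export
calibration_record <- function(run_id, direction = c("cw", "ccw"),
                               angles, corrections) {
  direction <- match.arg(direction)
  corrections <- as.matrix(corrections)
  if (is.null(colnames(corrections))) colnames(corrections) <- CORRECTION_NAMES
  if (!identical(colnames(corrections), CORRECTION_NAMES))
    stop("corrections must have columns ", paste(CORRECTION_NAMES, collapse = ", "))
  if (nrow(corrections) != length(angles))
    stop("one correction row per angle required")
  if (any(diff(angles) <= 0)) stop("angles must be strictly increasing")
  structure(list(run_id = run_id, direction = direction,
                 angles = as.numeric(angles), corrections = corrections),
            class = "calibration_record")
}

#' Simulate an ensemble of calibration runs
#'
#' Produces one clockwise and one counter-clockwise
#' [calibration_record()] per run. The deterministic part (offset +
#' angular modulation +/- half the hysteresis) is the ground truth,
#' attached as attribute `"ground_truth"` of the returned list.
#'
#' @param spec a [calibration_sim_spec()].
#' @return List of `2 * n_runs` calibration records, CW and CCW per run.
#' @export
simulate_calibration_runs <- function(spec) {
  stopifnot(inherits(spec, "calibration_sim_spec"))
  angles <- calibration_schedule(spec$angle_start,
                                 spec$angle_stop - spec$angle_start,
                                 spec$angle_step)
  na <- length(angles)
  phases <- (seq_len(9L) - 1) * 40  # fixed per-correction modulation phases
  det_part <- sapply(seq_len(9L), function(k) {
    spec$offsets[k] +
      spec$mod_amplitude[k] * sin(2 * pi * (angles + phases[k]) / 360)
  })
  colnames(det_part) <- CORRECTION_NAMES
  records <- vector("list", 2L * spec$n_runs)
  with_seed(spec$seed, {
    i <- 0L
    for (run in seq_len(spec$n_runs)) {
      for (dir in c("cw", "ccw")) {
        sgn <- if (dir == "cw") +0.5 else -0.5
        noise <- sapply(seq_len(9L), function(k) rnorm(na, 0, spec$fluct_sd[k]))
        corr <- det_part +
          matrix(spec$hysteresis * sgn, na, 9L, byrow = TRUE) + noise
        colnames(corr) <- CORRECTION_NAMES
        i <- i + 1L
        records[[i]] <- calibration_record(run, dir, angles, corr)
      }
    }
  })
  attr(records, "ground_truth") <- list(spec = spec, angles = angles,
                                        deterministic_cw = det_part +
                                          matrix(spec$hysteresis / 2, na, 9L, byrow = TRUE),
                                        deterministic_ccw = det_part -
                                          matrix(spec$hysteresis / 2, na, 9L, byrow = TRUE))
  records
}

#' Simulate a pencil-chamber dose-length-product table
#'
#' Builds the five DLP readings (one central, four peripheral drill holes
#' of the body dosimetry phantom, 10 cm chamber) whose weighted
#' combination equals `true_cbdi` exactly before noise: the central DLP is
#' `3 L true_cbdi / (1 + 2 ratio)` and each peripheral DLP is `ratio`
#' times that.
#'
#' @param true_cbdi ground-truth weighted cone-beam dose index, mGy.
#' @param peripheral_to_central_ratio DLP ratio peripheral / central
#'   (> 0); air-prefiltered protocols can reach about 2.3.
#' @param noise_cv multiplicative Gaussian noise CV applied per reading.
#' @param seed RNG seed.
#' @param chamber_length_cm pencil chamber length, cm.
#' @return A dose table as produced by [dose_table()], with the ground
#'   truth attached as attribute `"ground_truth"`.
#' @export
simulate_dlp <- function(true_cbdi, peripheral_to_central_ratio = 1,
                         noise_cv = 0, seed = 1L, chamber_length_cm = 10) {
  if (peripheral_to_central_ratio <= 0) stop("ratio must be > 0")
  L <- chamber_length_cm
  central <- 3 * L * true_cbdi / (1 + 2 * peripheral_to_central_ratio)
  periph <- rep(central * peripheral_to_central_ratio, 4L)
  dlp <- c(central, periph)
  if (noise_cv > 0)
    dlp <- with_seed(seed, dlp * (1 + rnorm(5L, 0, noise_cv)))
  tab <- dose_table(central = dlp[1], peripheral = dlp[2:5],
                    chamber_length_cm = L)
  attr(tab, "ground_truth") <- list(true_cbdi = true_cbdi,
                                    ratio = peripheral_to_central_ratio,
                                    noise_cv = noise_cv)
  tab
}
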