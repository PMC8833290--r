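#' Construct a pencil-chamber DLP table
#'
#' One measurement of the body dosimetry phantom: the dose-length
#' products read in the central and the four peripheral drill holes with
#' a pencil ionization chamber.
#'
#' @param central central-hole DLP, mGy cm.
#' @param peripheral length-4 numeric of peripheral DLPs, mGy cm.
#' @param chamber_length_cm chamber length, cm (data, not a constant, so
#'   other chambers are representable).
#' @return data.frame of class `dose_table` with columns `position`,
#'   `dlp_mGy_cm`, `chamber_length_cm`.
#' @export
dose_table <- function(central, peripheral, chamber_length_cm = 10) {
  if (length(central) != 1L || length(peripheral) != 4L)
    stop("schema error: need one central and four peripheral DLPs")
  if (any(c(central, peripheral) < 0)) stop("DLPs must be >= 0")
  out <- data.frame(
    position = c("central", paste0("peripheral_", 1:4)),
    dlp_mGy_cm = c(central, peripheral),
    chamber_length_cm = chamber_length_cm)
  class(out) <- c("dose_table", "data.frame")
  out
}

#' Read a DLP table from CSV
#'
#' Expects columns `position` (`central`, `peripheral_1..4`),
#' `dlp_mGy_cm`, `chamber_length_cm`.
#'
#' @param path CSV path.
#' @return A [dose_table()].
#' @export
read_dose_table <- function(path) {
  df <- read.csv(path)
  need <- c("position", "dlp_mGy_cm", "chamber_length_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  pos <- c("central", paste0("peripheral_", 1:4))
  if (!setequal(df$position, pos))
    stop("schema error: positions must be ", paste(pos, collapse = ", "))
  df <- df[match(pos, df$position), ]
  dose_table(df$dlp_mGy_cm[1], df$dlp_mGy_cm[2:5], df$chamber_length_cm[1])
}

#' Weighted cone-beam dose index
#'
#' `CBDI_w = DLP_central / (3 L) + 2 * mean(DLP_peripheral) / (3 L)` with
#' `L` the chamber length: one third central plus two thirds mean
#' peripheral point dose over the chamber. When several replicate tables
#' are supplied the replicate mean and (n - 1) SD are reported.
#'
#' @param tables a single [dose_table()] or a list of replicates.
#' @return An object of class `cbdi_result`: `cbdi_w` (mGy; replicate
#'   mean), `sd` (NA for a single table), `replicates`, `dlp_central`,
#'   `dlp_peripheral_mean` (replicate means, mGy cm),
#'   `peripheral_to_central_ratio`, `n`.
#' @export
cbdi_w <- function(tables) {
  if (inherits(tables, "dose_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "dose_table")))
  one <- function(tab) {
    miss <- setdiff(c("central", paste0("peripheral_", 1:4)), tab$position)
    if (length(miss)) stop("schema error: missing position(s) ",
                           paste(miss, collapse = ", "))
    L <- tab$chamber_length_cm[1]
    dc <- tab$dlp_mGy_cm[tab$position == "central"]
    dp <- mean(tab$dlp_mGy_cm[grepl("^peripheral_", tab$position)])
    c(cbdi = dc / (3 * L) + 2 * dp / (3 * L), dc = dc, dp = dp,
      ratio = if (dc > 0) dp / dc else NA_real_)
  }
  m <- vapply(tables, one, numeric(4))
  structure(list(cbdi_w = mean(m["cbdi", ]),
                 sd = if (ncol(m) > 1L) sd(m["cbdi", ]) else NA_real_,
                 replicates = unname(m["cbdi", ]),
                 dlp_central = mean(m["dc", ]),
                 dlp_peripheral_mean = mean(m["dp", ]),
                 peripheral_to_central_ratio = mean(m["ratio", ]),
                 n = ncol(m)),
            class = "cbdi_result")
}

#' @export
print.cbdi_result <- function(x, ...) {
  cat(sprintf("<cbdi_result> CBDI_w = %.3f mGy", x$cbdi_w))
  if (!is.na(x$sd)) cat(sprintf(" +/- %.3f (n = %d)", x$sd, x$n))
  cat(sprintf("; peripheral/central DLP ratio %.3f\n",
              x$peripheral_to_central_ratio))
  invisible(x)
}

QA_METRICS <- c("cbdi_w_mGy", "cnr_ldpe", "cnr_polystyrene", "cnr_delrin",
                "nonuniformity_lateral_hu", "nonuniformity_ap_hu",
                "sigma_nps_hu", "noise_at_1mGy_hu",
                "fidelity_mean_mm", "fidelity_sd_mm", "f_lim_lp_cm")

#' Assemble a per-protocol QA report
#'
#' Collects the per-protocol metric outputs into one table mirroring the
#' usual QA overview layout (dose index, CNR triplet, lateral/AP
#' non-uniformity, noise raw and dose-normalized, imaging fidelity,
#' limiting frequency). Each metric may be a numeric vector of
#' replicates, aggregated to mean, (n - 1) SD and n. Metrics never
#' supplied are reported as explicit `NA`, not dropped; supplying the
#' same metric twice for one protocol is a collision error.
#'
#' @param metrics named list: one element per protocol, itself a named
#'   list of numeric vectors over the metric names
#'   `cbdi_w_mGy, cnr_ldpe, cnr_polystyrene, cnr_delrin,
#'   nonuniformity_lateral_hu, nonuniformity_ap_hu, sigma_nps_hu,
#'   noise_at_1mGy_hu, fidelity_mean_mm, fidelity_sd_mm, f_lim_lp_cm`.
#' @param run_info optional list of run metadata (seed, input hashes,
#'   versions) stored with the report.
#' @return An object of class `qa_report`: `table` (one row per protocol
#'   and metric: mean, sd, n) and `run_info`.
#' @export
assemble_report <- function(metrics, run_info = list()) {
  if (is.null(names(metrics)) || any(names(metrics) == ""))
    stop("each protocol must be named")
  if (anyDuplicated(names(metrics)))
    stop("collision error: duplicate protocol ",
         names(metrics)[duplicated(names(metrics))][1])
  rows <- do.call(rbind, lapply(names(metrics), function(p) {
    entry <- metrics[[p]]
    if (length(entry) && (is.null(names(entry)) || any(names(entry) == "")))
      stop("metrics for protocol ", p, " must be named")
    if (anyDuplicated(names(entry)))
      stop("collision error: duplicate metric '",
           names(entry)[duplicated(names(entry))][1],
           "' for protocol ", p)
    bad <- setdiff(names(entry), QA_METRICS)
    if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
    do.call(rbind, lapply(QA_METRICS, function(m) {
      v <- entry[[m]]
      data.frame(protocol = p, metric = m,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1L) sd(v) else NA_real_,
                 n = length(v))
    }))
  }))
  structure(list(table = rows,
                 run_info = c(run_info,
                              list(package_version =
                                     as.character(utils::packageVersion("cbctqa"))))),
            class = "qa_report")
}

#' Write / read a QA report
#'
#' JSON round-trips the full report (table plus run metadata); CSV writes
#' the flat table only.
#'
#' @param report a `qa_report`.
#' @param path output path.
#' @return `read_qa_report` returns a `qa_report`; the writers return
#'   `path` invisibly.
#' @export
write_qa_report_json <- function(report, path) {
  jsonlite::write_json(list(table = report$table, run_info = report$run_info),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_qa_report_json
#' @export
write_qa_report_csv <- function(report, path) {
  write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qa_report_json
#' @export
read_qa_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- x$table
  tab$mean <- as.numeric(tab$mean)
  tab$sd <- as.numeric(tab$sd)
  structure(list(table = tab, run_info = x$run_info), class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report>", length(unique(x$table$protocol)), "protocol(s)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
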