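# Shared fixtures, built in code at test time.

# Small uniform-module volume with white noise, for NPS tests.
noisy_uniform_volume <- function(sigma = 20, seed = 7, n_slices = 8L,
                                 exponent = 0) {
  render_phantom(phantom_spec("uniform"),
                 degradation_spec(noise_sigma = sigma,
                                  noise_color_exponent = exponent,
                                  seed = seed),
                 spacing = c(0.4, 0.4, 1),
                 dims = c(512L, 512L, n_slices))
}

# Naive two-loop oracle for calibration statistics (pooled variant).
calibration_stats_oracle <- function(records) {
  dirs <- vapply(records, `[[`, "", "direction")
  out <- list()
  for (d in unique(dirs)) {
    recs <- records[dirs == d]
    na <- length(recs[[1]]$angles)
    for (k in cbctqa:::CORRECTION_NAMES) {
      vals <- c()
      per_angle_sd <- numeric(na)
      for (a in seq_len(na)) {
        v <- vapply(recs, function(r) r$corrections[a, k], 0)
        vals <- c(vals, v)
        per_angle_sd[a] <- sd(v)
      }
      out[[paste(d, k)]] <- list(mean = mean(vals), sd = sd(vals),
                                 per_angle_sd = per_angle_sd)
    }
  }
  out
}

# Hand-built 4x2 rod centre matrix for a square of side `side` centred at
# (r0, c0).
square_centers <- function(side = 50, r0 = 0, c0 = 0) {
  h <- side / 2
  m <- rbind(c(r0 - h, c0 - h), c(r0 - h, c0 + h),
             c(r0 + h, c0 - h), c(r0 + h, c0 + h))
  colnames(m) <- c("row", "col")
  m
}

# Reorder detected centres to correspond row-by-row with nominal centres
# (nearest neighbour; detection order is deterministic but ties in noisy
# row coordinates can swap labels).
match_centers <- function(found, nominal) {
  found[apply(nominal, 1, function(p)
    which.min(colSums((t(found) - p)^2))), , drop = FALSE]
}

# Brute-force pairwise-distance oracle.
pairwise_distances <- function(centers) {
  out <- c()
  for (i in 1:3) for (j in (i + 1):4)
    out <- c(out, sqrt(sum((centers[i, ] - centers[j, ])^2)))
  sort(out)
}
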