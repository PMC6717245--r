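# shared fixtures and independent oracles

# brute-force probability-of-localization oracle: nested loops over
# source-level samples and grid cells, nothing shared with the implementation
brute_force_p_l <- function(sl, tl, nl_minute, thr) {
  n_cell <- nrow(tl)
  cell_p <- numeric(n_cell)
  for (cell in seq_len(n_cell)) {
    hits <- 0L
    for (s in sl) {
      snrs <- numeric(ncol(tl))
      for (i in seq_len(ncol(tl)))
        snrs[i] <- s - tl[cell, i] - nl_minute[i]
      if (min(snrs) > thr) hits <- hits + 1L
    }
    cell_p[cell] <- hits / length(sl)
  }
  mean(cell_p)
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  w_all <- apply(idx, 2, function(k) sum(r[k])) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# a small hand-built sighting table: 5 pods, varying conditions
five_pod_sightings <- function() {
  data.frame(
    pod_id = c("A", "A", "B", "C", "C", "C", "D", "E"),
    time_s = c(10, 50, 20, 5, 40, 80, 30, 60),
    range_m = c(1000, 2000, 800, 3000, 3200, 3400, 1500, 2500),
    group_size = c(1, 2, 3, 2, 2, 4, 1, 2),
    direction = c("south", "south", "south", "south", "south", "south",
                  "north", "south"),
    beaufort = c(2, 2, 5, 1, 1, 1, 2, 3),
    visibility = c(2, 2, 2, 3, 3, 3, 2, 6),
    stringsAsFactors = FALSE)
}

# hourly blow counts from event times (seconds), binned by hour of day
hourly_blow_counts <- function(time_s, n_days = 1L) {
  hour <- floor((time_s %% 86400) / 3600)
  as.numeric(table(factor(hour, levels = 0:23)))
}
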