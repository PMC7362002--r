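# Independent oracles and fixture builders used across the suite.

# Brute-force percent-area-NETs: explicit nested pixel loop.
pan_bruteforce <- function(red, blue) {
  n <- 0L
  for (i in seq_len(nrow(red))) {
    for (j in seq_len(ncol(red))) {
      if (red[i, j] && !blue[i, j]) n <- n + 1L
    }
  }
  100 * n / length(red)
}

# Exhaustive between-class-variance search over the 256-bin edges of a
# plane's range, computed from the raw pixels (not histogram moments).
otsu_bruteforce <- function(plane, n_bins = 256L) {
  x <- as.numeric(plane)
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  best_t <- NA_real_; best_v <- -Inf
  for (t in edges[2:n_bins]) {
    fg <- x[x > t]; bg <- x[x <= t]
    if (length(fg) == 0L || length(bg) == 0L) next
    w0 <- length(bg) / length(x)
    v <- w0 * (1 - w0) * (mean(bg) - mean(fg))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Logical mask with a filled digital disk.
disk_mask <- function(nr, nc, cy, cx, radius) {
  d <- sqrt(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+"))
  d <= radius
}

# A small noiseless field with one uniform-intensity disk per channel spec;
# handy for exact-value tests of measurement and classification.
uniform_disk_field <- function(blue_val, red_val, green_val = 0,
                               nr = 64, nc = 64, radius = 10,
                               background = 0, pixel_size_um = 0.5) {
  m <- disk_mask(nr, nc, nr / 2, nc / 2, radius)
  mk <- function(v) {
    p <- matrix(background, nr, nc)
    p[m] <- background + v
    p
  }
  list(field = multichannel_field(mk(blue_val), mk(red_val), mk(green_val),
                                  pixel_size_um = pixel_size_um),
       mask = m)
}

# Default-conditions generator panel reused by recovery tests.
recovery_panel_seeds <- function(n = 20L) 100L + seq_len(n)
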