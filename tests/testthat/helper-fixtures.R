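# Shared fixtures. Small sections (1500 px wide, ~135 basal cells) are
# used for unit/property tests; the acceptance suite builds full-size
# sections once and caches them (helper-acceptance.R).

small_geometry <- function(width = 1500) section_geometry(width = width)

# render non-overlapping discs into a blank field (segmentation oracle)
render_discs <- function(centres, radii, value = 600, H = 120, W = 300,
                         noise_sd = 2, seed = 1) {
  set.seed(seed)
  img <- matrix(0, H, W)
  for (k in seq_len(nrow(centres))) {
    xc <- centres[k, 1]; yc <- centres[k, 2]; r <- radii[k]
    for (x in max(0, floor(xc - r)):min(W - 1, ceiling(xc + r)))
      for (y in max(0, floor(yc - r)):min(H - 1, ceiling(yc + r)))
        if ((x - xc)^2 + (y - yc)^2 <= r^2) img[y + 1, x + 1] <- value
  }
  pmax(img + rnorm(H * W, sd = noise_sd), 0)
}

# Gaussian PLA-like spot field over a given label mask
render_spots <- function(pts, H = 80, W = 80, amp = 900, sigma = 1.1) {
  img <- matrix(0, H, W)
  for (k in seq_len(nrow(pts))) {
    for (dx in -3:3) for (dy in -3:3) {
      x <- pts[k, 1] + dx; y <- pts[k, 2] + dy
      if (x >= 0 && x < W && y >= 0 && y < H)
        img[y + 1, x + 1] <- img[y + 1, x + 1] +
          amp * exp(-(dx^2 + dy^2) / (2 * sigma^2))
    }
  }
  img
}

as_label_map <- function(m) structure(m, class = c("label_map", "matrix"))

# toy marker lists used across the markerset tests
toy_collection <- function() {
  marker_list_collection(
    list(hu1 = c("KRT15", "ITGB1", "XPC", "COL17A1"),
         hu2 = c("KRT15", "ITGB1", "TP63"),
         mo1 = c("Krt15", "Itgb1", "Lgr6", "Col17a1"),
         mo2 = c("Krt15", "Lgr6", "Sox2")),
    species = c("human", "human", "mouse", "mouse"))
}
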