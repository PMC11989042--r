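# Nuclear segmentation and per-cell intensity extraction.
#
# The manual per-cell segmentation of the original workflow is replaced
# by a standard blob/watershed pipeline; a precomputed label image can
# be supplied downstream instead, so external (manual) masks remain
# usable.

#' Segment nuclei in a nuclear-stain channel
#'
#' Gaussian smoothing, global (Otsu) thresholding and a
#' distance-transform watershed to split touching nuclei. Deterministic
#' for fixed input and parameters.
#'
#' @param nuclear_channel 2D non-negative matrix.
#' @param params list: `sigma` (smoothing, px), `threshold` (`"otsu"` or
#'   a number; the Otsu value is relaxed by `threshold_scale` to keep
#'   dim nuclei), `threshold_scale`, `min_area` (px),
#'   `min_peak_separation` (px; also sets the watershed merge
#'   tolerance), and `merge_small` (px; watershed fragments below this
#'   area rejoin the nearest touching label).
#' @return An integer label matrix (`label_map`): 0 background, labels
#'   `1..N` contiguous, each of area >= `min_area`.
#' @export
segment_nuclei <- function(nuclear_channel,
                           params = list()) {
  p <- utils::modifyList(list(sigma = 1, threshold = "otsu",
                              threshold_scale = 1, min_area = 15,
                              min_peak_separation = 5, merge_small = 25),
                         params)
  if (!is.matrix(nuclear_channel) || !is.numeric(nuclear_channel))
    stop("nuclear_channel must be a 2D numeric matrix")
  if (min(nuclear_channel) < 0)
    stop("nuclear_channel must be non-negative")
  if (max(nuclear_channel) == 0)
    return(structure(matrix(0L, nrow(nuclear_channel), ncol(nuclear_channel)),
                     class = c("label_map", "matrix")))
  sm <- as.matrix(EBImage::gblur(nuclear_channel, sigma = p$sigma,
                                 radius = 2 * ceiling(2 * p$sigma) + 1))
  thr <- if (identical(p$threshold, "otsu")) {
    rng <- range(sm)
    EBImage::otsu(EBImage::Image(sm), range = rng) * p$threshold_scale
  } else as.numeric(p$threshold)
  mask <- sm > thr
  if (!any(mask))
    return(structure(matrix(0L, nrow(mask), ncol(mask)),
                     class = c("label_map", "matrix")))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm,
                               tolerance = max(1, p$min_peak_separation / 5),
                               ext = max(1L, round(p$min_peak_separation / 2)))
  labels <- as.matrix(EBImage::imageData(labels))
  # small watershed fragments (e.g. slivers split off an irregular
  # nucleus) are merged back into the label they touch most
  labels <- .merge_small_fragments(labels, p$merge_small)
  # drop small isolated objects and relabel contiguously
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= p$min_area)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0
  out[nz] <- remap[labels[nz]]
  structure(out, class = c("label_map", "matrix"))
}

.merge_small_fragments <- function(labels, merge_small) {
  if (is.null(merge_small) || merge_small <= 0) return(labels)
  for (pass in 1:2) {
    sizes <- tabulate(labels[labels > 0])
    small <- which(sizes > 0 & sizes < merge_small)
    if (!length(small)) break
    # adjacency counts between differing nonzero labels (4-neighbourhood)
    pair_tab <- function(a, b) {
      sel <- a > 0 & b > 0 & a != b
      if (!any(sel)) return(NULL)
      data.frame(a = a[sel], b = b[sel])
    }
    H <- nrow(labels); W <- ncol(labels)
    pr <- rbind(pair_tab(labels[-H, ], labels[-1, ]),
                pair_tab(labels[, -W], labels[, -1]))
    if (is.null(pr) || !nrow(pr)) break
    pr <- rbind(pr, data.frame(a = pr$b, b = pr$a))
    # label centroids: a fragment joins the touching label whose
    # centroid is nearest (it broke off that nucleus)
    nz <- which(labels > 0)
    lab <- as.integer(labels[nz])
    cy <- (nz - 1L) %% H; cx <- (nz - 1L) %/% H
    area <- as.vector(rowsum(rep(1, length(lab)), lab))
    ids <- sort(unique(lab))
    gx <- gy <- rep(NA_real_, length(sizes))
    gx[ids] <- as.vector(rowsum(as.numeric(cx), lab)) / area
    gy[ids] <- as.vector(rowsum(as.numeric(cy), lab)) / area
    remap <- seq_len(length(sizes))
    for (s in small) {
      nb <- unique(pr$b[pr$a == s])
      nb <- nb[nb != s]
      if (!length(nb)) next
      d2 <- (gx[nb] - gx[s])^2 + (gy[nb] - gy[s])^2
      remap[s] <- nb[which.min(d2)]
    }
    # resolve chains (small fragment merged into another small fragment)
    for (i in seq_along(remap)) {
      seen <- integer(); j <- i
      while (remap[j] != j && !j %in% seen) { seen <- c(seen, j); j <- remap[j] }
      remap[i] <- j
    }
    nz <- labels > 0
    labels[nz] <- remap[labels[nz]]
    if (all(remap == seq_along(remap))) break
  }
  labels
}

#' Read an externally produced label image
#'
#' Escape hatch for workflows where cells were segmented elsewhere
#' (e.g. manually): reads a single-page TIFF of integer labels so the
#' downstream stages can run on those masks instead.
#'
#' @param path TIFF file of integer labels (0 = background).
#' @return A `label_map` matrix.
#' @export
read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) != 2) stop("label TIFF must be single-channel 2D")
  structure(matrix(as.integer(round(img)), nrow(img), ncol(img)),
            class = c("label_map", "matrix"))
}

#' Extract the per-cell intensity table
#'
#' One row per label: centroid (unweighted mask centroid, 0-based px),
#' area (px) and the mean intensity of every channel over the mask
#' (mean, not median or sum: each cell contributes one expression value
#' per marker).
#'
#' @param labels a `label_map` from [segment_nuclei()] (or an externally
#'   produced integer label matrix).
#' @param channels named list of matrices, same size as `labels`.
#' @param pixel_size physical pixel size (um/px), stored as an attribute
#'   and used for micrometre distances downstream.
#' @return A `cell_table` data.frame: `cell_id`, `x`, `y`, `area`, one
#'   column per channel.
#' @export
extract_cell_table <- function(labels, channels, pixel_size = 0.5) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)))
  dims <- dim(labels)
  for (ch in names(channels))
    if (!identical(dim(channels[[ch]]), dims))
      stop("channel '", ch, "' does not match the label map size")
  nz <- which(labels > 0)
  lab <- as.integer(labels[nz])
  n <- max(labels)
  if (n == 0)
    return(.as_cell_table(data.frame(cell_id = integer(), x = numeric(),
                                     y = numeric(), area = numeric()),
                          pixel_size))
  H <- dims[1]
  ys <- (nz - 1L) %% H          # 0-based row
  xs <- (nz - 1L) %/% H         # 0-based col
  area <- as.vector(rowsum(rep(1, length(lab)), lab))
  out <- data.frame(cell_id = seq_len(n),
                    x = as.vector(rowsum(as.numeric(xs), lab)) / area,
                    y = as.vector(rowsum(as.numeric(ys), lab)) / area,
                    area = area)
  for (ch in names(channels))
    out[[ch]] <- as.vector(rowsum(as.numeric(channels[[ch]][nz]), lab)) / area
  .as_cell_table(out, pixel_size)
}

.as_cell_table <- function(df, pixel_size = attr(df, "pixel_size")) {
  attr(df, "pixel_size") <- pixel_size
  class(df) <- c("cell_table", "data.frame")
  df
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", nrow(x), " cells, pixel size ",
      attr(x, "pixel_size"), " um/px\n", sep = "")
  if ("layer" %in% names(x)) {
    tab <- table(x$layer)
    cat("  layers: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  NextMethod()
}
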