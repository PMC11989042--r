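# Basement-membrane estimation, layer assignment and delamination
# detection. Distances are signed: d = membrane_y(x) - y_cell, so
# positive d means above the membrane (inside the epithelium); the
# boundary itself belongs to the epithelium.

#' Layer-assignment and delamination parameters
#'
#' @param basal_depth basal band depth in um (default one nucleus
#'   diameter at the packaged geometry: 3.6 um).
#' @param parabasal_depth additional parabasal band depth in um
#'   (default two diameters: 7.2 um).
#' @param delam_displacement delamination displacement threshold as a
#'   fraction of the median nucleus diameter.
#' @param touch_tol membrane contact tolerance (px).
#' @param window half-width (px) of the running window used for the
#'   local basal-centroid plane.
#' @return A `layer_params` list.
#' @export
layer_params <- function(basal_depth = 3.6, parabasal_depth = 7.2,
                         delam_displacement = 0.5, touch_tol = 3,
                         window = 50) {
  stopifnot(basal_depth > 0, parabasal_depth > 0, delam_displacement > 0,
            touch_tol > 0, window > 0)
  structure(list(basal_depth = basal_depth, parabasal_depth = parabasal_depth,
                 delam_displacement = delam_displacement,
                 touch_tol = touch_tol, window = window),
            class = "layer_params")
}

#' Estimate the basement membrane from a structural channel
#'
#' Thresholds the epithelial (outline-marker, e.g. KRT14) mask, takes
#' the lower boundary — the largest row with epithelial signal in each
#' column — and smooths it with a running median. The stroma expresses
#' little of the structural marker, so this boundary traces the
#' basement membrane.
#'
#' @param structural_channel 2D matrix of the structural channel.
#' @param params list: `sigma` (smoothing), `threshold` (`"otsu"` or a
#'   number), `gap_tol` (widest run of empty columns bridged by
#'   interpolation, px), `smooth_k` (running-median width, odd).
#' @return A `membrane_curve`: numeric vector `y(x)`, one value per
#'   image column (0-based y).
#' @export
estimate_membrane <- function(structural_channel, params = list()) {
  p <- utils::modifyList(list(sigma = 2, threshold = "otsu", gap_tol = 50,
                              smooth_k = 31), params)
  img <- structural_channel
  if (!is.matrix(img)) stop("structural_channel must be a 2D matrix")
  sm <- as.matrix(EBImage::gblur(img, sigma = p$sigma,
                                 radius = 2 * ceiling(2 * p$sigma) + 1))
  rng <- range(sm)
  thr <- if (!identical(p$threshold, "otsu")) as.numeric(p$threshold)
         else if (diff(rng) == 0) rng[1] - 1   # flat image: all-signal mask
         else EBImage::otsu(EBImage::Image(sm), range = rng)
  mask <- sm > thr
  H <- nrow(mask); W <- ncol(mask)
  lower <- apply(mask, 2, function(col) {
    w <- which(col)
    if (length(w)) max(w) - 1L else NA_integer_   # 0-based
  })
  if (all(is.na(lower)))
    stop("no epithelial signal found in the structural channel")
  na_run <- rle(is.na(lower))
  if (any(na_run$lengths[na_run$values] > p$gap_tol))
    stop("no epithelial pixels over a column span wider than gap_tol (",
         p$gap_tol, " px)")
  if (mean(lower >= H - 2, na.rm = TRUE) > 0.9)
    stop("epithelial mask reaches the image bottom almost everywhere; ",
         "no stromal compartment below the epithelium")
  xs <- which(!is.na(lower))
  y <- stats::approx(xs, lower[xs], xout = seq_len(W), rule = 2)$y
  k <- p$smooth_k
  if (k %% 2 == 0) k <- k + 1
  y <- stats::runmed(y, k = min(k, 2 * (W %/% 2) - 1), endrule = "median")
  structure(as.numeric(y), class = "membrane_curve", smooth_k = k)
}

.membrane_at <- function(membrane, x) {
  # x is 0-based; half-up rounding keeps distances translation-invariant
  membrane[pmin(pmax(floor(x + 0.5), 0), length(membrane) - 1) + 1]
}

#' Assign epithelial layers by signed membrane distance
#'
#' Computes the signed distance `d = membrane_y(x) - y` for each cell
#' centroid (positive above the membrane) and assigns: stromal if
#' `d < 0`; basal if `0 <= d <= basal_depth`; parabasal within the next
#' `parabasal_depth`; suprabasal beyond. Distances are reported in um.
#'
#' @param cells a `cell_table`.
#' @param membrane a `membrane_curve` covering the image width.
#' @param params a [layer_params()] list.
#' @return The `cell_table` with `dist_um` and `layer` columns appended.
#' @export
assign_layers <- function(cells, membrane, params = layer_params()) {
  px <- attr(cells, "pixel_size")
  if (is.null(px)) stop("cell_table lacks a pixel_size attribute")
  d_px <- .membrane_at(membrane, cells$x) - cells$y
  d_um <- d_px * px
  layer <- ifelse(d_um < 0, "stromal",
           ifelse(d_um <= params$basal_depth, "basal",
           ifelse(d_um <= params$basal_depth + params$parabasal_depth,
                  "parabasal", "suprabasal")))
  cells$dist_um <- d_um
  cells$layer <- layer
  .as_cell_table(cells)
}

#' Detect delaminating cells
#'
#' A delaminating cell still contacts the basement membrane but has
#' moved upward out of the basal plane. Operationalized as: the cell
#' mask reaches within `touch_tol` px of the membrane AND the centroid
#' sits more than `delam_displacement` x the median nucleus diameter
#' above the local basal-centroid plane (the running median of
#' basal-cell centroid heights within `window` px). Cells with no basal
#' neighbours in the window get an `NA` flag with a warning.
#'
#' @param cells a `cell_table` with layers assigned.
#' @param labels the `label_map` the table was extracted from.
#' @param membrane a `membrane_curve`.
#' @param params a [layer_params()] list.
#' @return The `cell_table` with `delaminating` (logical) and
#'   `membrane_contact_px` columns appended.
#' @export
detect_delaminating <- function(cells, labels, membrane,
                                params = layer_params()) {
  if (!"layer" %in% names(cells))
    stop("assign layers before detecting delamination")
  H <- nrow(labels)
  nz <- which(labels > 0)
  lab <- as.integer(labels[nz])
  ys <- (nz - 1L) %% H
  xs <- (nz - 1L) %/% H
  depth <- .membrane_at(membrane, xs) - ys   # px above membrane
  min_depth <- rep(NA_real_, nrow(cells))
  agg <- tapply(depth, lab, min)
  min_depth[as.integer(names(agg))] <- agg
  touch <- !is.na(min_depth) & min_depth <= params$touch_tol

  dia_px <- 2 * sqrt(stats::median(cells$area) / pi)
  px <- attr(cells, "pixel_size")
  d_px <- cells$dist_um / px
  basal <- which(cells$layer == "basal")
  flag <- rep(FALSE, nrow(cells))
  undetermined <- FALSE
  cand <- which(touch & cells$layer != "stromal")
  for (i in cand) {
    nb <- basal[abs(cells$x[basal] - cells$x[i]) <= params$window]
    nb <- setdiff(nb, i)
    if (!length(nb)) { flag[i] <- NA; undetermined <- TRUE; next }
    plane <- stats::median(d_px[nb])
    flag[i] <- (d_px[i] - plane) > params$delam_displacement * dia_px
  }
  if (undetermined)
    warning("no basal cells within the window for some candidates; ",
            "their delamination flag is undetermined (NA)")
  cells$delaminating <- flag
  cells$membrane_contact_px <- min_depth
  .as_cell_table(cells)
}
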