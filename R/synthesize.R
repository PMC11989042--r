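# Synthetic multichannel section rendering.
#
# Coordinate conventions: 0-based pixel coordinates, x = column,
# y = row, y increasing downward; the membrane is stored as y(x) and
# "above the membrane" means smaller y. Matrices are indexed [row, col]
# = [y + 1, x + 1].

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# pixel indices (into an H x W matrix) of a disc at 0-based (xc, yc)
.disc_idx <- function(xc, yc, r, H, W) {
  x0 <- max(0L, floor(xc - r)); x1 <- min(W - 1L, ceiling(xc + r))
  y0 <- max(0L, floor(yc - r)); y1 <- min(H - 1L, ceiling(yc + r))
  if (x1 < x0 || y1 < y0) return(integer())
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - xc)^2; dy2 <- (ys - yc)^2
  keep <- outer(dy2, dx2, "+") <= r^2
  (rep(xs, each = length(ys)) * H + rep(ys, length(xs)) + 1L)[keep]
}

# vertically elongated ellipse (semi-axes a horizontal, b vertical)
.ellipse_idx <- function(xc, yc, a, b, H, W) {
  x0 <- max(0L, floor(xc - a)); x1 <- min(W - 1L, ceiling(xc + a))
  y0 <- max(0L, floor(yc - b)); y1 <- min(H - 1L, ceiling(yc + b))
  if (x1 < x0 || y1 < y0) return(integer())
  xs <- x0:x1; ys <- y0:y1
  dx2 <- ((xs - xc) / a)^2; dy2 <- ((ys - yc) / b)^2
  keep <- outer(dy2, dx2, "+") <= 1
  (rep(xs, each = length(ys)) * H + rep(ys, length(xs)) + 1L)[keep]
}

.lnorm_draw <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# place one row of cells: x grid with jitter, membrane-relative depth d
.place_row <- function(g, mem_fun, d_lo, d_hi, x_spacing, x_offset = 0) {
  xs <- seq(x_spacing / 2 + x_offset, g$width - x_spacing / 2, by = x_spacing)
  if (!length(xs)) return(NULL)
  xs <- xs + stats::runif(length(xs), -1.2, 1.2)
  xs <- pmin(pmax(xs, 2), g$width - 3)
  d <- stats::runif(length(xs), d_lo, d_hi)
  data.frame(x = xs, y = mem_fun(xs) - d, d = d)
}

#' Render a synthetic multichannel tissue section
#'
#' Places nuclei in membrane-relative layer bands (stroma below a
#' sinusoidal basement membrane; basal, parabasal and suprabasal rows
#' above it), draws per-cell marker intensities from the profile's
#' per-layer log-normal mixtures, renders nuclei as uniform discs (the
#' structural outline marker additionally as cytoplasmic territory
#' discs), converts a fraction of basal cells into delaminating cells
#' (nucleus displaced upward out of the basal plane, retaining a thin
#' stalk of contact with the membrane), scatters Poisson-distributed
#' PLA puncta as Gaussian spots over each cell, and finally applies
#' read noise plus signal-dependent noise and quantizes to 16-bit
#' camera counts. Identical `(profile, geometry, seed)` give
#' bit-identical output.
#'
#' @param profile a `species_profile` (see [default_profile()]).
#' @param geometry a `section_geometry` (see [section_geometry()]).
#' @param seed integer seed; every random draw derives from it.
#' @return A `synthetic_section`: list with `channels` (named list of
#'   height x width intensity matrices; `DNA`, the panel markers, and
#'   `PLA`), `truth` (one row per cell: id, centroid, radius, layer,
#'   delaminating flag, per-marker true mean `mean_*` and positivity
#'   `pos_*`, `puncta_count`), `membrane_truth` (y(x) of the generated
#'   membrane), plus the profile name, geometry and seed used.
#' @export
synthesize_section <- function(profile, geometry = section_geometry(), seed) {
  viol <- validate_profile(profile)
  if (length(viol)) stop("invalid profile: ", paste(viol, collapse = "; "))
  viol <- validate_geometry(geometry)
  if (length(viol)) stop("invalid geometry: ", paste(viol, collapse = "; "))
  g <- geometry
  .with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    mem_fun <- function(x)
      g$membrane_y + g$amplitude * sin(2 * pi * x / g$wavelength + phase)

    b1 <- g$basal_band; b2 <- g$parabasal_band; b3 <- g$suprabasal_band
    rows <- list()
    rows$stromal <- rbind(
      .place_row(g, mem_fun, -0.32 * g$stromal_band - 2,
                 -0.24 * g$stromal_band + 2, g$spacing + 7),
      .place_row(g, mem_fun, -0.64 * g$stromal_band - 2,
                 -0.56 * g$stromal_band + 2, g$spacing + 7, g$spacing / 2))
    sup_centres <- seq(b1 + b2 + 4.4, b1 + b2 + b3 - 4, by = 12)
    rows$suprabasal <- do.call(rbind, lapply(seq_along(sup_centres), function(i)
      .place_row(g, mem_fun, sup_centres[i] - 2, sup_centres[i] + 2,
                 g$spacing + 2, if (i %% 2 == 0) (g$spacing + 2) / 2 else 0)))
    rows$parabasal <- rbind(
      .place_row(g, mem_fun, b1 + 0.23 * b2 - 1, b1 + 0.23 * b2 + 1,
                 g$spacing, g$spacing / 2),
      .place_row(g, mem_fun, b1 + 0.75 * b2 - 1.5, b1 + 0.75 * b2 + 1.5,
                 g$spacing))
    rows$basal <- .place_row(g, mem_fun, max(2, 0.35 * b1), b1 - 2.2,
                             g$spacing)
    if (is.null(rows$basal) || nrow(rows$basal) < 3)
      stop("geometry too small: cannot fit a basal cell row per layer")

    # convert a fraction of basal cells into delaminating cells
    delam_p <- profile$delamination$frequency / 100
    is_delam <- stats::runif(nrow(rows$basal)) < delam_p
    delam <- rows$basal[is_delam, , drop = FALSE]
    rows$basal <- rows$basal[!is_delam, , drop = FALSE]
    if (nrow(delam)) {
      # a delaminating nucleus is an elongated comet spanning from the
      # membrane up to d = top: still connected to the membrane but with
      # its centroid displaced out of the basal plane
      dia <- 2 * mean(g$nucleus_radius)
      delam$top <- stats::runif(nrow(delam), 2.5 * dia, 3.05 * dia)
      delam$d <- delam$top / 2
      delam$y <- mem_fun(delam$x) - delam$d
      # the comet pushes through the parabasal rows: clear space
      keep <- rep(TRUE, nrow(rows$parabasal))
      for (i in seq_len(nrow(delam))) {
        dmem <- mem_fun(rows$parabasal$x) - rows$parabasal$y
        dist2 <- (rows$parabasal$x - delam$x[i])^2 +
          (rows$parabasal$y - delam$y[i])^2
        inpath <- abs(rows$parabasal$x - delam$x[i]) <= 4.5 &
          dmem <= delam$top[i] + 2
        keep <- keep & !(dist2 <= 8.5^2 | inpath)
      }
      rows$parabasal <- rows$parabasal[keep, , drop = FALSE]
    }

    layer_of <- rep(names(rows), vapply(rows, function(r)
      if (is.null(r)) 0L else nrow(r), integer(1)))
    cells <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    cells$layer <- layer_of
    cells$delaminating <- FALSE
    cells$top <- NA_real_
    if (nrow(delam)) {
      delam$layer <- "basal"      # basal-origin by definition
      delam$delaminating <- TRUE
      cells <- rbind(cells, delam[names(cells)])
    }
    # nuclei cannot interpenetrate: greedy minimum-spacing enforcement,
    # basal and delaminating cells taking priority
    prio <- order(match(paste0(cells$layer, ifelse(cells$delaminating,
                                                   "_delam", "")),
                        c("basal", "basal_delam", "parabasal",
                          "suprabasal", "stromal")))
    min_dist <- 0.76 * g$spacing
    keep <- logical(nrow(cells))
    kx <- ky <- numeric(nrow(cells)); nk <- 0L
    for (i in prio) {
      if (nk) {
        d2 <- (kx[seq_len(nk)] - cells$x[i])^2 +
          (ky[seq_len(nk)] - cells$y[i])^2
        if (any(d2 < min_dist^2)) next
      }
      keep[i] <- TRUE
      nk <- nk + 1L
      kx[nk] <- cells$x[i]; ky[nk] <- cells$y[i]
    }
    cells <- cells[keep, , drop = FALSE]
    n <- nrow(cells)
    cells$cell_id <- seq_len(n)
    cells$radius <- stats::runif(n, g$nucleus_radius[1], g$nucleus_radius[2])
    if (is.null(cells$top)) cells$top <- NA_real_

    # --- per-cell generative draws -------------------------------------
    markers <- profile$panel$name
    truth <- data.frame(cell_id = cells$cell_id, x = cells$x, y = cells$y,
                        radius = cells$radius, layer = cells$layer,
                        delaminating = cells$delaminating)
    delam_prolif <- profile$delamination$proliferation
    overrides <- profile$delamination$overrides
    for (m in markers) {
      entry_of <- lapply(profile$layers, function(l) l$markers[[m]])
      pos <- value <- numeric(n)
      posflag <- logical(n)
      for (ln in names(profile$layers)) {
        idx <- which(cells$layer == ln & !cells$delaminating)
        if (!length(idx)) next
        e <- entry_of[[ln]]
        p <- stats::runif(length(idx)) < e$pos_frac
        mu <- ifelse(p, e$pos_mean, e$neg_mean)
        value[idx] <- .lnorm_draw(length(idx), 1, e$cv) * mu
        posflag[idx] <- p
      }
      idx <- which(cells$delaminating)
      if (length(idx)) {
        e <- if (!is.null(overrides[[m]])) overrides[[m]]
             else entry_of[["basal"]]
        f <- if (!is.null(delam_prolif[[m]])) delam_prolif[[m]] else e$pos_frac
        p <- stats::runif(length(idx)) < f
        if (f > 0 && f < 1 && is.na(e$pos_mean))
          e$pos_mean <- e$mean   # override without mixture spec
        mu <- ifelse(p, if (is.na(e$pos_mean)) e$mean else e$pos_mean,
                     if (is.na(e$neg_mean) || e$neg_mean <= 0) e$mean
                     else e$neg_mean)
        if (f >= 1) mu <- rep(if (is.na(e$pos_mean)) e$mean else e$pos_mean,
                              length(idx))
        if (f <= 0) mu <- rep(e$mean, length(idx))
        value[idx] <- .lnorm_draw(length(idx), 1, e$cv) * mu
        posflag[idx] <- p
      }
      truth[[paste0("mean_", m)]] <- value
      truth[[paste0("pos_", m)]] <- posflag
    }
    truth$mean_DNA <- .lnorm_draw(n, g$dna_mean, 0.20)
    rate <- vapply(seq_len(n), function(i)
      profile$layers[[if (cells$delaminating[i]) "basal" else
        cells$layer[i]]]$pla_rate, numeric(1))
    truth$puncta_count <- stats::rpois(n, rate)

    # --- rendering -----------------------------------------------------
    H <- g$height; W <- g$width
    # draw order: later layers overwrite at rare contact points
    ord <- order(match(cells$layer, c("stromal", "suprabasal", "parabasal",
                                      "basal")), cells$delaminating)
    masks <- vector("list", n)
    for (i in ord) {
      idx <- if (cells$delaminating[i])
        .ellipse_idx(cells$x[i], cells$y[i], 0.75 * cells$radius[i],
                     cells$top[i] / 2, H, W)
      else .disc_idx(cells$x[i], cells$y[i], cells$radius[i], H, W)
      masks[[i]] <- idx
    }
    mask_idx <- unlist(masks[ord])
    mask_len <- lengths(masks)[ord]

    structural <- profile$panel$name[profile$panel$role == "structural"]
    epithelial <- cells$layer != "stromal" | cells$delaminating
    channels <- vector("list", length(markers) + 2L)
    names(channels) <- c("DNA", markers, "PLA")
    for (ch in names(channels)) {
      img <- numeric(H * W)
      if (ch %in% structural) {
        # cytoplasmic territory discs give a contiguous epithelial band
        for (i in ord[epithelial[ord]]) {
          ti <- .disc_idx(cells$x[i], cells$y[i], g$territory_radius, H, W)
          img[ti] <- truth[[paste0("mean_", ch)]][i]
        }
        for (i in ord[!epithelial[ord]])
          img[masks[[i]]] <- truth[[paste0("mean_", ch)]][i]
        for (i in ord[epithelial[ord]])
          img[masks[[i]]] <- truth[[paste0("mean_", ch)]][i]
      } else if (ch == "PLA") {
        half <- 3L
        off <- -half:half
        patch_dx <- rep(off, each = 2 * half + 1)
        patch_dy <- rep(off, 2 * half + 1)
        for (i in seq_len(n)) {
          np <- truth$puncta_count[i]
          if (np == 0) next
          r <- cells$radius[i] + 1
          repeat {
            px <- stats::runif(np, -r, r); py <- stats::runif(np, -r, r)
            ok <- px^2 + py^2 <= r^2
            if (all(ok)) break
            px[!ok] <- stats::runif(sum(!ok), -r, r)
            py[!ok] <- stats::runif(sum(!ok), -r, r)
          }
          px <- cells$x[i] + px; py <- cells$y[i] + py
          for (k in seq_len(np)) {
            cx <- round(px[k]); cy <- round(py[k])
            xs <- cx + patch_dx; ys <- cy + patch_dy
            keep <- xs >= 0 & xs <= W - 1 & ys >= 0 & ys <= H - 1
            amp <- g$pla_amplitude *
              exp(-((xs - px[k])^2 + (ys - py[k])^2) / (2 * g$pla_sigma^2))
            ii <- xs[keep] * H + ys[keep] + 1L
            img[ii] <- img[ii] + amp[keep]
          }
        }
      } else {
        vals <- if (ch == "DNA") truth$mean_DNA else truth[[paste0("mean_", ch)]]
        img[mask_idx] <- rep(vals[ord], mask_len)
      }
      noisy <- img + stats::rnorm(H * W,
                                  sd = sqrt(g$read_noise_sd^2 +
                                            g$noise_gain * img))
      channels[[ch]] <- matrix(pmin(pmax(round(noisy), 0), 65535), H, W)
    }

    section <- list(channels = channels, truth = truth,
                    membrane_truth = .membrane_truth(g, phase),
                    phase = phase, profile = profile$name,
                    geometry = g, seed = seed)
    class(section) <- "synthetic_section"
    section
  })
}

#' @export
print.synthetic_section <- function(x, ...) {
  cat("<synthetic_section> profile '", x$profile, "', seed ", x$seed,
      "\n", sep = "")
  cat("  ", x$geometry$width, " x ", x$geometry$height, " px, ",
      length(x$channels), " channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  tab <- table(x$truth$layer)
  cat("  cells: ", nrow(x$truth), " (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      sum(x$truth$delaminating), " delaminating\n", sep = "")
  invisible(x)
}

#' Default PLA progression cohort design
#'
#' Group puncta rates are taken from the packaged profiles (normal basal
#' NB and suprabasal NS from `human`; LGD/HGD/SCC from the progression
#' profiles) and sample numbers follow the quantified cohort: 25 normal,
#' 14 low-grade, 19 high-grade and 9 carcinoma samples.
#'
#' @return data.frame with columns `group`, `rate`, `n_samples`.
#' @export
pla_progression_groups <- function() {
  hu <- default_profile("human")
  data.frame(
    group = c("NB", "NS", "LGD", "HGD", "SCC"),
    rate = c(hu$layers$basal$pla_rate, hu$layers$suprabasal$pla_rate,
             default_profile("human_lgd")$layers$basal$pla_rate,
             default_profile("human_hgd")$layers$basal$pla_rate,
             default_profile("human_scc")$layers$basal$pla_rate),
    n_samples = c(25L, 25L, 14L, 19L, 9L))
}

#' Simulate per-cell PLA puncta counts for a progression cohort
#'
#' Counts are Poisson per cell; each sample (patient/lesion) carries a
#' log-normal rate multiplier with coefficient of variation
#' `sample_cv`, emulating between-sample biological variability — the
#' unit on which the progression t-tests operate.
#'
#' @param groups design data.frame as from [pla_progression_groups()].
#' @param cells_per_sample cells quantified per sample.
#' @param sample_cv between-sample log-normal coefficient of variation.
#' @param seed integer seed.
#' @return data.frame with columns `group`, `sample`, `count` (one row
#'   per cell).
#' @export
simulate_pla_cohort <- function(groups = pla_progression_groups(),
                                cells_per_sample = 120, sample_cv = 0.3,
                                seed) {
  .with_seed(seed, {
    out <- lapply(seq_len(nrow(groups)), function(i) {
      mult <- .lnorm_draw(groups$n_samples[i], 1, sample_cv)
      data.frame(
        group = groups$group[i],
        sample = rep(paste0(groups$group[i], "_", seq_len(groups$n_samples[i])),
                     each = cells_per_sample),
        count = stats::rpois(groups$n_samples[i] * cells_per_sample,
                             rep(groups$rate[i] * mult,
                                 each = cells_per_sample)))
    })
    do.call(rbind, out)
  })
}
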