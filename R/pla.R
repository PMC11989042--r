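# Proximity ligation assay (PLA): puncta detection per cell and
# progression statistics across normal -> dysplasia -> carcinoma.

#' Detect PLA puncta and assign them to cells
#'
#' Band-pass (difference-of-Gaussians) filtering, local-maximum
#' detection above a prominence threshold with a minimum separation,
#' and assignment of each punctum to its enclosing nuclear label —
#' or the nearest label within `dilate` px, since PLA dots sit on the
#' cell but not strictly inside the nucleus. Deterministic.
#'
#' @param pla_channel 2D matrix of the PLA channel.
#' @param labels a `label_map` aligned with the channel.
#' @param params list: `sigma` (spot scale, px), `min_prominence`
#'   (DoG response threshold, a.u.), `min_separation` (px), `dilate`
#'   (label dilation radius for assignment, px).
#' @return Integer vector of puncta counts, one per label; the total
#'   number of detected maxima (assigned or not) is attached as
#'   attribute `n_detected`.
#' @export
detect_puncta <- function(pla_channel, labels, params = list()) {
  p <- utils::modifyList(list(sigma = 1.1, min_prominence = 120,
                              min_separation = 3, dilate = 2), params)
  if (!identical(dim(pla_channel), dim(labels)))
    stop("PLA channel and label map sizes differ")
  n <- max(labels)
  g1 <- as.matrix(EBImage::gblur(pla_channel, sigma = p$sigma,
                                 radius = 2 * ceiling(2 * p$sigma) + 1))
  g2 <- as.matrix(EBImage::gblur(pla_channel, sigma = 2.5 * p$sigma,
                                 radius = 2 * ceiling(5 * p$sigma) + 1))
  dog <- g1 - g2
  size <- 2 * floor(p$min_separation / 2) + 1L
  mx <- as.matrix(EBImage::imageData(EBImage::dilate(
    EBImage::Image(dog), EBImage::makeBrush(size, shape = "disc"))))
  peaks <- which(dog >= mx & dog > p$min_prominence)
  counts <- integer(max(1L, n))
  if (n == 0 || !length(peaks)) {
    out <- integer(n)
    attr(out, "n_detected") <- length(peaks)
    return(out)
  }
  H <- nrow(labels); W <- ncol(labels)
  py <- (peaks - 1L) %% H
  px <- (peaks - 1L) %/% H
  lab <- labels[peaks]
  # nearest label within `dilate` px for orphan peaks
  orphan <- which(lab == 0L)
  r <- ceiling(p$dilate)
  for (k in orphan) {
    best <- 0L; bestd <- Inf
    for (dy in -r:r) for (dx in -r:r) {
      yy <- py[k] + dy; xx <- px[k] + dx
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) next
      l <- labels[yy + 1L, xx + 1L]
      if (l > 0L) {
        d <- dy^2 + dx^2
        if (d <= p$dilate^2 && d < bestd) { best <- l; bestd <- d }
      }
    }
    lab[k] <- best
  }
  assigned <- lab[lab > 0L]
  out <- integer(n)
  if (length(assigned)) {
    t <- table(assigned)
    out[as.integer(names(t))] <- as.integer(t)
  }
  attr(out, "n_detected") <- length(peaks)
  out
}

#' Summarize PLA counts across progression groups
#'
#' Per-group median and interquartile range of puncta counts, and
#' Student's t-tests of every group against the reference (normal
#' basal) group. When `sample` identifiers are supplied the tests run
#' on per-sample mean counts — the per-sample unit of the original
#' quantification — otherwise on cells. Groups with fewer than two
#' test units are excluded from testing with a warning. The summary
#' flags the "recovery" pattern: whether the SCC group mean exceeds
#' the HGD group mean.
#'
#' @param counts integer puncta counts per cell.
#' @param group group label per cell (e.g. NB, NS, LGD, HGD, SCC).
#' @param sample optional sample/lesion identifier per cell.
#' @param ref reference group (default `"NB"`).
#' @param alpha significance level for starring (default 0.05).
#' @return A `pla_progression` object: `summary` (per-group n, median,
#'   IQR, mean), `tests` (vs-reference t-tests), `recovery`
#'   (logical or NA), and the unit used for testing.
#' @export
progression_summary <- function(counts, group, sample = NULL, ref = "NB",
                                alpha = 0.05) {
  stopifnot(length(counts) == length(group))
  if (any(counts < 0)) stop("puncta counts must be non-negative")
  groups <- unique(as.character(group))
  if (length(groups) < 2) stop("at least two groups required")
  if (!ref %in% groups) stop("reference group '", ref, "' not present")
  summ <- do.call(rbind, lapply(groups, function(gq) {
    v <- counts[group == gq]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = gq, n_cells = length(v),
               n_samples = if (is.null(sample)) NA_integer_ else
                 length(unique(sample[group == gq])),
               median = q[2], q25 = q[1], q75 = q[3], mean = mean(v))
  }))
  if (is.null(sample)) {
    unit_vals <- counts; unit_grp <- as.character(group)
    unit <- "cell"
  } else {
    agg <- stats::aggregate(counts,
                            by = list(group = as.character(group),
                                      sample = sample), FUN = mean)
    unit_vals <- agg$x; unit_grp <- agg$group
    unit <- "sample"
  }
  small <- names(which(table(unit_grp) < 2))
  small <- setdiff(small, ref)
  if (length(small))
    warning("group(s) with fewer than 2 ", unit, "s excluded from tests: ",
            paste(small, collapse = ", "))
  keep <- unit_grp == ref | !unit_grp %in% small
  tests <- pairwise_t_vs_ref(unit_vals[keep], unit_grp[keep], ref,
                             alpha = alpha)
  recovery <- if (all(c("SCC", "HGD") %in% groups))
    summ$mean[summ$group == "SCC"] > summ$mean[summ$group == "HGD"]
  else NA
  structure(list(summary = summ, tests = tests, recovery = recovery,
                 ref = ref, unit = unit, alpha = alpha),
            class = "pla_progression")
}

#' @export
print.pla_progression <- function(x, ...) {
  cat("<pla_progression> reference ", x$ref, ", tests on ", x$unit,
      " means\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  cat("Student's t vs ", x$ref, " (* p <= ", x$alpha, "):\n", sep = "")
  df <- x$tests
  df$star <- ifelse(df$significant, "*", "")
  print(df, row.names = FALSE, digits = 3)
  if (!is.na(x$recovery))
    cat("SCC-over-HGD recovery pattern: ",
        if (x$recovery) "present" else "absent", "\n", sep = "")
  invisible(x)
}
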