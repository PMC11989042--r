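# Core quantification: marker capture, fold changes, delamination
# proliferation state, basal subpopulation clustering.

#' Basal-marker capture statistics
#'
#' For each marker, the percentage of basal cells called positive by
#' its gate ("capture": how well the marker identifies basalness), and
#' for every pair `anchor` + other marker, the number of double-positive
#' cells and the fraction of double-positive cells that are basal.
#'
#' @param cells a `cell_table` with layers assigned.
#' @param gates named gate set from [gate_markers()].
#' @param markers markers to report (default: all gated markers).
#' @param basal logical vector defining basal cells (default: the
#'   geometry-derived `layer == "basal"`; pass ground-truth or a manual
#'   selection instead to reproduce a manual workflow).
#' @param anchor marker anchoring the double-positive pairs.
#' @return A `capture_stats` object: `capture` data.frame (`marker`,
#'   `n_basal`, `n_positive`, `percent`) and `pairs` data.frame
#'   (`marker_a`, `marker_b`, `n_double`, `frac_double_basal`).
#' @export
capture_stats <- function(cells, gates, markers = names(gates),
                          basal = NULL, anchor = "XPC") {
  if (is.null(basal)) {
    if (!"layer" %in% names(cells))
      stop("assign layers or supply a basal selection")
    basal <- cells$layer == "basal"
  }
  if (!any(basal)) stop("zero basal cells defined")
  missing <- setdiff(markers, names(gates))
  if (length(missing))
    stop("no gate for marker(s): ", paste(missing, collapse = ", "))
  pos <- lapply(markers, function(m) apply_gate(cells[[m]], gates[[m]]))
  names(pos) <- markers
  # double-positive concordance is judged against basal ORIGIN: cells
  # flagged as delaminating are basal cells that left the basal plane
  basal_origin <- basal
  if ("delaminating" %in% names(cells))
    basal_origin <- basal | (cells$delaminating %in% TRUE)
  capture <- data.frame(
    marker = markers,
    n_basal = sum(basal),
    n_positive = vapply(markers, function(m) sum(pos[[m]] & basal),
                        integer(1)),
    row.names = NULL)
  capture$percent <- 100 * capture$n_positive / capture$n_basal
  pairs <- NULL
  if (anchor %in% markers && length(markers) > 1) {
    others <- setdiff(markers, anchor)
    pairs <- data.frame(
      marker_a = anchor, marker_b = others,
      n_double = vapply(others, function(m) sum(pos[[anchor]] & pos[[m]]),
                        integer(1)),
      frac_double_basal = vapply(others, function(m) {
        dp <- pos[[anchor]] & pos[[m]]
        if (!any(dp)) NA_real_ else mean(basal_origin[dp])
      }, numeric(1)),
      row.names = NULL)
  }
  structure(list(capture = capture, pairs = pairs), class = "capture_stats")
}

#' @export
print.capture_stats <- function(x, ...) {
  cat("<capture_stats> basal cells: ", x$capture$n_basal[1], "\n", sep = "")
  df <- x$capture
  df$percent <- sprintf("%.2f%%", df$percent)
  print(df, row.names = FALSE)
  if (!is.null(x$pairs)) {
    cat("double-positive pairs:\n")
    print(x$pairs, row.names = FALSE)
  }
  invisible(x)
}

#' Fold change between two cell groups
#'
#' Ratio of group means and of group medians for a marker (both are
#' reported; the mean ratio is the primary estimate), with a seeded
#' percentile-bootstrap confidence interval on the mean ratio.
#'
#' @param cells a `cell_table`.
#' @param marker marker column, or any numeric column (e.g. a
#'   normalized `norm_h1_*` column).
#' @param group factor/character vector splitting the cells (defaults
#'   to `cells$layer`).
#' @param a,b the two group labels compared as `a / b`.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return A `fold_change` object with `mean_ratio`, `median_ratio`,
#'   `ci` and group summaries.
#' @export
fold_change <- function(cells, marker, group = cells$layer, a, b,
                        n_boot = 1000, seed = 1, conf = 0.95) {
  if (!marker %in% names(cells))
    stop("column '", marker, "' not present in the cell table")
  va <- cells[[marker]][group == a]
  vb <- cells[[marker]][group == b]
  if (!length(va)) stop("group '", a, "' is empty")
  if (!length(vb)) stop("group '", b, "' is empty")
  mean_ratio <- mean(va) / mean(vb)
  median_ratio <- stats::median(va) / stats::median(vb)
  ci <- .with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i)
      mean(sample(va, replace = TRUE)) / mean(sample(vb, replace = TRUE)),
      numeric(1))
    stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  })
  structure(list(marker = marker, group_a = a, group_b = b,
                 n_a = length(va), n_b = length(vb),
                 mean_a = mean(va), mean_b = mean(vb),
                 mean_ratio = mean_ratio, median_ratio = median_ratio,
                 ci = ci, conf = conf, n_boot = n_boot),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat("<fold_change> ", x$marker, ": ", x$group_a, " / ", x$group_b,
      "\n", sep = "")
  cat(sprintf("  mean ratio %.3g (%d%% CI %.3g-%.3g), median ratio %.3g\n",
              x$mean_ratio, round(100 * x$conf), x$ci[1], x$ci[2],
              x$median_ratio))
  cat(sprintf("  n = %d vs %d, means %.4g vs %.4g\n", x$n_a, x$n_b,
              x$mean_a, x$mean_b))
  invisible(x)
}

#' Proliferation state of delaminating cells
#'
#' Counts delaminating cells and, for each proliferation marker, the
#' percentage of delaminating cells gated positive. Markers without a
#' measured channel (or without a gate) are reported `NA`.
#'
#' @param cells a `cell_table` with `delaminating` flags.
#' @param gates named gate set.
#' @param markers proliferation markers to report (defaults cover
#'   MCM2, PCNA, PHH3 and Ki67; absent channels yield `NA`).
#' @return A `delamination_stats` object: `n_delaminating` and a
#'   per-marker `percent_positive` data.frame.
#' @export
delamination_stats <- function(cells, gates,
                               markers = c("MCM2", "PCNA", "PHH3", "Ki67")) {
  if (!"delaminating" %in% names(cells))
    stop("run delamination detection first")
  delam <- which(!is.na(cells$delaminating) & cells$delaminating)
  pct <- vapply(markers, function(m) {
    if (!m %in% names(cells) || !m %in% names(gates) || !length(delam))
      return(NA_real_)
    100 * mean(apply_gate(cells[[m]][delam], gates[[m]]))
  }, numeric(1))
  structure(list(n_delaminating = length(delam),
                 percent_positive = data.frame(marker = markers,
                                               percent = unname(pct),
                                               row.names = NULL)),
            class = "delamination_stats")
}

#' @export
print.delamination_stats <- function(x, ...) {
  cat("<delamination_stats> ", x$n_delaminating, " delaminating cells\n",
      sep = "")
  df <- x$percent_positive
  df$percent <- ifelse(is.na(df$percent), "N/A",
                       sprintf("%.1f%%", df$percent))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cluster basal cells into subpopulations
#'
#' Gaussian-mixture clustering (seeded, deterministic) of the
#' standardized log marker matrix of basal cells, with per-cluster
#' marker medians so subpopulations such as FTH1-high vs FTH1-low are
#' identifiable from the summary.
#'
#' @param cells a `cell_table` with layers assigned.
#' @param markers marker columns to cluster on.
#' @param k number of clusters (>= 1).
#' @param subset logical vector selecting cells (default basal layer).
#' @param seed seed for the mixture fit.
#' @return A `basal_clusters` object: `labels` (cluster id per selected
#'   cell), `cells_idx` (row indices), and `medians` (cluster x marker
#'   median matrix, raw intensity scale).
#' @export
cluster_basal <- function(cells, markers, k, subset = NULL, seed = 1) {
  if (k < 1) stop("k must be >= 1")
  if (is.null(subset)) subset <- cells$layer == "basal"
  idx <- which(subset)
  if (length(idx) < 20 * k)
    stop("need at least ", 20 * k, " cells to fit ", k, " clusters")
  X <- vapply(markers, function(m) log(pmax(cells[[m]][idx], 1)),
              numeric(length(idx)))
  X <- matrix(X, nrow = length(idx), dimnames = list(NULL, markers))
  Xs <- scale(X)
  labels <- if (k == 1) rep(1L, length(idx)) else .with_seed(seed, {
    fit <- mclust::Mclust(Xs, G = k, verbose = FALSE)
    as.integer(fit$classification)
  })
  ids <- sort(unique(labels))
  medians <- matrix(NA_real_, length(ids), length(markers),
                    dimnames = list(paste0("cluster", ids), markers))
  for (j in seq_along(ids))
    medians[j, ] <- apply(X[labels == ids[j], , drop = FALSE], 2,
                          function(v) stats::median(exp(v)))
  structure(list(labels = labels, cells_idx = idx, k = k,
                 markers = markers, medians = medians),
            class = "basal_clusters")
}

#' @export
print.basal_clusters <- function(x, ...) {
  cat("<basal_clusters> k = ", x$k, ", ", length(x$labels), " cells\n",
      sep = "")
  cat("cluster sizes: ", paste(table(x$labels), collapse = ", "), "\n",
      sep = "")
  print(round(x$medians, 1))
  invisible(x)
}

#' Pairwise Student's t-tests with starring
#'
#' Classic two-sample Student's t-tests (equal variances) of a value
#' against a reference group, starred at `p <= alpha`; a Holm-adjusted
#' column is included for reference but the stars follow the unadjusted
#' p-values.
#'
#' @param values numeric vector.
#' @param group group labels.
#' @param ref reference group label.
#' @param alpha significance level (default 0.05).
#' @return data.frame: `group`, `n`, `p_value`, `p_holm`, `significant`.
#' @export
pairwise_t_vs_ref <- function(values, group, ref, alpha = 0.05) {
  others <- setdiff(unique(group), ref)
  res <- lapply(others, function(gq) {
    a <- values[group == ref]; b <- values[group == gq]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(group = gq, n = length(b), p_value = NA_real_))
    data.frame(group = gq, n = length(b),
               p_value = stats::t.test(a, b, var.equal = TRUE)$p.value)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out$significant <- !is.na(out$p_value) & out$p_value <= alpha
  out
}
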