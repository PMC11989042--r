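# Positivity gating. The visual rule "the lowest level of expression of
# clearly positive cells" is mapped to the posterior crossing of a
# two-component Gaussian mixture on log intensities, with an Otsu
# fallback for degenerate fits.

# Otsu threshold on a numeric vector (between-class variance maximizer
# on a fixed histogram; EBImage's otsu() is image-oriented).
.otsu_vector <- function(x, n_breaks = 256) {
  rng <- range(x)
  if (diff(rng) == 0) stop("all values identical; cannot place a gate")
  breaks <- seq(rng[1], rng[2], length.out = n_breaks + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_breaks)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h); tot <- w[n_breaks]
  mu <- cumsum(h * mids); mu_t <- mu[n_breaks]
  w0 <- w[-n_breaks]; w1 <- tot - w0
  ok <- w0 > 0 & w1 > 0
  between <- (mu_t * w0 - mu[-n_breaks] * tot)^2 / (w0 * w1 * tot^2)
  between[!ok] <- -Inf
  mids[which.max(between)]
}

# crossing of two weighted normal densities between their means
.mixture_crossing <- function(w, mu, sd) {
  o <- order(mu)
  w <- w[o]; mu <- mu[o]; sd <- sd[o]
  a <- 1 / sd[1]^2 - 1 / sd[2]^2
  b <- -2 * (mu[1] / sd[1]^2 - mu[2] / sd[2]^2)
  cc <- mu[1]^2 / sd[1]^2 - mu[2]^2 / sd[2]^2 -
    2 * log((w[1] * sd[2]) / (w[2] * sd[1]))
  if (abs(a) < 1e-12) {
    r <- -cc / b
    return(if (r > mu[1] && r < mu[2]) r else mean(mu))
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(mean(mu))
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside)) inside[1] else mean(mu)
}

#' Place a positivity gate on marker intensities
#'
#' Fits a two-component Gaussian mixture to log intensities and places
#' the threshold at the posterior crossing between the components — the
#' lowest value more likely to come from the positive population. If
#' the fit is degenerate (a component weight below `min_weight` or
#' component means closer than `min_separation` log units) the gate
#' falls back to an Otsu threshold on log values and is tagged
#' `"otsu"` with a warning. Manual gates are passed through.
#'
#' @param values positive intensities (>= 50 values required).
#' @param method `"mixture"`, `"otsu"` or `"manual"`.
#' @param manual numeric threshold when `method = "manual"`.
#' @param min_weight,min_separation degeneracy guards for the mixture
#'   fit.
#' @return A `gate`: list with `threshold` (intensity scale),
#'   `log_threshold`, `method`, and the fitted component summary.
#' @export
place_gate <- function(values, method = c("mixture", "otsu", "manual"),
                       manual = NULL, min_weight = 0.05,
                       min_separation = 0.25) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (method == "manual") {
    if (is.null(manual) || manual <= 0)
      stop("manual gating requires a positive threshold")
    return(structure(list(threshold = manual, log_threshold = log(manual),
                          method = "manual"), class = "gate"))
  }
  if (length(values) < 50)
    stop("at least 50 values required to place a gate")
  if (any(values <= 0)) values <- pmax(values, min(values[values > 0]))
  lv <- log(values)
  if (diff(range(lv)) == 0) stop("all values identical; cannot place a gate")
  if (method == "otsu") {
    t <- .otsu_vector(lv)
    return(structure(list(threshold = exp(t), log_threshold = t,
                          method = "otsu"), class = "gate"))
  }
  fit <- mclust::Mclust(lv, G = 2, modelNames = "V", verbose = FALSE)
  degenerate <- is.null(fit) ||
    min(fit$parameters$pro) < min_weight ||
    abs(diff(fit$parameters$mean)) < min_separation
  if (degenerate) {
    warning("degenerate mixture fit; falling back to Otsu on log values")
    t <- .otsu_vector(lv)
    return(structure(list(threshold = exp(t), log_threshold = t,
                          method = "otsu"), class = "gate"))
  }
  t <- .mixture_crossing(fit$parameters$pro, fit$parameters$mean,
                         sqrt(fit$parameters$variance$sigmasq))
  structure(list(threshold = exp(t), log_threshold = t, method = "mixture",
                 means = exp(fit$parameters$mean),
                 weights = fit$parameters$pro),
            class = "gate")
}

#' @export
print.gate <- function(x, ...) {
  cat("<gate> threshold ", signif(x$threshold, 5), " (", x$method, ")\n",
      sep = "")
  if (!is.null(x$means))
    cat("  component means ", paste(signif(x$means, 4), collapse = " / "),
        ", weights ", paste(signif(x$weights, 3), collapse = " / "),
        "\n", sep = "")
  invisible(x)
}

#' Apply a gate to intensities
#' @param values numeric intensities.
#' @param gate a `gate` from [place_gate()].
#' @return Logical vector: value above the gate threshold.
#' @export
apply_gate <- function(values, gate) values > gate$threshold

#' Gate several markers of a cell table
#'
#' Places one gate per marker on the epithelial cells (stromal cells
#' are excluded by default: the gates describe epithelial positivity).
#'
#' @param cells a `cell_table` with layers assigned.
#' @param markers marker columns to gate.
#' @param subset logical vector selecting the cells the gates are
#'   fitted on; defaults to all non-stromal cells.
#' @param ... passed to [place_gate()].
#' @return Named list of `gate` objects (a gate set).
#' @export
gate_markers <- function(cells, markers, subset = NULL, ...) {
  if (is.null(subset))
    subset <- if ("layer" %in% names(cells)) cells$layer != "stromal"
              else rep(TRUE, nrow(cells))
  gates <- lapply(markers, function(m) {
    if (!m %in% names(cells)) return(NULL)
    place_gate(cells[[m]][subset], ...)
  })
  names(gates) <- markers
  gates[!vapply(gates, is.null, logical(1))]
}
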