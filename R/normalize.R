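# Dual normalization: reference protein (histone H1) per cell, and
# reference cells (stromal median) per section. Both are invariant to
# global channel gain.

#' Reference-protein (histone H1) normalization
#'
#' Divides each cell's marker intensity by its intensity of the
#' reference protein in the same cell — the in-situ analogue of a
#' housekeeping normalizer in qRT-PCR or Western blotting. Cells with a
#' non-positive reference value are dropped with a warning.
#'
#' @param cells a `cell_table`.
#' @param marker marker column to normalize.
#' @param reference reference-protein column (default `"H1"`).
#' @return The `cell_table` (possibly with rows dropped) with a
#'   `norm_h1_<marker>` column appended.
#' @export
normalize_reference_protein <- function(cells, marker, reference = "H1") {
  if (!reference %in% names(cells))
    stop("reference channel '", reference, "' not present in the cell table")
  if (!marker %in% names(cells))
    stop("marker channel '", marker, "' not present in the cell table")
  bad <- cells[[reference]] <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with non-positive ", reference,
            " intensity dropped")
    cells <- cells[!bad, , drop = FALSE]
  }
  cells[[paste0("norm_h1_", marker)]] <- cells[[marker]] / cells[[reference]]
  .as_cell_table(cells)
}

#' Reference-cell (stromal) normalization
#'
#' Divides every cell's marker intensity by the median intensity of the
#' same marker in the stromal cells of the same section. Stromal cells
#' act as internal normalizers; by construction the stromal median maps
#' to 1 exactly.
#'
#' @param cells a `cell_table` with layers assigned.
#' @param marker marker column to normalize.
#' @param min_stromal minimum number of stromal cells required.
#' @return The `cell_table` with a `norm_stroma_<marker>` column.
#' @export
normalize_to_stroma <- function(cells, marker, min_stromal = 20) {
  if (!"layer" %in% names(cells))
    stop("assign layers before stromal normalization")
  if (!marker %in% names(cells))
    stop("marker channel '", marker, "' not present in the cell table")
  stromal <- cells[[marker]][cells$layer == "stromal"]
  if (length(stromal) < min_stromal)
    stop("only ", length(stromal), " stromal cells; at least ", min_stromal,
         " required for stromal normalization")
  med <- stats::median(stromal)
  cells[[paste0("norm_stroma_", marker)]] <- cells[[marker]] / med
  .as_cell_table(cells)
}
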