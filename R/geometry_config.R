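#' Section geometry for the synthetic tissue generator
#'
#' Describes the 2D geometry of a rendered section. Coordinates are
#' 0-based pixel indices with `x` = column and `y` = row; `y` increases
#' downward, so "above the basement membrane" means smaller `y`. The
#' membrane is a sinusoid `y(x) = membrane_y + amplitude *
#' sin(2*pi*x/wavelength + phase)`; the stroma lies below it and the
#' epithelial layer bands stack above it.
#'
#' Defaults produce a 6000 x 210 px field at 0.5 um/px with a single
#' basal row of ~545 nuclei (>= 500 basal cells per section, enough for
#' stable percentages), two parabasal rows, five suprabasal rows and a
#' sparse stroma — roughly 4,500 cells in total.
#'
#' @param width,height image size in px.
#' @param pixel_size physical pixel size, um/px.
#' @param membrane_y membrane baseline row (px).
#' @param amplitude,wavelength sinusoid amplitude and wavelength (px).
#' @param nucleus_radius two-vector, min/max nucleus radius (px).
#' @param spacing minimum centre-to-centre nucleus spacing within a row (px).
#' @param basal_band,parabasal_band,suprabasal_band,stromal_band layer
#'   band thicknesses (px) measured from the membrane; basal defaults to
#'   one nucleus diameter and parabasal to two.
#' @param dna_mean mean nuclear-stain intensity (a.u.).
#' @param read_noise_sd Gaussian read-noise standard deviation (a.u.).
#' @param noise_gain Poisson-like signal-dependent noise gain
#'   (variance = `noise_gain` * signal).
#' @param pla_amplitude,pla_sigma peak amplitude (a.u.) and Gaussian
#'   radius (px) of a rendered PLA punctum.
#' @param territory_radius radius (px) of the cytoplasmic territory disc
#'   used to render structural (outline) markers.
#' @return A validated `section_geometry` list.
#' @export
section_geometry <- function(width = 6000, height = 210, pixel_size = 0.5,
                             membrane_y = 140, amplitude = 12,
                             wavelength = 500,
                             nucleus_radius = c(3.2, 4.0), spacing = 11,
                             basal_band = 2 * mean(nucleus_radius),
                             parabasal_band = 4 * mean(nucleus_radius),
                             suprabasal_band = 60, stromal_band = 50,
                             dna_mean = 600, read_noise_sd = 2,
                             noise_gain = 0.02,
                             pla_amplitude = 900, pla_sigma = 1.1,
                             territory_radius = 4.75) {
  g <- list(width = as.integer(width), height = as.integer(height),
            pixel_size = pixel_size, membrane_y = membrane_y,
            amplitude = amplitude, wavelength = wavelength,
            nucleus_radius = nucleus_radius, spacing = spacing,
            basal_band = basal_band, parabasal_band = parabasal_band,
            suprabasal_band = suprabasal_band, stromal_band = stromal_band,
            dna_mean = dna_mean, read_noise_sd = read_noise_sd,
            noise_gain = noise_gain, pla_amplitude = pla_amplitude,
            pla_sigma = pla_sigma, territory_radius = territory_radius)
  class(g) <- "section_geometry"
  viol <- validate_geometry(g)
  if (length(viol)) stop("invalid geometry: ", paste(viol, collapse = "; "))
  g
}

#' Validate a section geometry
#' @param g a `section_geometry`.
#' @return Character vector of violations (empty if valid).
#' @export
validate_geometry <- function(g) {
  v <- character()
  bands <- c("basal_band", "parabasal_band", "suprabasal_band", "stromal_band")
  for (b in bands) if (g[[b]] <= 0) v <- c(v, paste0(b, ": must be > 0"))
  if (g$amplitude >= g$membrane_y)
    v <- c(v, "amplitude: must be smaller than membrane baseline")
  if (g$spacing < 2 * g$nucleus_radius[1])
    v <- c(v, "spacing: must be >= 2x the minimum nucleus radius")
  if (length(g$nucleus_radius) != 2L || diff(g$nucleus_radius) < 0)
    v <- c(v, "nucleus_radius: must be an increasing (min, max) pair")
  dia <- 2 * mean(g$nucleus_radius)
  # room for at least one cell row per layer
  if (g$basal_band < dia * 0.8)
    v <- c(v, "basal_band: too thin for one row of nuclei")
  if (g$parabasal_band < dia * 0.8)
    v <- c(v, "parabasal_band: too thin for one row of nuclei")
  top <- g$membrane_y - g$amplitude -
    (g$basal_band + g$parabasal_band + g$suprabasal_band)
  if (top < 0)
    v <- c(v, "height/membrane_y: epithelial bands exceed the image top")
  if (g$membrane_y + g$amplitude + g$stromal_band > g$height)
    v <- c(v, "stromal_band: extends beyond the image bottom")
  if (g$width < 3 * g$spacing)
    v <- c(v, "width: too narrow for a cell row")
  v
}

#' Membrane curve of a geometry at a given phase
#' @keywords internal
.membrane_truth <- function(g, phase) {
  x <- 0:(g$width - 1)
  g$membrane_y + g$amplitude * sin(2 * pi * x / g$wavelength + phase)
}

#' @export
print.section_geometry <- function(x, ...) {
  cat("<section_geometry> ", x$width, " x ", x$height, " px @ ",
      x$pixel_size, " um/px\n", sep = "")
  cat("  membrane y=", x$membrane_y, " +/- ", x$amplitude,
      " px (wavelength ", x$wavelength, ")\n", sep = "")
  cat("  bands (px): basal ", round(x$basal_band, 1), ", parabasal ",
      round(x$parabasal_band, 1), ", suprabasal ", x$suprabasal_band,
      ", stromal ", x$stromal_band, "\n", sep = "")
  invisible(x)
}
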