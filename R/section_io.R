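# Section serialization: multipage TIFF + JSON channel metadata +
# ground-truth CSV + generation-config YAML.

#' Write a synthetic section to disk
#'
#' Writes `channels.tif` (one 16-bit page per channel),
#' `channels.json` (channel names in stack order), `truth.csv` (one row
#' per cell) and `config.yaml` (profile name, geometry, seed). Arrays
#' survive the round trip exactly: the renderer already quantizes to
#' integer camera counts.
#'
#' @param section a `synthetic_section`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_section <- function(section, dir) {
  stopifnot(inherits(section, "synthetic_section"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir)
  paths <- c(tif = file.path(dir, "channels.tif"),
             json = file.path(dir, "channels.json"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.yaml"))
  ok <- try({
    tiff::writeTIFF(lapply(section$channels, function(m) m / 65535),
                    paths["tif"], bits.per.sample = 16L)
    jsonlite::write_json(list(channels = names(section$channels),
                              pixel_size = section$geometry$pixel_size),
                         paths["json"], auto_unbox = TRUE, digits = NA)
    utils::write.csv(section$truth, paths["truth"], row.names = FALSE)
    yaml::write_yaml(list(profile = section$profile, seed = section$seed,
                          phase = section$phase,
                          geometry = unclass(section$geometry)),
                     paths["config"])
  }, silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed writing section to '", dir, "': ",
         attr(ok, "condition")$message)
  invisible(paths)
}

#' Read a section written by [write_section()]
#'
#' @param dir directory containing `channels.tif`, `channels.json`,
#'   `truth.csv` and `config.yaml`.
#' @return A `synthetic_section` (without `membrane_truth` unless the
#'   config allows its reconstruction, which it does for packaged
#'   geometries).
#' @export
read_section <- function(dir) {
  need <- file.path(dir, c("channels.tif", "channels.json", "truth.csv",
                           "config.yaml"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("section directory '", dir, "' is missing: ",
         paste(basename(missing), collapse = ", "))
  meta <- jsonlite::read_json(need[2], simplifyVector = TRUE)
  pages <- tiff::readTIFF(need[1], all = TRUE)
  channels <- lapply(pages, function(p) round(p * 65535))
  names(channels) <- meta$channels
  cfg <- yaml::read_yaml(need[4])
  geometry <- do.call(section_geometry, cfg$geometry[names(cfg$geometry) %in%
    names(formals(section_geometry))])
  truth <- utils::read.csv(need[3])
  section <- list(channels = channels, truth = truth,
                  membrane_truth = if (!is.null(cfg$phase))
                    .membrane_truth(geometry, cfg$phase) else NULL,
                  phase = cfg$phase, profile = cfg$profile,
                  geometry = geometry, seed = cfg$seed)
  class(section) <- "synthetic_section"
  section
}
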