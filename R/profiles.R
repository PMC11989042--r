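#' Marker panels
#'
#' A marker panel describes the antibody set of a multiplex run: one row
#' per marker with a functional role. Exactly one marker must carry the
#' `reference_protein` role (histone H1, used for per-cell
#' reference-protein normalization) and at least one marker must be
#' `structural` (an epithelial outline stain such as KRT14, required for
#' basement-membrane estimation).
#'
#' @param markers data.frame with columns `name` and `role`, or a named
#'   character vector of roles.
#' @return A `marker_panel` data.frame.
#' @export
#' @examples
#' marker_panel(c(MECP2 = "basal", H1 = "reference_protein",
#'                KRT14 = "structural"))
marker_panel <- function(markers) {
  if (is.character(markers) && !is.null(names(markers)))
    markers <- data.frame(name = names(markers), role = unname(markers))
  stopifnot(is.data.frame(markers), all(c("name", "role") %in% names(markers)))
  panel <- data.frame(name = as.character(markers$name),
                      role = as.character(markers$role))
  class(panel) <- c("marker_panel", "data.frame")
  viol <- validate_panel(panel)
  if (length(viol))
    stop("invalid marker panel: ", paste(viol, collapse = "; "))
  panel
}

panel_roles <- c("basal", "proliferation", "differentiation",
                 "reference_protein", "structural", "pla_target")

#' Validate a marker panel
#'
#' @param panel a `marker_panel` or data.frame with `name`/`role`.
#' @return Character vector of violations (empty if valid).
#' @export
validate_panel <- function(panel) {
  v <- character()
  if (anyDuplicated(panel$name))
    v <- c(v, "panel$name: marker names must be unique")
  bad <- setdiff(panel$role, panel_roles)
  if (length(bad))
    v <- c(v, paste0("panel$role: unknown role(s) ",
                     paste(bad, collapse = ", ")))
  if (sum(panel$role == "reference_protein") != 1L)
    v <- c(v, "panel$role: exactly one reference_protein marker required")
  if (!any(panel$role == "structural"))
    v <- c(v, "panel$role: at least one structural marker required")
  v
}

#' The packaged default 13-marker panel
#'
#' Basal/stemness markers (MECP2, XPC, TP63, ITGB1, KRT15, EGFR, FTH1),
#' proliferation markers (MCM2, PCNA, Ki67), the differentiation marker
#' KRT10/13, histone H1 as reference protein and KRT14 as the
#' structural epithelial outline.
#'
#' @return A `marker_panel`.
#' @export
default_panel <- function() {
  .profile_db()$panel
}

.profiles_env <- new.env(parent = emptyenv())

.profile_db <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "profiles.yaml", package = "stratiquant")
  key <- normalizePath(path)
  if (!is.null(.profiles_env[[key]])) return(.profiles_env[[key]])
  raw <- yaml::read_yaml(path)
  panel <- marker_panel(do.call(rbind, lapply(raw$panel, function(m)
    data.frame(name = m$name, role = m$role))))
  profiles <- lapply(names(raw$profiles), function(nm)
    .build_profile(nm, raw$profiles[[nm]], panel))
  names(profiles) <- names(raw$profiles)
  db <- list(panel = panel, profiles = profiles)
  .profiles_env[[key]] <- db
  db
}

.layer_names <- c("stromal", "basal", "parabasal", "suprabasal")

.build_marker_entry <- function(e) {
  m <- list(mean = as.numeric(e$mean),
            pos_frac = if (is.null(e$pos_frac)) 1 else as.numeric(e$pos_frac),
            neg_mean = if (is.null(e$neg_mean)) NA_real_ else as.numeric(e$neg_mean),
            cv = if (is.null(e$cv)) 0.35 else as.numeric(e$cv))
  # derive the positive-component mean so layer means hold exactly
  if (m$pos_frac == 0) {
    m$neg_mean <- m$mean
    m$pos_mean <- NA_real_
  } else if (m$pos_frac == 1) {
    m$pos_mean <- m$mean
    if (is.na(m$neg_mean)) m$neg_mean <- 0
  } else {
    m$pos_mean <- (m$mean - (1 - m$pos_frac) * m$neg_mean) / m$pos_frac
  }
  m
}

.build_profile <- function(name, spec, panel) {
  layers <- lapply(spec$layers, function(l) {
    list(pla_rate = as.numeric(l$pla_rate),
         markers = lapply(l$markers, .build_marker_entry))
  })
  delam <- spec$delamination
  prof <- list(
    name = name,
    description = if (is.null(spec$description)) "" else spec$description,
    panel = panel,
    basal_like = isTRUE(spec$basal_like),
    layers = layers,
    delamination = list(
      frequency = if (is.null(delam$frequency)) 0 else as.numeric(delam$frequency),
      proliferation = lapply(delam$proliferation, as.numeric),
      overrides = lapply(delam$overrides, .build_marker_entry)))
  class(prof) <- "species_profile"
  prof
}

#' Retrieve a packaged species/condition profile
#'
#' Packaged profiles encode the organization models of normal stratified
#' squamous epithelium in several mammals plus human disease progression
#' states: `human` (quiescent MECP2-high/XPC-high basal stem cell layer,
#' proliferative parabasal compartment), `mouse` and `rat`
#' (basal-restricted proliferation, flat MECP2/XPC), `monkey`
#' (attenuated drop), `dog` (human-like, two FTH1-split basal
#' populations), and `human_lgd`/`human_hgd`/`human_scc` (progressive
#' dysplasia/carcinoma states with reduced MECP2/XPC and a PLA-rate
#' recovery in carcinoma). `uniform_test` is a degenerate profile with
#' identical layers, useful for null checks (every fold-change is 1).
#'
#' The human profile anchors the printed organization numbers: a 16-fold
#' basal-to-suprabasal drop in MECP2 and 5-fold in XPC; 5-fold (MECP2)
#' and 11-fold (XPC) higher basal expression than mouse; basal
#' positivity fractions 0.8824 (XPC), 0.6706 (ITGB1), 0.6353 (KRT15),
#' 0.6235 (EGFR-high); and delaminating-cell proliferation
#' probabilities 0.40 (MCM2/PCNA) and 0.20 (Ki67).
#'
#' @param name profile name; see Details.
#' @return A validated `species_profile`.
#' @export
#' @examples
#' hp <- default_profile("human")
#' profile_mean(hp, "MECP2", "basal") / profile_mean(hp, "MECP2", "suprabasal")
default_profile <- function(name) {
  if (identical(name, "uniform_test")) return(uniform_profile())
  db <- .profile_db()
  if (!name %in% names(db$profiles))
    stop("unknown profile '", name, "'; available: ",
         paste(c(names(db$profiles), "uniform_test"), collapse = ", "))
  prof <- db$profiles[[name]]
  viol <- validate_profile(prof)
  if (length(viol))
    stop("packaged profile '", name, "' failed validation: ",
         paste(viol, collapse = "; "))
  prof
}

#' List the packaged profile names
#' @return Character vector of profile names.
#' @export
list_profiles <- function() c(names(.profile_db()$profiles), "uniform_test")

#' Build a uniform null profile
#'
#' All four layers share the same intensity model for every marker, so
#' every true fold-change between layers equals 1. Intended for
#' null/identity checks of the quantification stages.
#'
#' @param mean common marker mean intensity (a.u.).
#' @param cv log-normal coefficient of variation.
#' @param pla_rate common puncta rate per cell.
#' @return A `species_profile` named `uniform_test`.
#' @export
uniform_profile <- function(mean = 300, cv = 0.35, pla_rate = 1) {
  panel <- .profile_db()$panel
  entry <- .build_marker_entry(list(mean = mean, cv = cv))
  markers <- stats::setNames(rep(list(entry), nrow(panel)), panel$name)
  layer <- list(pla_rate = pla_rate, markers = markers)
  prof <- list(name = "uniform_test",
               description = "identity profile: all layers identical",
               panel = panel, basal_like = FALSE,
               layers = stats::setNames(rep(list(layer), 4), .layer_names),
               delamination = list(frequency = 0, proliferation = list(),
                                   overrides = list()))
  class(prof) <- "species_profile"
  prof
}

#' Validate a species profile
#'
#' Checks the structural invariants of a generative profile: all four
#' layers present, all positivity fractions in \[0, 1\], positive scale
#' parameters, non-negative PLA rates, and consistent mixture means
#' (the derived positive-component mean must exceed the negative mean).
#' Violations are returned, not raised.
#'
#' @param profile a `species_profile`.
#' @return Character vector of violations; empty if the profile is valid.
#' @export
validate_profile <- function(profile) {
  v <- character()
  if (!inherits(profile, "species_profile"))
    return("profile: not a species_profile object")
  v <- c(v, validate_panel(profile$panel))
  missing <- setdiff(.layer_names, names(profile$layers))
  if (length(missing))
    v <- c(v, paste0("layers: missing layer ", paste(missing, collapse = ", ")))
  for (ln in intersect(names(profile$layers), .layer_names)) {
    l <- profile$layers[[ln]]
    if (is.null(l$pla_rate) || is.na(l$pla_rate) || l$pla_rate < 0)
      v <- c(v, paste0("layers$", ln, "$pla_rate: must be >= 0"))
    for (mn in names(l$markers)) {
      m <- l$markers[[mn]]
      at <- paste0("layers$", ln, "$markers$", mn)
      if (!is.finite(m$mean) || m$mean <= 0)
        v <- c(v, paste0(at, "$mean: must be finite and > 0"))
      if (!is.finite(m$pos_frac) || m$pos_frac < 0 || m$pos_frac > 1)
        v <- c(v, paste0(at, "$pos_frac: must be in [0, 1]"))
      if (!is.finite(m$cv) || m$cv <= 0)
        v <- c(v, paste0(at, "$cv: scale must be > 0"))
      if (is.finite(m$pos_frac) && m$pos_frac > 0 && m$pos_frac < 1) {
        if (!is.finite(m$neg_mean) || m$neg_mean <= 0)
          v <- c(v, paste0(at, "$neg_mean: required and > 0 for mixtures"))
        else if (is.finite(m$pos_mean) && m$pos_mean <= m$neg_mean)
          v <- c(v, paste0(at, ": derived pos_mean must exceed neg_mean"))
      }
    }
    extra <- setdiff(profile$panel$name, names(l$markers))
    if (length(extra))
      v <- c(v, paste0("layers$", ln, "$markers: missing marker(s) ",
                       paste(extra, collapse = ", ")))
  }
  d <- profile$delamination
  if (d$frequency < 0)
    v <- c(v, "delamination$frequency: must be >= 0")
  for (mn in names(d$proliferation)) {
    p <- d$proliferation[[mn]]
    if (!is.finite(p) || p < 0 || p > 1)
      v <- c(v, paste0("delamination$proliferation$", mn, ": must be in [0, 1]"))
  }
  v
}

#' Effective layer mean of a marker
#'
#' The arithmetic mean intensity a layer generates for a marker,
#' including its positive/negative mixture:
#' `pos_frac * pos_mean + (1 - pos_frac) * neg_mean`. Packaged
#' fold-change anchors (e.g. the human 16-fold basal/suprabasal MECP2
#' drop) hold exactly on these values.
#'
#' @param profile a `species_profile`.
#' @param marker marker name.
#' @param layer one of `"stromal"`, `"basal"`, `"parabasal"`, `"suprabasal"`.
#' @return Numeric mean intensity (a.u.).
#' @export
profile_mean <- function(profile, marker, layer) {
  l <- profile$layers[[match.arg(layer, .layer_names)]]
  m <- l$markers[[marker]]
  if (is.null(m)) stop("marker '", marker, "' not in profile")
  m$mean
}

#' Per-layer positivity fraction of a marker
#' @inheritParams profile_mean
#' @return Numeric fraction in \[0, 1\].
#' @export
profile_pos_frac <- function(profile, marker, layer) {
  l <- profile$layers[[match.arg(layer, .layer_names)]]
  m <- l$markers[[marker]]
  if (is.null(m)) stop("marker '", marker, "' not in profile")
  m$pos_frac
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile> ", x$name, "\n", sep = "")
  if (nzchar(x$description)) cat(strwrap(x$description, indent = 2,
                                         exdent = 2), sep = "\n")
  cat("  markers: ", paste(x$panel$name, collapse = ", "), "\n", sep = "")
  cat("  layers:  ", paste(names(x$layers), collapse = ", "),
      if (x$basal_like) "  (basal-like: layering lost)", "\n", sep = "")
  cat("  delamination: ", x$delamination$frequency,
      " per 100 basal cells\n", sep = "")
  invisible(x)
}
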