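# Pipeline orchestration: synth -> segment -> geometry -> quant -> pla,
# plus truth matching and the packaged replication scenarios.

#' Run segmentation, membrane estimation and layer/delamination
#' assignment on one section
#'
#' The image-to-cell-table workhorse shared by [run_pipeline()] and the
#' replication scenarios.
#'
#' @param section a `synthetic_section` (or an equivalent list with
#'   `channels` and `geometry`).
#' @param seg_params parameters for [segment_nuclei()].
#' @param membrane_params parameters for [estimate_membrane()].
#' @param structural name of the structural (outline) channel.
#' @param params optional [layer_params()]; defaults are derived from
#'   the section geometry (basal band = one nucleus diameter).
#' @return List with `cells` (a fully annotated `cell_table`),
#'   `labels` and `membrane`.
#' @export
analyze_section <- function(section, seg_params = list(),
                            membrane_params = list(),
                            structural = "KRT14", params = NULL) {
  g <- section$geometry
  labels <- segment_nuclei(section$channels$DNA, seg_params)
  cells <- extract_cell_table(labels, section$channels,
                              pixel_size = g$pixel_size)
  membrane <- estimate_membrane(section$channels[[structural]],
                                membrane_params)
  if (is.null(params))
    params <- layer_params(basal_depth = g$basal_band * g$pixel_size,
                           parabasal_depth = g$parabasal_band * g$pixel_size)
  cells <- assign_layers(cells, membrane, params)
  cells <- detect_delaminating(cells, labels, membrane, params)
  list(cells = cells, labels = labels, membrane = membrane)
}

#' Match segmented cells to ground truth by nearest centroid
#'
#' Greedy nearest-centroid matching within `max_dist` px (default: the
#' mean true nucleus radius). Each truth cell and each segmented cell
#' is used at most once.
#'
#' @param cells a `cell_table`.
#' @param truth the `truth` data.frame of a `synthetic_section`.
#' @param max_dist maximum centroid distance (px).
#' @return data.frame with `truth_row`, `cell_row` and `dist` (px), one
#'   row per matched pair.
#' @export
match_to_truth <- function(cells, truth, max_dist = mean(truth$radius)) {
  ord <- order(cells$x)
  cx <- cells$x[ord]; cy <- cells$y[ord]
  cand <- lapply(seq_len(nrow(truth)), function(i) {
    lo <- findInterval(truth$x[i] - max_dist, cx) + 1L
    hi <- findInterval(truth$x[i] + max_dist, cx)
    if (hi < lo) return(NULL)
    j <- lo:hi
    d2 <- (cx[j] - truth$x[i])^2 + (cy[j] - truth$y[i])^2
    keep <- d2 <= max_dist^2
    if (!any(keep)) return(NULL)
    data.frame(truth_row = i, cell_row = ord[j[keep]], d2 = d2[keep])
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand))
    return(data.frame(truth_row = integer(), cell_row = integer(),
                      dist = numeric()))
  cand <- cand[order(cand$d2), ]
  taken_t <- logical(nrow(truth)); taken_c <- logical(nrow(cells))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ti <- cand$truth_row[k]; ci <- cand$cell_row[k]
    if (!taken_t[ti] && !taken_c[ci]) {
      keep[k] <- TRUE; taken_t[ti] <- TRUE; taken_c[ci] <- TRUE
    }
  }
  out <- cand[keep, ]
  data.frame(truth_row = out$truth_row, cell_row = out$cell_row,
             dist = sqrt(out$d2), row.names = NULL)
}

.pipeline_stages <- c("synth", "segment", "geometry", "quant", "pla")

#' Run the full pipeline over seeded synthetic sections
#'
#' Executes the requested stages for each seed: section synthesis,
#' segmentation, membrane/layer geometry, quantification (dual
#' normalization, gating, capture, fold changes, delamination
#' statistics) and PLA puncta counting. Fully reproducible given the
#' seed list; when `out_dir` is set, per-seed cell tables (CSV) and a
#' stats report (JSON) are written.
#'
#' @param config list (or path to a YAML file) with entries: `profile`
#'   (name or `species_profile`), `geometry` (overrides for
#'   [section_geometry()]), `seeds` (integer vector, required),
#'   `stages` (subset of synth/segment/geometry/quant/pla), `out_dir`,
#'   `alpha` (significance level, in (0,1)).
#' @return A `pipeline_report`: per-seed results plus aggregate
#'   fold-change and capture summaries.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(profile = "human", geometry = list(), seeds = NULL,
         stages = .pipeline_stages, out_dir = NULL, alpha = 0.05),
    config)
  bad <- setdiff(cfg$stages, .pipeline_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (available: ", paste(.pipeline_stages, collapse = ", "), ")")
  if (!length(cfg$seeds)) stop("config$seeds must be a non-empty seed list")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  profile <- if (inherits(cfg$profile, "species_profile")) cfg$profile
             else default_profile(cfg$profile)
  geometry <- do.call(section_geometry, cfg$geometry)
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)

  run_seed <- function(seed) {
    res <- list(seed = seed)
    section <- synthesize_section(profile, geometry, seed)
    res$n_cells_truth <- nrow(section$truth)
    if (!any(c("segment", "geometry", "quant", "pla") %in% cfg$stages))
      return(res)
    ana <- analyze_section(section)
    cells <- ana$cells
    if ("quant" %in% cfg$stages) {
      for (m in c("MECP2", "XPC")) {
        cells <- normalize_reference_protein(cells, m)
        cells <- normalize_to_stroma(cells, m)
      }
      gates <- gate_markers(cells, c("XPC", "ITGB1", "KRT15", "EGFR",
                                     "MCM2", "PCNA", "Ki67"))
      grp_a <- "basal"; grp_b <- "suprabasal"
      fc <- lapply(c(MECP2 = "MECP2", XPC = "XPC"), function(m) {
        lapply(c(raw = m, h1 = paste0("norm_h1_", m),
                 stroma = paste0("norm_stroma_", m)),
               function(col) fold_change(cells, col, a = grp_a, b = grp_b,
                                         seed = seed))
      })
      res$fold_changes <- fc
      res$capture <- capture_stats(cells, gates,
                                   markers = c("XPC", "ITGB1", "KRT15",
                                               "EGFR"))
      res$delamination <- delamination_stats(cells, gates)
      # per-layer box-plot summaries: median with the 25th/75th percentiles
      res$layer_summary <- do.call(rbind, lapply(
        c("MECP2", "XPC", "MCM2"), function(m) {
          agg <- stats::aggregate(cells[[m]], by = list(layer = cells$layer),
                                  FUN = function(v)
                                    stats::quantile(v, c(0.25, 0.5, 0.75)))
          data.frame(marker = m, layer = agg$layer, q25 = agg$x[, 1],
                     median = agg$x[, 2], q75 = agg$x[, 3])
        }))
    }
    if ("pla" %in% cfg$stages) {
      counts <- detect_puncta(section$channels$PLA, ana$labels)
      cells$puncta <- counts[cells$cell_id]
      res$pla_by_layer <- stats::aggregate(puncta ~ layer, data = cells,
                                           FUN = stats::median)
    }
    res$cells <- cells
    if (!is.null(cfg$out_dir))
      utils::write.csv(cells, file.path(cfg$out_dir,
                                        sprintf("cells_seed%d.csv", seed)),
                       row.names = FALSE)
    res
  }
  runs <- lapply(cfg$seeds, run_seed)
  report <- list(config = cfg[setdiff(names(cfg), "out_dir")], runs = runs)
  if ("quant" %in% cfg$stages) {
    report$aggregate <- list(
      mecp2_basal_suprabasal = mean(vapply(runs, function(r)
        r$fold_changes$MECP2$raw$mean_ratio, numeric(1))),
      xpc_basal_suprabasal = mean(vapply(runs, function(r)
        r$fold_changes$XPC$raw$mean_ratio, numeric(1))),
      capture_percent = rowMeans(sapply(runs, function(r)
        r$capture$capture$percent)))
    names(report$aggregate$capture_percent) <- runs[[1]]$capture$capture$marker
  }
  class(report) <- "pipeline_report"
  if (!is.null(cfg$out_dir)) {
    stats_out <- list(
      profile = profile$name, seeds = cfg$seeds,
      aggregate = report$aggregate,
      per_seed = lapply(runs, function(r)
        list(seed = r$seed,
             mecp2_ratio = if (!is.null(r$fold_changes))
               r$fold_changes$MECP2$raw$mean_ratio,
             xpc_ratio = if (!is.null(r$fold_changes))
               r$fold_changes$XPC$raw$mean_ratio,
             n_delaminating = if (!is.null(r$delamination))
               r$delamination$n_delaminating)))
    jsonlite::write_json(stats_out, file.path(cfg$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> profile '", x$config$profile, "', ",
      length(x$runs), " seed(s)\n", sep = "")
  if (!is.null(x$aggregate)) {
    cat(sprintf("  MECP2 basal/suprabasal mean ratio: %.2f\n",
                x$aggregate$mecp2_basal_suprabasal))
    cat(sprintf("  XPC   basal/suprabasal mean ratio: %.2f\n",
                x$aggregate$xpc_basal_suprabasal))
    cp <- x$aggregate$capture_percent
    cat("  basal capture: ",
        paste(sprintf("%s %.1f%%", names(cp), cp), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Run the packaged replication scenarios
#'
#' Runs the five packaged study scenarios on seeded synthetic data —
#' human-vs-mouse organization fold changes, basal-marker capture,
#' delamination proliferation state, dog two-population basal
#' clustering, and PLA progression — and reports recovered against
#' encoded values. Section sizes default to a reduced field width for
#' responsiveness; the encoded values do not depend on the seed list.
#'
#' @param seeds integer seeds for the synthetic sections.
#' @param geometry a `section_geometry` used for all imaging scenarios.
#' @param out_dir optional directory for a JSON report.
#' @return A `scenario_report` list with elements `fold_changes`,
#'   `capture`, `delamination`, `dog_clustering`, `pla_progression` and
#'   a `comparison` data.frame of recovered vs encoded values.
#' @export
replicate_scenarios <- function(seeds = 1:3,
                                geometry = section_geometry(width = 2000),
                                out_dir = NULL) {
  human <- default_profile("human")
  mouse <- default_profile("mouse")
  dog <- default_profile("dog")

  analyze <- function(profile, seed) {
    section <- synthesize_section(profile, geometry, seed)
    ana <- analyze_section(section)
    list(section = section, cells = ana$cells)
  }
  hu <- lapply(seeds, function(s) analyze(human, s))
  mo <- lapply(seeds, function(s) analyze(mouse, s))

  basal_mean <- function(run, m)
    mean(run$cells[[m]][run$cells$layer == "basal"])
  ratio_seeded <- function(f) mean(vapply(seq_along(seeds), f, numeric(1)))

  fc <- list(
    mecp2_basal_suprabasal = ratio_seeded(function(i)
      fold_change(hu[[i]]$cells, "MECP2", a = "basal", b = "suprabasal",
                  seed = seeds[i])$mean_ratio),
    xpc_basal_suprabasal = ratio_seeded(function(i)
      fold_change(hu[[i]]$cells, "XPC", a = "basal", b = "suprabasal",
                  seed = seeds[i])$mean_ratio),
    mecp2_human_mouse = ratio_seeded(function(i)
      basal_mean(hu[[i]], "MECP2") / basal_mean(mo[[i]], "MECP2")),
    xpc_human_mouse = ratio_seeded(function(i)
      basal_mean(hu[[i]], "XPC") / basal_mean(mo[[i]], "XPC")))

  cap <- rowMeans(sapply(seq_along(seeds), function(i) {
    gates <- gate_markers(hu[[i]]$cells, c("XPC", "ITGB1", "KRT15"))
    capture_stats(hu[[i]]$cells, gates)$capture$percent
  }))
  names(cap) <- c("XPC", "ITGB1", "KRT15")

  delam_pos <- c(MCM2 = 0L, PCNA = 0L, Ki67 = 0L); delam_n <- 0L
  for (i in seq_along(seeds)) {
    cells <- hu[[i]]$cells
    gates <- gate_markers(cells, names(delam_pos))
    dl <- which(!is.na(cells$delaminating) & cells$delaminating)
    delam_n <- delam_n + length(dl)
    for (m in names(delam_pos))
      delam_pos[m] <- delam_pos[m] +
        sum(apply_gate(cells[[m]][dl], gates[[m]]))
  }
  delam <- list(n = delam_n, percent = 100 * delam_pos / max(delam_n, 1))

  dg <- analyze(dog, seeds[1])
  dmatch <- match_to_truth(dg$cells, dg$section$truth)
  dcells <- dg$cells[dmatch$cell_row, ]
  dtruth <- dg$section$truth[dmatch$truth_row, ]
  sel <- dcells$layer == "basal" & dtruth$layer == "basal" &
    !dtruth$delaminating
  cl <- cluster_basal(.as_cell_table(dcells,
                                     attr(dg$cells, "pixel_size")),
                      c("FTH1", "MECP2", "TP63"), k = 2,
                      subset = sel, seed = seeds[1])
  ari <- mclust::adjustedRandIndex(cl$labels,
                                   dtruth$pos_FTH1[cl$cells_idx])
  dogres <- list(ari = ari, medians = cl$medians)

  cohort <- simulate_pla_cohort(seed = seeds[1])
  pla <- progression_summary(cohort$count, cohort$group, cohort$sample)

  enc <- function(p, m, l) profile_mean(p, m, l)
  comparison <- data.frame(
    quantity = c("MECP2 basal/suprabasal", "XPC basal/suprabasal",
                 "MECP2 human/mouse basal", "XPC human/mouse basal",
                 "XPC capture %", "ITGB1 capture %", "KRT15 capture %",
                 "delaminating MCM2 %"),
    recovered = c(fc$mecp2_basal_suprabasal, fc$xpc_basal_suprabasal,
                  fc$mecp2_human_mouse, fc$xpc_human_mouse,
                  cap["XPC"], cap["ITGB1"], cap["KRT15"],
                  delam$percent[["MCM2"]]),
    encoded = c(enc(human, "MECP2", "basal") / enc(human, "MECP2", "suprabasal"),
                enc(human, "XPC", "basal") / enc(human, "XPC", "suprabasal"),
                enc(human, "MECP2", "basal") / enc(mouse, "MECP2", "basal"),
                enc(human, "XPC", "basal") / enc(mouse, "XPC", "basal"),
                100 * profile_pos_frac(human, "XPC", "basal"),
                100 * profile_pos_frac(human, "ITGB1", "basal"),
                100 * profile_pos_frac(human, "KRT15", "basal"),
                100 * human$delamination$proliferation$MCM2))
  report <- list(fold_changes = fc, capture = cap, delamination = delam,
                 dog_clustering = dogres, pla_progression = pla,
                 comparison = comparison, seeds = seeds)
  class(report) <- "scenario_report"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(
      list(comparison = comparison, dog_ari = ari,
           pla_tests = pla$tests, seeds = seeds),
      file.path(out_dir, "scenarios.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report> seeds: ", paste(x$seeds, collapse = ", "), "\n",
      sep = "")
  df <- x$comparison
  df$recovered <- signif(df$recovered, 4)
  print(df, row.names = FALSE)
  cat(sprintf("dog basal two-population clustering ARI: %.3f\n",
              x$dog_clustering$ari))
  cat("PLA progression recovery pattern: ",
      if (isTRUE(x$pla_progression$recovery)) "present" else "absent",
      "\n", sep = "")
  invisible(x)
}
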