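# Cross-dataset marker-list logic for the scRNA-seq comparison:
# consensus sets, species-specific sets and Venn region counts.

#' Build a marker list collection
#'
#' @param sets named list of gene symbol vectors.
#' @param species species tag per set (`"human"` or `"mouse"`),
#'   recycled if length 1.
#' @param provenance optional provenance string per set.
#' @return A `marker_list_collection`. Symbols are uppercased (mouse
#'   title-case symbols map onto human symbols) and deduplicated per
#'   dataset.
#' @export
marker_list_collection <- function(sets, species,
                                   provenance = rep("", length(sets))) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  species <- rep_len(as.character(species), length(sets))
  bad <- setdiff(species, c("human", "mouse"))
  if (length(bad))
    stop("unknown species tag(s): ", paste(unique(bad), collapse = ", "),
         " (expected human or mouse)")
  sets <- lapply(sets, function(s) unique(toupper(as.character(s))))
  structure(list(sets = sets, species = stats::setNames(species, names(sets)),
                 provenance = stats::setNames(rep_len(provenance,
                                                      length(sets)),
                                              names(sets))),
            class = "marker_list_collection")
}

#' Load marker lists from TSV or GMT files
#'
#' TSV files need columns `gene` and `dataset` (and optionally
#' `species`); GMT files contribute one set per line. Symbols are
#' matched case-insensitively (uppercased), which maps mouse title-case
#' symbols (`Xpc`) onto human symbols (`XPC`).
#'
#' @param paths files to load (`.tsv`/`.txt` or `.gmt`).
#' @param species species tag per file; for TSVs with a `species`
#'   column, that column wins.
#' @return A `marker_list_collection`.
#' @export
load_marker_lists <- function(paths, species) {
  species <- rep_len(as.character(species), length(paths))
  sets <- list(); tags <- character(); prov <- character()
  for (i in seq_along(paths)) {
    path <- paths[i]
    ext <- tolower(tools::file_ext(path))
    if (ext == "gmt") {
      gs <- fgsea::gmtPathways(path)
      for (nm in names(gs)) {
        sets[[nm]] <- gs[[nm]]
        tags[nm] <- species[i]
        prov[nm] <- path
      }
    } else {
      df <- utils::read.delim(path, stringsAsFactors = FALSE)
      if (!all(c("gene", "dataset") %in% names(df)))
        stop("TSV '", path, "' needs columns gene and dataset")
      for (ds in unique(df$dataset)) {
        rows <- df[df$dataset == ds, , drop = FALSE]
        sets[[ds]] <- rows$gene
        tags[ds] <- if ("species" %in% names(df)) rows$species[1] else
          species[i]
        prov[ds] <- path
      }
    }
  }
  marker_list_collection(sets, tags[names(sets)], prov[names(sets)])
}

#' @export
print.marker_list_collection <- function(x, ...) {
  cat("<marker_list_collection> ", length(x$sets), " datasets\n", sep = "")
  for (nm in names(x$sets))
    cat("  ", nm, " (", x$species[nm], "): ", length(x$sets[[nm]]),
        " genes\n", sep = "")
  invisible(x)
}

.species_sets <- function(collection, species) {
  collection$sets[collection$species == species]
}

#' Consensus gene set for one species
#'
#' Genes appearing in at least `min_datasets` of the species' lists —
#' the selection rule behind robust basal-marker sets.
#'
#' @param collection a `marker_list_collection`.
#' @param species `"human"` or `"mouse"`.
#' @param min_datasets minimum number of lists a gene must appear in.
#' @return Character vector of gene symbols (sorted).
#' @export
consensus <- function(collection, species, min_datasets = 2) {
  sets <- .species_sets(collection, species)
  if (min_datasets > length(sets))
    stop("min_datasets (", min_datasets, ") exceeds the number of ",
         species, " lists (", length(sets), ")")
  counts <- table(unlist(sets))
  sort(names(counts)[counts >= min_datasets])
}

#' Species-specific and shared marker sets
#'
#' `mouse_specific` = mouse consensus minus the union of all human
#' lists (markers robust in mouse and absent from any human list);
#' `human_specific` symmetrically; `shared` = intersection of the two
#' consensuses.
#'
#' @param collection a `marker_list_collection` containing both species.
#' @param min_datasets consensus threshold per species.
#' @return List with `human_specific`, `mouse_specific`, `shared`.
#' @export
species_specific <- function(collection, min_datasets = 2) {
  for (sp in c("human", "mouse"))
    if (!any(collection$species == sp))
      stop("species '", sp, "' absent from the collection")
  hu_cons <- consensus(collection, "human",
                       min(min_datasets, sum(collection$species == "human")))
  mo_cons <- consensus(collection, "mouse",
                       min(min_datasets, sum(collection$species == "mouse")))
  hu_union <- unique(unlist(.species_sets(collection, "human")))
  mo_union <- unique(unlist(.species_sets(collection, "mouse")))
  list(human_specific = sort(setdiff(hu_cons, mo_union)),
       mouse_specific = sort(setdiff(mo_cons, hu_union)),
       shared = sort(intersect(hu_cons, mo_cons)))
}

#' Venn region counts for up to five marker lists
#'
#' Counts the genes in every region of the Venn diagram of the selected
#' lists. Region names encode membership as `A&B` style combinations;
#' the counts always sum to the size of the union.
#'
#' @param collection a `marker_list_collection`.
#' @param species restrict to one species' lists (optional).
#' @param sets names of the lists to use (default: all selected lists).
#' @return Named integer vector of region counts.
#' @export
venn_counts <- function(collection, species = NULL, sets = NULL) {
  pool <- if (is.null(species)) collection$sets
          else .species_sets(collection, species)
  if (!is.null(sets)) pool <- pool[sets]
  if (length(pool) < 2) stop("at least 2 sets required")
  if (length(pool) > 5)
    stop("more than 5 sets; consider an upset-style summary instead")
  genes <- unique(unlist(pool))
  membership <- sapply(pool, function(s) genes %in% s)
  if (length(genes) == 1) membership <- matrix(membership, nrow = 1,
                                               dimnames = list(NULL,
                                                               names(pool)))
  key <- apply(membership, 1, function(r)
    paste(names(pool)[r], collapse = "&"))
  counts <- table(key)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
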