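# File formats and provenance: sample metadata TSV, FASTA, Newick with a
# tip-age sidecar, deme-graph YAML configuration, and run manifests.

#' Read a sample metadata table
#'
#' Tab-separated file with columns `id`, `deme`, `age_ky` and optionally
#' `lat`, `lon`. Ages are in ky BP; samples younger than 0.5 ky are
#' classified as modern.
#'
#' @param path TSV file path.
#' @param graph Optional [deme_graph()]; if given, deme labels are checked
#'   against it.
#' @return data.frame with the input columns plus logical `is_modern`.
#' @export
read_metadata <- function(path, graph = NULL) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "deme", "age_ky")
  if (!all(need %in% names(md))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(md$id)) {
    stop("duplicate sample id: ",
         paste(unique(md$id[duplicated(md$id)]), collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(md$age_ky))
  if (any(is.na(age))) {
    stop("malformed age for id: ",
         paste(md$id[is.na(age)], collapse = ", "))
  }
  if (any(age < 0)) {
    stop("negative age for id: ", paste(md$id[age < 0], collapse = ", "))
  }
  md$age_ky <- age
  if (!is.null(graph)) {
    bad <- setdiff(unique(md$deme), graph$demes)
    if (length(bad)) stop("unknown deme: ", paste(bad, collapse = ", "))
  }
  md$is_modern <- md$age_ky < 0.5
  md
}

#' Write a sample metadata table
#' @param samples data.frame with at least `id`, `deme`, `age_ky`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write FASTA alignments
#'
#' Thin wrappers over ape's FASTA support returning/accepting `DNAbin`
#' matrices; `read_alignment` checks that all sequences have equal length.
#'
#' @param path File path.
#' @return `read_alignment`: a `DNAbin` matrix.
#' @export
read_alignment <- function(path) {
  aln <- ape::read.FASTA(path)
  len <- lengths(aln)
  if (length(unique(len)) != 1L) {
    stop("sequences have unequal lengths: not an alignment")
  }
  as.matrix(aln)
}

#' @rdname read_alignment
#' @param aln A `DNAbin` alignment.
#' @export
write_alignment <- function(aln, path) {
  ape::write.FASTA(as.matrix(aln), path)
  invisible(path)
}

#' Write a genealogy as Newick plus a tip metadata sidecar
#'
#' The tree is written with branch lengths in ky; the sidecar TSV holds tip
#' ids, demes and ages so the genealogy can be re-read with
#' [read_dated_tree()].
#'
#' @param g A `genealogy`.
#' @param path Newick output path; the sidecar is written next to it with
#'   suffix `.tips.tsv`.
#' @return Named character vector with the two paths, invisibly.
#' @export
write_genealogy <- function(g, path) {
  ape::write.tree(g$phylo, file = path)
  side <- paste0(path, ".tips.tsv")
  md <- data.frame(id = g$phylo$tip.label,
                   deme = unname(g$tip_deme[g$phylo$tip.label]),
                   age_ky = unname(g$tip_age[g$phylo$tip.label]),
                   stringsAsFactors = FALSE)
  write_metadata(md, side)
  invisible(c(tree = path, tips = side))
}

#' Read a genealogy written by [write_genealogy()]
#' @param path Newick path (sidecar expected at `<path>.tips.tsv`).
#' @return A `genealogy`.
#' @export
read_genealogy <- function(path) {
  md <- read_metadata(paste0(path, ".tips.tsv"))
  read_dated_tree(path, md)
}

#' Deme-graph configuration files
#'
#' The graph is serialized to YAML with three blocks: `demes` (ordered
#' names), `edges` (list of two-element pairs) and `stat_groups` (deme to
#' group mapping). `write_graph_config(deme_graph(), path)` produces the
#' default configuration.
#'
#' @param path YAML file path.
#' @return `read_graph_config`: a [deme_graph()].
#' @export
read_graph_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$demes) || is.null(cfg$edges) || is.null(cfg$stat_groups)) {
    stop("graph config needs 'demes', 'edges' and 'stat_groups'")
  }
  edges <- do.call(rbind, lapply(cfg$edges, function(e) {
    if (length(e) != 2L) stop("each edge must have two endpoints")
    as.character(e)
  }))
  deme_graph(demes = unlist(cfg$demes), edges = edges,
             stat_groups = unlist(cfg$stat_groups))
}

#' @rdname read_graph_config
#' @param graph A [deme_graph()].
#' @export
write_graph_config <- function(graph, path) {
  cfg <- list(
    demes = as.list(graph$demes),
    edges = lapply(seq_len(nrow(graph$edges)),
                   function(i) as.list(graph$edges[i, ])),
    stat_groups = as.list(graph$stat_groups)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write ground-truth and manifest JSON records
#'
#' `write_truth` serializes the truth record of a pseudo-observed data set;
#' `write_run_manifest` records the settings, seeds and package version of
#' an analysis run so outputs can be reproduced bit for bit.
#'
#' @param truth Truth list from [make_pseudo_observed()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_truth
#' @param settings Named list of run settings (seeds, counts, file paths).
#' @param dir Output directory; the manifest is written as `manifest.json`.
#' @export
write_run_manifest <- function(settings, dir) {
  man <- c(list(package = "wolfdemog",
                version = as.character(utils::packageVersion("wolfdemog")),
                timestamp = format(Sys.time(), tz = "UTC")),
           settings)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
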