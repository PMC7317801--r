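# Reduction of a dated genealogy to the TMRCA summary statistics used for
# scenario selection: mean pairwise TMRCA within and between the four
# deme groups (EUR, ME, EAS, AME).

# Column order of the 10 group-combination sums produced by the engine.
STAT_NAMES_FULL <- c("within_EUR", "within_ME", "within_EAS", "within_AME",
                     "EUR_ME", "EUR_EAS", "EUR_AME",
                     "ME_EAS", "ME_AME", "EAS_AME")

#' Names of the nine TMRCA summary statistics
#'
#' The canonical statistic vector: mean pairwise TMRCA within EUR, EAS and
#' AME and between all six group pairs. The within-ME statistic is excluded
#' by default (all candidate scenarios systematically underestimate the
#' Middle-Eastern deme TMRCA, and an outlying statistic would bias the ABC
#' likelihoods), but can be included via `within_me = TRUE`.
#'
#' @param within_me Include `within_ME` (making 10 statistics)?
#' @return Character vector of statistic names, fixed order.
#' @export
summary_stat_names <- function(within_me = FALSE) {
  nine <- c("within_EUR", "within_EAS", "within_AME",
            "EUR_ME", "EUR_EAS", "EUR_AME", "ME_EAS", "ME_AME", "EAS_AME")
  if (within_me) STAT_NAMES_FULL else nine
}

#' Read a dated tree and attach sample metadata
#'
#' Parses a Newick tree whose branch lengths are in ky, assigns tip ages and
#' demes from a metadata table, and computes internal node ages. Node ages
#' are cross-checked over every root-to-tip path: if two paths imply root
#' ages differing by more than `tol`, the tree and the tip dates are
#' inconsistent and an error is raised.
#'
#' @param tree A file path, a Newick string, or an [ape::phylo] object.
#' @param metadata data.frame with columns `id`, `deme`, `age_ky` covering
#'   every tip.
#' @param tol Tolerance (ky) for path-consistency of node ages.
#' @return A `genealogy` object (see [simulate_genealogy()]).
#' @examples
#' md <- data.frame(id = c("A", "B"), deme = "Beringia", age_ky = c(5, 0))
#' g <- read_dated_tree("(A:2,B:7);", md)
#' max(g$node_age)  # root age 7
#' @export
read_dated_tree <- function(tree, metadata, tol = 1e-6) {
  if (inherits(tree, "phylo")) {
    phy <- tree
  } else if (is.character(tree) && length(tree) == 1L) {
    phy <- if (grepl("\\(", tree)) ape::read.tree(text = tree)
           else ape::read.tree(tree)
  } else {
    stop("'tree' must be a phylo object, a Newick string or a file path")
  }
  if (is.null(phy)) stop("could not parse tree")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  n <- length(phy$tip.label)
  miss <- setdiff(phy$tip.label, metadata$id)
  if (length(miss)) {
    stop("tip missing from metadata: ", paste(miss, collapse = ", "))
  }
  md <- metadata[match(phy$tip.label, metadata$id), ]
  if (any(md$age_ky < 0)) stop("negative tip age")
  # depth = path length from root; for every tip, age + depth must equal the
  # same root age
  depth <- ape::node.depth.edgelength(phy)
  root_cand <- md$age_ky + depth[seq_len(n)]
  if (diff(range(root_cand)) > tol) {
    stop(sprintf(
      "inconsistent tip dates/branch lengths: implied root ages span %g ky (tol %g)",
      diff(range(root_cand)), tol))
  }
  root_age <- root_cand[1]
  node_age <- root_age - depth
  node_age[seq_len(n)] <- md$age_ky  # exact tip ages
  if (any(node_age < -tol)) stop("negative implied node age")
  parent_age <- node_age[phy$edge[, 1]]
  child_age <- node_age[phy$edge[, 2]]
  if (any(parent_age - child_age < -tol)) {
    stop("parent younger than child beyond tolerance")
  }
  structure(
    list(phylo = phy, node_age = node_age,
         tip_deme = setNames(as.character(md$deme), phy$tip.label),
         tip_age = setNames(as.numeric(md$age_ky), phy$tip.label),
         coal_deme = rep(NA_character_, n + phy$Nnode), seed = NULL),
    class = "genealogy"
  )
}

#' TMRCA summary statistics of a genealogy
#'
#' Computes the mean pairwise TMRCA within and between the four deme groups
#' defined by `graph$stat_groups`. Group combinations with no qualifying tip
#' pair are returned as `NA` (and flagged via the `"missing"` attribute);
#' [abc_distance()] refuses `NA` entries unless they are masked out.
#'
#' @param g A `genealogy`.
#' @param graph A [deme_graph()] supplying the deme-to-group mapping.
#' @param within_me Include the within-ME statistic (see
#'   [summary_stat_names()]).
#' @return Named numeric vector of mean TMRCAs (ky), with attributes
#'   `n_pairs` (pair counts per entry, over the full 10 combinations) and
#'   `missing` (names of undefined entries).
#' @export
tmrca_summary <- function(g, graph, within_me = FALSE) {
  stopifnot(inherits(g, "genealogy"))
  tips <- g$phylo$tip.label
  if (!length(tips)) stop("empty tree")
  grp <- graph$stat_groups[g$tip_deme[tips]]
  if (any(is.na(grp))) stop("tip without a deme group")
  tm <- tmrca_matrix(g)
  grp_levels <- c("EUR", "ME", "EAS", "AME")
  sums <- setNames(numeric(10), STAT_NAMES_FULL)
  cnts <- setNames(numeric(10), STAT_NAMES_FULL)
  comb_name <- function(a, b) {
    if (a == b) return(paste0("within_", a))
    key <- grp_levels[sort(match(c(a, b), grp_levels))]
    paste(key, collapse = "_")
  }
  nt <- length(tips)
  for (i in seq_len(nt - 1L)) {
    for (j in seq.int(i + 1L, nt)) {
      nm <- comb_name(grp[i], grp[j])
      sums[nm] <- sums[nm] + tm[i, j]
      cnts[nm] <- cnts[nm] + 1
    }
  }
  means <- ifelse(cnts > 0, sums / cnts, NA_real_)
  out <- means[summary_stat_names(within_me = within_me)]
  structure(out, n_pairs = cnts, missing = names(out)[is.na(out)])
}
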