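# Deme geography: the seven-deme graph, summary-statistic groupings,
# hop distances and colonization schedules shared by all expansion scenarios.

#' Names of the seven demes
#'
#' The wolf range is modelled as seven demes separated by major geographical
#' barriers: Europe, the Middle East, Central North Eurasia (the Siberian
#' plateau), East Eurasia, Beringia (Lena river to Mackenzie river),
#' Arctic North America and continental North America.
#'
#' @return Character vector of the seven deme identifiers, in canonical order.
#' @export
deme_names <- function() {
  c("Europe", "MiddleEast", "CentralNorthEurasia", "EastEurasia",
    "Beringia", "ArcticNorthAmerica", "NorthAmerica")
}

#' Summary-statistic group labels
#'
#' Demes are pooled into four groups for the TMRCA summary statistics:
#' EUR (Europe), ME (Middle East), EAS (Central North Eurasia, East Eurasia
#' and Beringia combined) and AME (Arctic and continental North America
#' combined).
#'
#' @return Named character vector mapping deme name to group label.
#' @export
default_stat_groups <- function() {
  c(Europe = "EUR", MiddleEast = "ME",
    CentralNorthEurasia = "EAS", EastEurasia = "EAS", Beringia = "EAS",
    ArcticNorthAmerica = "AME", NorthAmerica = "AME")
}

default_deme_edges <- function() {
  rbind(
    c("Europe", "MiddleEast"),
    c("Europe", "CentralNorthEurasia"),
    c("MiddleEast", "CentralNorthEurasia"),
    c("CentralNorthEurasia", "EastEurasia"),
    c("CentralNorthEurasia", "Beringia"),
    c("EastEurasia", "Beringia"),
    c("Beringia", "NorthAmerica"),
    c("Beringia", "ArcticNorthAmerica"),
    c("NorthAmerica", "ArcticNorthAmerica")
  )
}

#' Build the deme adjacency graph
#'
#' Constructs the network of demes connected by gene flow. The default edge
#' set links each deme to its geographical neighbours across passable
#' barriers; both the edges and the summary-statistic grouping can be
#' overridden (e.g. from a configuration file read with
#' [read_graph_config()]).
#'
#' @param demes Character vector of deme names (default: the seven demes).
#' @param edges Two-column character matrix (or data.frame) of unordered
#'   deme pairs. Default: the nine-edge neighbour network.
#' @param stat_groups Named character vector mapping each deme to one of
#'   `"EUR"`, `"ME"`, `"EAS"`, `"AME"`.
#' @return An object of class `deme_graph`: a list with elements `demes`,
#'   `edges` (character matrix), `stat_groups` and `adj` (named list of
#'   neighbour vectors).
#' @examples
#' g <- deme_graph()
#' g$demes
#' @export
deme_graph <- function(demes = deme_names(), edges = default_deme_edges(),
                       stat_groups = default_stat_groups()) {
  demes <- as.character(demes)
  if (anyDuplicated(demes)) stop("duplicated deme names")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  if (!all(edges %in% demes)) {
    stop("edge endpoint not among demes: ",
         paste(setdiff(unique(c(edges)), demes), collapse = ", "))
  }
  if (any(edges[, 1] == edges[, 2])) stop("self-loop edge")
  stat_groups <- stat_groups[demes]
  if (any(is.na(stat_groups))) stop("every deme needs a stat group")
  if (!all(stat_groups %in% c("EUR", "ME", "EAS", "AME"))) {
    stop("stat groups must be EUR, ME, EAS or AME")
  }
  adj <- lapply(demes, function(d) {
    nb <- c(edges[edges[, 1] == d, 2], edges[edges[, 2] == d, 1])
    sort(unique(nb))
  })
  names(adj) <- demes
  g <- structure(
    list(demes = demes, edges = edges, stat_groups = stat_groups, adj = adj),
    class = "deme_graph"
  )
  hops <- hop_distances(g, demes[1])
  if (any(!is.finite(hops))) {
    stop("deme graph is not connected: ",
         paste(demes[!is.finite(hops)], collapse = ", "),
         " unreachable from ", demes[1])
  }
  g
}

#' @export
print.deme_graph <- function(x, ...) {
  cat("Deme graph:", length(x$demes), "demes,", nrow(x$edges), "edges\n")
  for (d in x$demes) {
    cat(sprintf("  %-20s [%s] -- %s\n", d, x$stat_groups[[d]],
                paste(x$adj[[d]], collapse = ", ")))
  }
  invisible(x)
}

#' Graph hop distances from one deme
#'
#' Breadth-first hop distance from `origin` to every deme.
#'
#' @param graph A [deme_graph()].
#' @param origin Deme name.
#' @return Named numeric vector of hop counts (`Inf` for unreachable demes).
#' @export
hop_distances <- function(graph, origin) {
  if (!origin %in% graph$demes) stop("unknown deme: ", origin)
  dist <- setNames(rep(Inf, length(graph$demes)), graph$demes)
  dist[origin] <- 0
  frontier <- origin
  while (length(frontier)) {
    nxt <- character(0)
    for (d in frontier) {
      for (nb in graph$adj[[d]]) {
        if (!is.finite(dist[nb])) {
          dist[nb] <- dist[d] + 1
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

#' Colonization schedule of a range expansion
#'
#' Starting at time `T` (ky BP) the population of the origin deme expands and
#' replaces its neighbours; the expansion then proceeds in fixed steps of
#' `dT` per graph hop, so a deme at hop distance `d` from the origin is
#' colonized at `T - (d - 1) * dT`. With `neighbours_at = "T_minus_dT"` the
#' alternative convention is used where the first replacements happen one
#' step after the expansion starts, i.e. at `T - d * dT`. A deme's
#' colonization sources are its already-colonized neighbours (neighbours at
#' strictly smaller hop distance, or the origin itself).
#'
#' @param graph A [deme_graph()].
#' @param origin Deme of expansion origin.
#' @param T Expansion start time, ky BP.
#' @param dT Per-step interval, ky (> 0).
#' @param neighbours_at Timing convention for the origin's neighbours:
#'   colonized at `T` itself (default) or at `T - dT`.
#' @return Object of class `colonization_schedule`: data.frame with columns
#'   `deme`, `hop`, `time` and a list column `sources`; attributes `origin`,
#'   `T`, `dT`.
#' @examples
#' colonization_schedule(deme_graph(), "Beringia", T = 25, dT = 1)
#' @export
colonization_schedule <- function(graph, origin, T, dT,
                                  neighbours_at = c("T", "T_minus_dT")) {
  neighbours_at <- match.arg(neighbours_at)
  if (!is.numeric(dT) || length(dT) != 1L || dT <= 0) stop("dT must be > 0")
  if (!is.numeric(T) || length(T) != 1L || T <= 0) stop("T must be > 0")
  hops <- hop_distances(graph, origin)
  offset <- if (neighbours_at == "T") 1 else 0
  others <- graph$demes[graph$demes != origin]
  time <- T - (hops[others] - offset) * dT
  if (any(time <= 0)) {
    stop("expansion incomplete at present: colonization time <= 0 for ",
         paste(others[time <= 0], collapse = ", "))
  }
  sources <- lapply(others, function(d) {
    nb <- graph$adj[[d]]
    nb[hops[nb] < hops[d]]
  })
  out <- data.frame(deme = others, hop = as.integer(hops[others]),
                    time = as.numeric(time), row.names = NULL,
                    stringsAsFactors = FALSE)
  out$sources <- sources
  structure(out, origin = origin, T = T, dT = dT,
            neighbours_at = neighbours_at,
            class = c("colonization_schedule", "data.frame"))
}
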