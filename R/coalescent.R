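# Scenario specification and the structured-coalescent simulator for dated
# samples: R-level surface over the compiled event-loop engine.

SCENARIO_FAMILIES <- c("static", "bottleneck", "expansion",
                       "expansion_bottleneck")

#' Specify a demographic scenario
#'
#' One of the four scenario families: `static` (constant deme size K,
#' migration m between neighbouring demes), `bottleneck` (piecewise-constant
#' sizes K1/K2/K3 over the epochs 0-15, 15-40 and >40 ky BP), `expansion`
#' (static sizes plus a range expansion with founder effects and replacement
#' of local populations), and `expansion_bottleneck` (both).
#'
#' All sizes K are expressed as the mean within-deme pairwise coalescence
#' time in ky (so the coalescence rate per lineage pair is `1/K`);
#' `m` is the per-lineage migration rate in events per ky.
#'
#' @param family Scenario family.
#' @param m Per-lineage migration rate (1/ky), >= 0.
#' @param K Deme size for `static`/`expansion` families (ky).
#' @param K1,K2,K3 Epoch sizes for the bottleneck families: K1 on 0-15 ky,
#'   K2 on 15-40 ky, K3 beyond 40 ky BP.
#' @param origin Expansion origin deme (expansion families only).
#' @param T Expansion start time in ky BP.
#' @param dT Expansion step per graph hop, ky.
#' @param x Founder-effect severity: probability that a pair of lineages
#'   coalesces in the instantaneous bottleneck accompanying a colonization
#'   (0 = none, 1 = complete loss of diversity).
#' @param epoch_boundaries Epoch boundary times, ky BP (bottleneck families).
#' @return Object of class `scenario_spec`.
#' @examples
#' scenario("expansion_bottleneck", m = 0.1, K1 = 20, K2 = 5, K3 = 40,
#'          origin = "Beringia", T = 25, dT = 1, x = 0.8)
#' @export
scenario <- function(family = SCENARIO_FAMILIES, m, K = NULL,
                     K1 = NULL, K2 = NULL, K3 = NULL,
                     origin = NULL, T = NULL, dT = NULL, x = NULL,
                     epoch_boundaries = c(15, 40)) {
  family <- match.arg(family)
  if (!is.numeric(m) || length(m) != 1L || m < 0) stop("m must be >= 0")
  bottleneck <- family %in% c("bottleneck", "expansion_bottleneck")
  expansion <- family %in% c("expansion", "expansion_bottleneck")
  if (bottleneck) {
    if (is.null(K1) || is.null(K2) || is.null(K3)) {
      stop(family, " scenario needs K1, K2 and K3")
    }
    sizes <- c(K1, K2, K3)
    if (length(epoch_boundaries) != length(sizes) - 1L ||
        is.unsorted(epoch_boundaries, strictly = TRUE)) {
      stop("epoch boundaries must be strictly increasing, one fewer than sizes")
    }
  } else {
    if (is.null(K)) stop(family, " scenario needs K")
    sizes <- K
    epoch_boundaries <- numeric(0)
  }
  if (any(sizes <= 0)) stop("all K must be > 0")
  if (expansion) {
    if (is.null(origin) || is.null(T) || is.null(dT) || is.null(x)) {
      stop(family, " scenario needs origin, T, dT and x")
    }
    if (x < 0 || x > 1) stop("x must be in [0, 1]")
    if (dT <= 0) stop("dT must be > 0")
  } else if (!is.null(origin) || !is.null(T) || !is.null(x)) {
    stop("expansion parameters supplied for a non-expansion family")
  }
  structure(
    list(family = family, m = m, sizes = sizes,
         epoch_boundaries = epoch_boundaries,
         expansion = if (expansion) {
           list(origin = origin, T = T, dT = dT, x = x)
         } else NULL),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario:", x$family, "\n")
  cat("  m =", x$m, "/ky;  K =", paste(signif(x$sizes, 4), collapse = ", "),
      "ky\n")
  if (!is.null(x$expansion)) {
    cat(sprintf("  expansion out of %s: T = %g ky, dT = %g ky, x = %g\n",
                x$expansion$origin, x$expansion$T, x$expansion$dT,
                x$expansion$x))
  }
  invisible(x)
}

#' Validate a sample table against a deme graph
#'
#' @param samples data.frame with columns `id`, `deme`, `age_ky` (and
#'   optionally `lat`, `lon`).
#' @param graph A [deme_graph()].
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_samples <- function(samples, graph) {
  need <- c("id", "deme", "age_ky")
  if (!all(need %in% names(samples))) {
    stop("sample table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(samples$id)) {
    stop("duplicate sample id: ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  }
  bad <- setdiff(unique(samples$deme), graph$demes)
  if (length(bad)) stop("unknown deme: ", paste(bad, collapse = ", "))
  if (!is.numeric(samples$age_ky) || any(is.na(samples$age_ky)) ||
      any(samples$age_ky < 0)) {
    stop("ages must be non-negative numbers")
  }
  samples
}

# assemble the C++ engine arguments shared by single and batch simulation
sim_engine_args <- function(graph, samples) {
  demes <- graph$demes
  grp_levels <- c("EUR", "ME", "EAS", "AME")
  list(
    adj = lapply(graph$adj, function(nb) match(nb, demes)),
    sample_deme = match(samples$deme, demes),
    sample_age = as.numeric(samples$age_ky),
    sample_group = match(graph$stat_groups[samples$deme], grp_levels)
  )
}

#' Simulate a genealogy under a demographic scenario
#'
#' Runs the structured coalescent backwards in time: within-deme coalescence
#' at rate `C(k,2)/K(t)`, per-lineage migration at rate `m` with destination
#' uniform over adjacent demes, lineages entering at their sample ages, and
#' -- for expansion scenarios -- a founder bottleneck followed by forced
#' migration into a source deme at each colonization time. Identical inputs
#' and seed yield an identical genealogy.
#'
#' @param graph A [deme_graph()].
#' @param scenario A [scenario()].
#' @param samples Sample table (see [validate_samples()]).
#' @param seed Integer seed for the simulation's own RNG stream.
#' @param time_cap Guard against non-coalescing configurations (e.g. `m = 0`
#'   with samples in several demes and no expansion): if the simulation
#'   reaches this age (ky BP) with lineages left, it aborts with an error.
#' @param neighbours_at Colonization timing convention, see
#'   [colonization_schedule()].
#' @return Object of class `genealogy`: list with elements `phylo` (an
#'   [ape::phylo] tree with branch lengths in ky), `node_age` (ages, ky BP,
#'   indexed by phylo node number), `tip_deme`, `tip_age`, `coal_deme`
#'   (deme of each coalescence, indexed by node number) and `seed`.
#' @export
simulate_genealogy <- function(graph, scenario, samples, seed,
                               time_cap = 1e4,
                               neighbours_at = c("T", "T_minus_dT")) {
  neighbours_at <- match.arg(neighbours_at)
  stopifnot(inherits(scenario, "scenario_spec"))
  samples <- validate_samples(samples, graph)
  ea <- sim_engine_args(graph, samples)
  n_demes <- length(graph$demes)
  col_time <- rep(-1, n_demes)
  col_sources <- vector("list", n_demes)
  x <- 0
  if (!is.null(scenario$expansion)) {
    sched <- colonization_schedule(graph, scenario$expansion$origin,
                                   scenario$expansion$T, scenario$expansion$dT,
                                   neighbours_at = neighbours_at)
    i <- match(sched$deme, graph$demes)
    col_time[i] <- sched$time
    col_sources[i] <- lapply(sched$sources, function(s) match(s, graph$demes))
    x <- scenario$expansion$x
  }
  res <- .sim_core_cpp(ea$adj, ea$sample_deme, ea$sample_age, ea$sample_group,
                       scenario$epoch_boundaries, scenario$sizes, scenario$m,
                       col_time, col_sources, x, time_cap, as.numeric(seed))
  if (isTRUE(res$capped)) {
    stop("non-coalescing configuration: time cap of ", time_cap,
         " ky reached with lineages remaining (m = ", scenario$m, ")")
  }
  g <- genealogy_from_merges(res$merges, samples, graph$demes)
  g$seed <- seed
  g
}

# Build a `genealogy` object (ape phylo + node ages) from the engine's merge
# records. Internal nodes are renumbered to ape's convention (root = n + 1,
# then preorder).
genealogy_from_merges <- function(merges, samples, deme_names_vec = NULL) {
  n <- nrow(samples)
  if (n == 1L) stop("need at least two samples")
  stopifnot(nrow(merges) == n - 1L)
  # engine ids: 0..n-1 tips (sample order), n..2n-2 internal in merge order
  parent_of <- integer(2L * n - 1L)
  age <- numeric(2L * n - 1L)
  age[seq_len(n)] <- samples$age_ky
  kids <- matrix(0L, nrow = 2L * n - 1L, ncol = 2L)
  for (r in seq_len(n - 1L)) {
    p <- as.integer(merges[r, "parent"]) + 1L
    c1 <- as.integer(merges[r, "child1"]) + 1L
    c2 <- as.integer(merges[r, "child2"]) + 1L
    kids[p, ] <- c(c1, c2)
    parent_of[c(c1, c2)] <- p
    age[p] <- merges[r, "time"]
  }
  root_old <- 2L * n - 1L  # last-created node
  # preorder renumbering of internal nodes
  new_id <- integer(2L * n - 1L)
  new_id[seq_len(n)] <- seq_len(n)
  stack <- root_old
  next_internal <- n + 1L
  order_old <- integer(n - 1L)
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order_old[k] <- v
    new_id[v] <- n + k
    ch <- kids[v, ]
    stack <- c(stack, ch[ch > n])
  }
  edge <- matrix(0L, nrow = 2L * (n - 1L), ncol = 2L)
  edge_len <- numeric(2L * (n - 1L))
  r <- 0L
  for (v in order_old) {
    for (ch in kids[v, ]) {
      r <- r + 1L
      edge[r, ] <- c(new_id[v], new_id[ch])
      edge_len[r] <- age[v] - age[ch]
    }
  }
  node_age <- numeric(2L * n - 1L)
  node_age[new_id] <- age
  coal_deme <- rep(NA_character_, 2L * n - 1L)
  if (!is.null(deme_names_vec)) {
    coal_deme[new_id[as.integer(merges[, "parent"]) + 1L]] <-
      deme_names_vec[as.integer(merges[, "deme"]) + 1L]
  }
  phy <- structure(
    list(edge = edge, edge.length = edge_len,
         tip.label = as.character(samples$id), Nnode = n - 1L),
    class = "phylo", order = "cladewise"
  )
  structure(
    list(phylo = phy, node_age = node_age,
         tip_deme = setNames(as.character(samples$deme),
                             as.character(samples$id)),
         tip_age = setNames(as.numeric(samples$age_ky),
                            as.character(samples$id)),
         coal_deme = coal_deme, seed = NULL),
    class = "genealogy"
  )
}

#' @export
print.genealogy <- function(x, ...) {
  n <- length(x$phylo$tip.label)
  cat("Dated genealogy:", n, "tips, root age",
      signif(max(x$node_age), 4), "ky BP\n")
  cat("  tip ages:", signif(min(x$tip_age), 3), "-",
      signif(max(x$tip_age), 4), "ky BP\n")
  invisible(x)
}

#' Founder bottleneck among a set of lineages
#'
#' Applies the instantaneous founder-effect bottleneck used at colonization
#' events: a burst of Kingman coalescence of intensity `tau = -log(1 - x)`,
#' under which each pair of lineages coalesces with probability exactly `x`
#' (`x = 1`: all lineages merge into one; `x = 0`: no change). All merges are
#' dated at the colonization `time`.
#'
#' @param lineages Character (or integer) vector of lineage identifiers.
#' @param x Pair coalescence probability in \[0, 1\].
#' @param time Colonization time (ky BP) stamped on the coalescence records.
#' @param seed Integer seed.
#' @return List with `survivors` (identifiers; merge products are labelled
#'   `"coal_<i>"`) and `coalescences` (data.frame with columns `a`, `b`,
#'   `node`, `age`).
#' @export
founder_bottleneck <- function(lineages, x, time, seed) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("x must be in [0, 1]")
  }
  k <- length(lineages)
  ids <- c(as.character(lineages), paste0("coal_", seq_len(max(k - 1L, 0L))))
  rec <- .bottleneck_burst_cpp(k, x, as.numeric(seed))
  merged <- c(rec[, "a"], rec[, "b"])
  surv <- setdiff(seq_len(k + nrow(rec)), merged)
  coal <- data.frame(
    a = ids[rec[, "a"]], b = ids[rec[, "b"]], node = ids[rec[, "new"]],
    age = rep(as.numeric(time), nrow(rec)), stringsAsFactors = FALSE
  )
  list(survivors = ids[surv], coalescences = coal)
}

#' Pairwise TMRCA matrix of a genealogy
#'
#' @param g A `genealogy` (from [simulate_genealogy()] or
#'   [read_dated_tree()]).
#' @return Symmetric matrix (ky) over tip labels with zero diagonal;
#'   `TMRCA[i, j]` is the age of the most recent common ancestor of tips
#'   `i` and `j`.
#' @export
tmrca_matrix <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  mr <- ape::mrca(g$phylo)
  tm <- matrix(g$node_age[mr], nrow = nrow(mr),
               dimnames = dimnames(mr))
  diag(tm) <- 0
  tm
}
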