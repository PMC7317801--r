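# Synthetic-data generator: sampling designs emulating the study data set
# (90 modern + 45 ancient mitogenomes spread over seven demes and 0-50 ky),
# pseudo-observed genealogies with known ground truth, and finite-sites
# mitogenome-like alignments.

#' Reference coordinates of the seven demes
#'
#' A representative point per deme, used as the centre around which
#' synthetic sample coordinates are jittered.
#'
#' @return data.frame with columns `deme`, `lat`, `lon`.
#' @export
deme_ref_coords <- function() {
  data.frame(
    deme = deme_names(),
    lat = c(50, 33, 62, 45, 65, 70, 45),
    lon = c(10, 44, 90, 120, -170, -100, -100),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic sampling design
#'
#' Emulates the study's sampling: `n_modern` present-day samples (age 0) and
#' `n_ancient` ancient samples with ages uniform over `age_range` ky BP,
#' assigned to demes by `weights` and given coordinates jittered around each
#' deme's reference point.
#'
#' @param graph A [deme_graph()].
#' @param n_modern,n_ancient Sample counts (defaults 90 and 45, the size of
#'   the study data set).
#' @param seed Integer seed.
#' @param modern_weights,ancient_weights Named per-deme sampling weights.
#'   The defaults emulate the study's sampling: modern wolves spread across
#'   the whole range with the bulk in Eurasia, ancient specimens dominated
#'   by the permafrost- and cave-rich regions (Beringia, Europe, Central
#'   North Eurasia) and sparse in the Middle East and the Americas.
#' @param age_range Ancient age range, ky BP.
#' @param coord_jitter SD (degrees) of the coordinate jitter.
#' @return data.frame with columns `id`, `deme`, `age_ky`, `lat`, `lon`.
#' @examples
#' d <- make_design(deme_graph(), seed = 1)
#' nrow(d)            # 135
#' sum(d$age_ky > 0)  # 45
#' @export
make_design <- function(graph = deme_graph(), n_modern = 90, n_ancient = 45,
                        seed = 1, modern_weights = NULL,
                        ancient_weights = NULL, age_range = c(1, 50),
                        coord_jitter = 3) {
  if (is.null(modern_weights)) {
    modern_weights <- c(Europe = 2, MiddleEast = 1, CentralNorthEurasia = 2,
                        EastEurasia = 2, Beringia = 1,
                        ArcticNorthAmerica = 1, NorthAmerica = 1.5)
  }
  if (is.null(ancient_weights)) {
    ancient_weights <- c(Europe = 3, MiddleEast = 0.5,
                         CentralNorthEurasia = 1.5, EastEurasia = 1,
                         Beringia = 3.5, ArcticNorthAmerica = 0.25,
                         NorthAmerica = 0.25)
  }
  chk_w <- function(w, nm) {
    w <- w[graph$demes]
    if (any(is.na(w)) || sum(w) <= 0) {
      stop(nm, " must cover all demes and sum to > 0")
    }
    w
  }
  modern_weights <- chk_w(modern_weights, "modern_weights")
  ancient_weights <- chk_w(ancient_weights, "ancient_weights")
  refs <- deme_ref_coords()
  refs <- refs[match(graph$demes, refs$deme), ]
  with_seed(seed, {
    n <- n_modern + n_ancient
    deme <- c(
      sample(graph$demes, n_modern, replace = TRUE, prob = modern_weights),
      sample(graph$demes, n_ancient, replace = TRUE, prob = ancient_weights)
    )
    age <- c(rep(0, n_modern), runif(n_ancient, age_range[1], age_range[2]))
    i <- match(deme, graph$demes)
    lat <- pmax(-89, pmin(89, refs$lat[i] + rnorm(n, 0, coord_jitter)))
    lon <- refs$lon[i] + rnorm(n, 0, coord_jitter)
    lon <- ((lon + 180) %% 360) - 180
    data.frame(
      id = sprintf("s%03d", seq_len(n)),
      deme = deme, age_ky = age, lat = lat, lon = lon,
      stringsAsFactors = FALSE
    )
  })
}

#' The default data-generating scenario
#'
#' The regime inferred for Northern Hemisphere wolves: a range expansion out
#' of Beringia starting 25 ky BP (one deme replaced per ky), strong founder
#' effects, limited gene flow between neighbouring demes, and a population
#' bottleneck during the 15-40 ky BP epoch.
#'
#' @return A [scenario()] of family `expansion_bottleneck`.
#' @export
default_truth_scenario <- function() {
  scenario("expansion_bottleneck", m = 0.05, K1 = 20, K2 = 5, K3 = 15,
           origin = "Beringia", T = 25, dT = 1, x = 0.9)
}

#' Generate pseudo-observed data with known ground truth
#'
#' Simulates one genealogy for the design under the given scenario and
#' packages it with a machine-readable truth record (scenario family,
#' parameters, seed) for parameter-recovery experiments.
#'
#' @param design Sample table from [make_design()].
#' @param scenario Generating [scenario()] (default
#'   [default_truth_scenario()]).
#' @param seed Integer seed.
#' @param graph A [deme_graph()].
#' @return List with `genealogy` and `truth` (a list serializable to JSON
#'   via [write_truth()]).
#' @export
make_pseudo_observed <- function(design, scenario = default_truth_scenario(),
                                 seed = 1, graph = deme_graph()) {
  g <- simulate_genealogy(graph, scenario, design, seed = seed)
  truth <- list(
    family = scenario$family, m = scenario$m,
    sizes = scenario$sizes,
    epoch_boundaries = scenario$epoch_boundaries,
    expansion = scenario$expansion, seed = seed,
    n_samples = nrow(design)
  )
  list(genealogy = g, truth = truth)
}

#' Drop finite-sites mutations on a genealogy
#'
#' Jukes-Cantor mutation over an alignment of length `L`: a random root
#' sequence, `Poisson(mu * L * branch length)` mutations per branch placed
#' uniformly over sites, each substituting a uniformly chosen different
#' base. With `mu * L * (total tree length) << L` the model behaves
#' quasi-infinite-sites; the expected variable-site fraction is
#' approximately `1 - exp(-mu * total tree length)`.
#'
#' @param g A `genealogy`.
#' @param mu Mutation rate per site per ky. The default is a calibration
#'   constant chosen so the default design and scenario yield roughly the
#'   8.4% variable sites observed in real wolf mitogenome alignments; it is
#'   a placeholder, not an estimate of the wolf mitochondrial rate (though
#'   it falls in the plausible range for canid mtDNA).
#' @param L Alignment length in bp (default 15,466: a control-region-free
#'   wolf mitogenome).
#' @param seed Integer seed.
#' @return A `DNAbin` matrix with one row per tip.
#' @export
mutate_alignment <- function(g, mu = 5e-5, L = 15466, seed = 1) {
  stopifnot(inherits(g, "genealogy"))
  phy <- g$phylo
  n <- length(phy$tip.label)
  bases <- c("a", "c", "g", "t")
  with_seed(seed, {
    seqs <- vector("list", n + phy$Nnode)
    root <- n + 1L
    seqs[[root]] <- sample.int(4L, L, replace = TRUE)
    # phylo edges are in cladewise (preorder) order: parents precede children
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      s <- seqs[[par]]
      nmut <- rpois(1, mu * L * max(phy$edge.length[e], 0))
      if (nmut > 0) {
        sites <- sample.int(L, nmut, replace = TRUE)
        for (k in seq_len(nmut)) {
          s[sites[k]] <- sample((1:4)[-s[sites[k]]], 1)
        }
      }
      seqs[[ch]] <- s
    }
    m <- do.call(rbind, lapply(seq_len(n), function(i) bases[seqs[[i]]]))
    rownames(m) <- phy$tip.label
    ape::as.DNAbin(m)
  })
}

#' Count variable sites in an alignment
#'
#' @param aln A `DNAbin` matrix.
#' @return Number of columns with more than one distinct non-missing base.
#' @export
count_variable_sites <- function(aln) {
  m <- as.character(as.matrix(aln))
  sum(apply(m, 2, function(col) {
    col <- tolower(col)
    col <- col[col %in% c("a", "c", "g", "t")]
    length(unique(col)) > 1
  }))
}
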