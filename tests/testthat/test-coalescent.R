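# Unit and property tests of the structured-coalescent engine. The heavier
# Monte-Carlo versions of the closed-form checks (10,000 replicates) live in
# test-acceptance.R; here moderate replicate counts keep the suite quick.

test_that("single-deme pair TMRCA follows the serial Kingman coalescent", {
  g <- deme_graph()
  # modern pair, K = 1: TMRCA ~ Exp(mean 1)
  tm <- mean_pair_tmrca(g, "static", data.frame(m = 0, K = 1),
                        pair_samples(c("Europe", "Europe")), 4000, 11)
  expect_lt(abs(mean(tm) - 1), 3 * sd(tm) / sqrt(length(tm)))
  expect_lt(abs(var(tm) - 1), 0.15)
  # heterochronous pair (0, 5), K = 2: clock starts when both are active
  tm2 <- mean_pair_tmrca(g, "static", data.frame(m = 0, K = 2),
                         pair_samples(c("Europe", "Europe"), c(0, 5)),
                         4000, 12)
  expect_gte(min(tm2), 5)
  expect_lt(abs(mean(tm2) - 7), 3 * sd(tm2) / sqrt(length(tm2)))
})

test_that("two-deme closed forms hold: E[same] = 2K, E[diff] = 2K + 1/(2m)", {
  g2 <- toy_graph2()
  for (km in list(c(1, 0.5), c(2, 5))) {
    K <- km[1]; m <- km[2]
    tS <- mean_pair_tmrca(g2, "static", data.frame(m = m, K = K),
                          pair_samples(c("A", "A")), 4000, 21)
    tD <- mean_pair_tmrca(g2, "static", data.frame(m = m, K = K),
                          pair_samples(c("A", "B")), 4000, 22)
    expect_lt(abs(mean(tS) - 2 * K), 3 * sd(tS) / sqrt(length(tS)))
    expect_lt(abs(mean(tD) - (2 * K + 1 / (2 * m))),
              3 * sd(tD) / sqrt(length(tD)))
  }
})

test_that("static means match the exact first-step-analysis oracle on a line graph", {
  g3 <- toy_graph3_line()
  for (km in list(c(1, 1), c(3, 0.3))) {
    K <- km[1]; m <- km[2]
    E <- expected_pair_tmrca(g3, K, m)
    for (cfg in list(c("A", "A"), c("A", "B"), c("A", "C"))) {
      tm <- mean_pair_tmrca(g3, "static", data.frame(m = m, K = K),
                            pair_samples(cfg), 3000,
                            seed_base = 7e5 + K * 100 + sum(cfg == "A"))
      expect_lt(abs(mean(tm) - E[cfg[1], cfg[2]]),
                3 * sd(tm) / sqrt(length(tm)))
    }
  }
})

test_that("founder bottleneck implements pair-coalescence probability x", {
  for (x in c(0, 0.25, 0.5)) {
    hits <- 0
    for (i in 1:4000) {
      b <- founder_bottleneck(c("u", "v"), x = x, time = 10, seed = i)
      hits <- hits + nrow(b$coalescences)
    }
    phat <- hits / 4000
    se <- sqrt(max(x * (1 - x), 1e-9) / 4000)
    expect_lte(abs(phat - x), max(3 * se, 1e-12))
  }
  # x = 1: all k lineages collapse to one, nodes dated at the event
  b <- founder_bottleneck(letters[1:5], x = 1, time = 23.5, seed = 99)
  expect_length(b$survivors, 1)
  expect_equal(nrow(b$coalescences), 4)
  expect_true(all(b$coalescences$age == 23.5))
  expect_error(founder_bottleneck(c("u", "v"), x = 1.2, time = 1, seed = 1),
               "x must be")
})

test_that("complete founder loss pins the pair TMRCA at the colonization time", {
  g <- deme_graph()
  sc <- scenario("expansion", m = 0, K = 1e6, origin = "Beringia",
                 T = 25, dT = 1, x = 1)
  s <- pair_samples(c("Europe", "Europe"))
  for (seed in 1:20) {
    gg <- simulate_genealogy(g, sc, s, seed = seed)
    expect_equal(max(gg$node_age), 24)  # Europe is 2 hops from Beringia
  }
})

test_that("equal epoch sizes reproduce the static distribution", {
  g <- deme_graph()
  s <- pair_samples(c("Europe", "Europe"))
  t_static <- mean_pair_tmrca(g, "static", data.frame(m = 0, K = 3), s,
                              4000, 31)
  t_bn <- mean_pair_tmrca(g, "bottleneck",
                          data.frame(m = 0, K1 = 3, K2 = 3, K3 = 3), s,
                          4000, 32)
  se <- sqrt(var(t_static) / 4000 + var(t_bn) / 4000)
  expect_lt(abs(mean(t_static) - mean(t_bn)), 3 * se)
  expect_lt(abs(sd(t_static) - sd(t_bn)), 0.35)
})

test_that("piecewise K changes the coalescence rate at epoch boundaries", {
  g <- deme_graph()
  s <- pair_samples(c("Europe", "Europe"))
  # huge K until 15 ky then tiny: TMRCA ~ 15 + Exp(0.01)
  tm <- mean_pair_tmrca(g, "bottleneck",
                        data.frame(m = 0, K1 = 1e8, K2 = 0.01, K3 = 0.01),
                        s, 2000, 33)
  expect_true(all(tm >= 15))
  expect_lt(mean(tm) - 15, 0.01 + 3 * 0.01 / sqrt(2000))
})

test_that("replaced demes host no post-colonization coalescences older than the event", {
  g <- deme_graph()
  sc <- scenario("expansion", m = 0, K = 2, origin = "Beringia",
                 T = 25, dT = 1, x = 0.3)
  # all samples predate their deme's colonization (post-colonization
  # lineages); Beringia, the continuous origin, also carries older tips
  d <- data.frame(
    id = sprintf("s%02d", 1:12),
    deme = rep(c("Europe", "EastEurasia", "Beringia"), each = 4),
    age_ky = c(0, 0, 10, 20, 0, 0, 10, 20, 0, 10, 20, 40),
    stringsAsFactors = FALSE
  )
  sch <- colonization_schedule(g, "Beringia", T = 25, dT = 1)
  col_t <- setNames(sch$time, sch$deme)
  for (seed in 1:25) {
    gg <- simulate_genealogy(g, sc, d, seed = seed)
    phy <- gg$phylo
    n <- length(phy$tip.label)
    for (v in (n + 1):(n + phy$Nnode)) {
      dm <- gg$coal_deme[v]
      if (is.na(dm) || !dm %in% names(col_t)) next
      # with m = 0 no lineage can leave a replaced deme before its
      # colonization, so every coalescence recorded there is no older
      expect_lte(gg$node_age[v], col_t[dm] + 1e-9)
    }
  }
})

test_that("simulation is deterministic in the seed", {
  g <- deme_graph()
  d <- make_design(g, n_modern = 20, n_ancient = 10, seed = 3)
  sc <- default_truth_scenario()
  g1 <- simulate_genealogy(g, sc, d, seed = 77)
  g2 <- simulate_genealogy(g, sc, d, seed = 77)
  g3 <- simulate_genealogy(g, sc, d, seed = 78)
  expect_identical(ape::write.tree(g1$phylo), ape::write.tree(g2$phylo))
  expect_identical(g1$node_age, g2$node_age)
  expect_false(identical(ape::write.tree(g1$phylo), ape::write.tree(g3$phylo)))
})

test_that("non-coalescing configurations error out at the time cap", {
  g <- deme_graph()
  expect_error(
    simulate_genealogy(g, scenario("static", m = 0, K = 1),
                       pair_samples(c("Europe", "Beringia")), seed = 1),
    "non-coalescing"
  )
  expect_error(
    simulate_genealogy(g, scenario("static", m = 1, K = 1),
                       pair_samples(c("Europe", "Atlantis")), seed = 1),
    "unknown deme"
  )
})

test_that("pairwise TMRCA matrix reads node ages off the tree", {
  md2 <- data.frame(id = c("A", "B"), deme = "Europe", age_ky = 0)
  g2 <- read_dated_tree("(A:7,B:7);", md2)
  expect_equal(unname(tmrca_matrix(g2)), rbind(c(0, 7), c(7, 0)))

  md3 <- data.frame(id = c("A", "B", "C"), deme = "Europe", age_ky = 0)
  g3 <- read_dated_tree("((A:3,B:3):6,C:9);", md3)
  tm <- tmrca_matrix(g3)
  expect_equal(tm["A", "B"], 3)
  expect_equal(tm["A", "C"], 9)
  expect_equal(tm["B", "C"], 9)
  # ultrametric modern tree: max TMRCA equals the root age
  expect_equal(max(tm), max(g3$node_age))
})

test_that("genealogies satisfy structural invariants", {
  g <- deme_graph()
  d <- make_design(g, n_modern = 15, n_ancient = 10, seed = 5)
  gg <- simulate_genealogy(g, default_truth_scenario(), d, seed = 9)
  phy <- gg$phylo
  expect_s3_class(phy, "phylo")
  expect_equal(length(phy$tip.label), 25)
  expect_equal(phy$Nnode, 24)
  # parent age strictly older than child (bottleneck nodes may tie)
  expect_true(all(gg$node_age[phy$edge[, 1]] - gg$node_age[phy$edge[, 2]]
                  >= -1e-9))
  # tip ages preserved
  expect_equal(unname(gg$node_age[seq_len(25)]),
               unname(d$age_ky[match(phy$tip.label, d$id)]))
  # TMRCA of a pair is at least the older tip
  tm <- tmrca_matrix(gg)
  ages <- gg$tip_age[rownames(tm)]
  expect_true(all(tm >= outer(ages, ages, pmax) - 1e-9 |
                    row(tm) == col(tm)))
})
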