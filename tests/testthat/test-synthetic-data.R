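test_that("the default design reproduces the study's sample counts", {
  d <- make_design(seed = 1)
  expect_equal(nrow(d), 135)
  expect_equal(sum(d$age_ky > 0), 45)
  expect_equal(sum(d$age_ky == 0), 90)
  expect_true(all(d$age_ky >= 0 & d$age_ky <= 50))
  expect_true(all(d$deme %in% deme_names()))
  expect_false(anyDuplicated(d$id) > 0)
  expect_true(all(abs(d$lat) <= 90))
  expect_true(all(d$lon >= -180 & d$lon < 180))
  expect_identical(make_design(seed = 4), make_design(seed = 4))
  d0 <- make_design(n_ancient = 0, seed = 2)
  expect_true(all(d0$age_ky == 0))
})

test_that("pseudo-observed data carry a faithful truth record", {
  d <- make_design(deme_graph(), n_modern = 12, n_ancient = 6, seed = 3)
  po <- make_pseudo_observed(d, seed = 5)
  expect_s3_class(po$genealogy, "genealogy")
  expect_equal(po$truth$expansion$origin, "Beringia")
  expect_equal(po$truth$n_samples, 18)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(po$truth, path)
  tr <- read_truth(path)
  expect_equal(tr$family, po$truth$family)
  expect_equal(tr$expansion$T, po$truth$expansion$T)
  expect_equal(tr$sizes, po$truth$sizes)
  expect_equal(tr$seed, 5)
})

test_that("single-deme pseudo-observed root ages match the serial Kingman law", {
  g1 <- deme_graph(demes = "Beringia", edges = matrix(character(0), 0, 2),
                   stat_groups = c(Beringia = "EAS"))
  d <- data.frame(id = c("a", "b"), deme = "Beringia", age_ky = 0)
  sc <- scenario("static", m = 0, K = 2)
  roots <- vapply(1:1500, function(i)
    max(simulate_genealogy(g1, sc, d, seed = i)$node_age), numeric(1))
  expect_lt(abs(mean(roots) - 2), 3 * sd(roots) / sqrt(1500))
})

test_that("mutation layer follows the Poisson-thinning expectation", {
  graph <- deme_graph()
  d <- make_design(graph, n_modern = 12, n_ancient = 6, seed = 9)
  gg <- simulate_genealogy(graph, default_truth_scenario(), d, seed = 21)
  treelen <- sum(gg$phylo$edge.length)
  # mu = 0: no variable sites
  a0 <- mutate_alignment(gg, mu = 0, L = 400, seed = 1)
  expect_equal(count_variable_sites(a0), 0)
  expect_equal(dim(as.matrix(a0)), c(18, 400))
  # variable-site count within 3 SE of L * (1 - exp(-mu * treelen))
  mu <- 0.0001; L <- 8000
  a1 <- mutate_alignment(gg, mu = mu, L = L, seed = 2)
  pexp <- 1 - exp(-mu * treelen)
  v <- count_variable_sites(a1)
  expect_lt(abs(v - L * pexp), 3 * sqrt(L * pexp * (1 - pexp)) + 3)
  # determinism
  expect_identical(as.character(mutate_alignment(gg, mu = mu, L = 500,
                                                 seed = 3)),
                   as.character(mutate_alignment(gg, mu = mu, L = 500,
                                                 seed = 3)))
})

test_that("pairwise raw distance approximates 2*mu*TMRCA for a sample pair", {
  md <- data.frame(id = c("A", "B"), deme = "Beringia", age_ky = 0)
  g <- read_dated_tree("(A:10,B:10);", md)
  mu <- 2e-4; L <- 15466
  dd <- vapply(1:40, function(i) {
    aln <- mutate_alignment(g, mu = mu, L = L, seed = i)
    genetic_distance_matrix(aln)["A", "B"]
  }, numeric(1))
  expected <- 2 * mu * 10  # small-distance limit
  expect_lt(abs(mean(dd) - expected), 3 * sd(dd) / sqrt(40) + 0.1 * expected)
})

test_that("deeper population structure raises the AMOVA among-deme share", {
  graph <- deme_graph()
  d <- make_design(graph, n_modern = 36, n_ancient = 0, seed = 11)
  pct <- vapply(c(5, 0.3, 0.02), function(m) {
    sc <- scenario("static", m = m, K = 5)
    mean(vapply(1:4, function(r) {
      gg <- simulate_genealogy(graph, sc, d, seed = 100 * r + round(100 * m))
      aln <- mutate_alignment(gg, seed = r)
      gd <- genetic_distance_matrix(aln)
      amova_dist(gd, d$deme[match(rownames(gd), d$id)], n_perm = 19,
                 seed = r)$pct_among
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(pct) > 0))  # among-% grows as migration shrinks
})

test_that("stepping-stone structure produces positive isolation by distance", {
  graph <- deme_graph()
  d <- make_design(graph, n_modern = 40, n_ancient = 0, seed = 12)
  sc <- scenario("static", m = 0.1, K = 5)
  gg <- simulate_genealogy(graph, sc, d, seed = 31)
  aln <- mutate_alignment(gg, seed = 31)
  gd <- genetic_distance_matrix(aln)
  ids <- rownames(gd)
  geo <- geo_distance_matrix(d[match(ids, d$id), ])
  r <- mantel_ibd(geo, gd, n_perm = 199, seed = 1)
  expect_gt(r$rho, 0)
})
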