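test_that("Haversine distance matches known great-circle values", {
  expect_equal(haversine_km(12, 34, 12, 34), 0)
  expect_equal(haversine_km(0, 0, 0, 90), pi * 6371 / 2, tolerance = 1e-10)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-10)
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, -181, 0, 0), "longitude")
})

test_that("Haversine agrees with an independent geodesic implementation", {
  skip_if_not_installed("geosphere")
  set.seed(7)
  lat <- runif(20, -80, 80); lon <- runif(20, -180, 179)
  ours <- haversine_km(lat[1:10], lon[1:10], lat[11:20], lon[11:20])
  ref <- geosphere::distHaversine(cbind(lon[1:10], lat[1:10]),
                                  cbind(lon[11:20], lat[11:20]),
                                  r = 6371000) / 1000
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("genetic distances use pairwise deletion of missing sites", {
  aln <- ape::as.DNAbin(rbind(
    s1 = c("a", "c", "g", "t"),
    s2 = c("a", "c", "g", "t"),
    s3 = c("a", "c", "g", "a"),
    s4 = c("a", "c", "g", "n")
  ))
  d <- genetic_distance_matrix(aln)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 0.25)
  expect_equal(d["s4", "s3"], 0)   # N excluded: 0 differences over 3 sites
  expect_equal(d["s4", "s1"], 0)
  aln2 <- ape::as.DNAbin(rbind(a = c("n", "n"), b = c("a", "c")))
  expect_error(genetic_distance_matrix(aln2), "no comparable")
})

test_that("Mantel test recovers perfect and null correlation", {
  set.seed(31)
  n <- 12
  pts <- data.frame(id = letters[1:n], lat = runif(n, 0, 60),
                    lon = runif(n, 0, 90))
  geo <- geo_distance_matrix(pts)
  gen <- 0.001 + 1e-5 * geo  # exact affine image
  r <- mantel_ibd(geo, gen, n_perm = 999, seed = 5)
  expect_equal(r$rho, 1, tolerance = 1e-12)
  expect_lte(r$p, 1 / (999 + 1) + 1e-9)
  # joint relabeling leaves rho unchanged
  p <- sample(n)
  r2 <- mantel_ibd(geo[p, p], gen[p, p], n_perm = 99, seed = 5)
  expect_equal(r2$rho, r$rho, tolerance = 1e-12)
  # independent matrices: rho near 0
  gen0 <- matrix(0, n, n)
  gen0[lower.tri(gen0)] <- runif(n * (n - 1) / 2)
  gen0 <- gen0 + t(gen0)
  r0 <- mantel_ibd(geo, gen0, n_perm = 999, seed = 6)
  expect_lt(abs(r0$rho), 3 / sqrt(choose(n, 2)))
  expect_error(mantel_ibd(geo, matrix(1, n, n)), "constant")
})

test_that("Mantel matches the exhaustive brute-force oracle on a 4-sample toy", {
  set.seed(13)
  g1 <- matrix(0, 4, 4); g1[lower.tri(g1)] <- c(1, 4, 2, 6, 3, 5)
  g1 <- g1 + t(g1)
  g2 <- matrix(0, 4, 4); g2[lower.tri(g2)] <- c(2, 3, 1, 5, 6, 4)
  g2 <- g2 + t(g2)
  ours <- mantel_ibd(g1, g2, permutations = "exhaustive")
  oracle <- brute_mantel(g1, g2)
  expect_equal(ours$rho, oracle$rho, tolerance = 1e-12)
  expect_equal(ours$p, oracle$p, tolerance = 1e-12)
  expect_equal(ours$n_perm, 24)
})

test_that("Mantel statistic agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(41)
  n <- 10
  a <- as.matrix(dist(matrix(runif(n * 2), ncol = 2)))
  b <- as.matrix(dist(matrix(runif(n * 2), ncol = 2)))
  ours <- mantel_ibd(a, b, n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 99)
  expect_equal(ours$rho, unname(ref$statistic), tolerance = 1e-12)
})

test_that("AMOVA attributes all variance among groups for two separated clusters", {
  d <- matrix(3, 6, 6)
  d[1:3, 1:3] <- 0
  d[4:6, 4:6] <- 0
  diag(d) <- 0
  a <- amova_dist(d, rep(c("g1", "g2"), each = 3), n_perm = 99, seed = 1)
  expect_equal(a$pct_among, 100, tolerance = 1e-9)
  expect_equal(a$sigma2_within, 0, tolerance = 1e-12)
  expect_error(amova_dist(d, rep("g1", 6)), "two groups")
})

test_that("AMOVA matches the brute-force oracle on a 6-sample toy", {
  set.seed(17)
  x <- c(rnorm(3, 0), rnorm(2, 2), rnorm(1, 5))
  d <- as.matrix(dist(x))
  groups <- c("a", "a", "a", "b", "b", "c")
  ours <- amova_dist(d, groups, permutations = "exhaustive")
  oracle <- brute_amova(d, groups)
  for (f in c("ss_among", "ss_within", "sigma2_among", "sigma2_within",
              "phi_st", "pct_among")) {
    expect_equal(ours[[f]], oracle[[f]], tolerance = 1e-12)
  }
  # exhaustive p equals explicit enumeration of label permutations
  perms <- wolfdemog:::all_permutations(6)
  stats <- apply(perms, 1, function(p) brute_amova(d, groups[p])$phi_st)
  expect_equal(ours$p, mean(stats >= oracle$phi_st - 1e-12),
               tolerance = 1e-12)
})

test_that("AMOVA is invariant to reordering and to distance scaling", {
  set.seed(23)
  x <- rnorm(10)
  d <- as.matrix(dist(x))
  groups <- rep(c("u", "v"), 5)
  a1 <- amova_dist(d, groups, n_perm = 49, seed = 3)
  p <- sample(10)
  a2 <- amova_dist(d[p, p], groups[p], n_perm = 49, seed = 3)
  expect_equal(a2$pct_among, a1$pct_among, tolerance = 1e-9)
  a3 <- amova_dist(2.5 * d, groups, n_perm = 49, seed = 3)
  expect_equal(a3$pct_among, a1$pct_among, tolerance = 1e-9)
  expect_equal(a3$phi_st, a1$phi_st, tolerance = 1e-9)
})

test_that("homogeneous data yield near-zero among-group variance", {
  set.seed(29)
  reps <- 40
  pcts <- numeric(reps)
  ps <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- as.matrix(dist(rnorm(12)))
    out <- amova_dist(d, rep(c("a", "b", "c"), 4), n_perm = 59,
                      seed = 1000 + i)
    pcts[i] <- out$pct_among
    ps[i] <- out$p
  }
  expect_lt(abs(mean(pcts)), 5)
  expect_gt(mean(ps > 0.05), 0.75)  # null p-values mostly non-significant
})
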