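test_that("prior draws respect intervals and scales", {
  p <- sample_prior("expansion_bottleneck", "Beringia", 4000, seed = 1)
  expect_named(p, c("m", "K1", "K2", "K3", "x", "T", "dT"))
  expect_true(all(p$m >= 0.001 & p$m <= 20))
  expect_true(all(p$K1 >= 0.01 & p$K1 <= 100))
  expect_true(all(p$x >= 0 & p$x <= 1))
  expect_true(all(p$T >= 5 & p$T <= 40))
  expect_true(all(p$dT >= 0.001 & p$dT <= 1))
  # log-uniform K: median at the geometric centre of [0.01, 100] = 1,
  # and log10(K) uniform (quartiles at -1 and 1)
  expect_lt(abs(median(p$K1) - 1), 0.25)
  expect_lt(abs(quantile(log10(p$K2), 0.25) + 1), 0.15)
  expect_lt(abs(quantile(log10(p$K2), 0.75) - 1), 0.15)
  # American origins carry the ice-sheet restriction on T
  pa <- sample_prior("expansion", "NorthAmerica", 500, seed = 2)
  expect_true(all(pa$T >= 9 & pa$T <= 16))
  pa2 <- sample_prior("expansion", "ArcticNorthAmerica", 500, seed = 2)
  expect_true(all(pa2$T >= 9 & pa2$T <= 16))
  expect_error(sample_prior("expansion", "Beringia", 0, seed = 1), "n must")
  expect_error(sample_prior("weird", NULL, 10, seed = 1))
  # reproducible
  expect_identical(sample_prior("static", NULL, 50, seed = 9),
                   sample_prior("static", NULL, 50, seed = 9))
})

test_that("ABC distance is the squared-Euclidean over unmasked entries", {
  obs <- setNames(as.numeric(1:10), wolfdemog:::STAT_NAMES_FULL)
  expect_equal(abc_distance(obs, obs, mask = names(obs)), 0)
  sim <- obs + 1
  expect_equal(abc_distance(sim, obs, mask = names(obs)), 10)
  # default nine-statistic mask drops within_ME
  sim2 <- obs
  sim2["within_ME"] <- 1e6
  expect_equal(abc_distance(sim2, obs), 0)
  # unmasked missing entries are an error
  sim3 <- obs
  sim3["within_EUR"] <- NA
  expect_error(abc_distance(sim3, obs), "missing")
  # capped simulations get infinite distance
  m <- rbind(c(obs, capped = 0), c(obs, capped = 1))
  d <- abc_distance(m, obs)
  expect_equal(d, c(0, Inf))
})

test_that("rejection accepts the smallest tenth with index tie-breaks", {
  d <- rev(seq_len(1000))  # distances 1000..1
  acc <- abc_reject(d, 0.10)
  expect_equal(sum(acc), 100)
  expect_true(all(which(acc) > 900))
  # ties broken by draw index
  acc2 <- abc_reject(rep(1, 50), 0.10)
  expect_equal(which(acc2), 1:5)
  expect_equal(sum(abc_reject(runif(57), 0.10)), ceiling(5.7))
  expect_true(all(abc_reject(runif(20), 1)))
  expect_error(abc_reject(runif(5), 0.1), "at least 10")
  expect_error(abc_reject(runif(20), 0), "fraction")
})

test_that("kernel likelihood ranks near clouds above far ones", {
  set.seed(42)
  nm <- summary_stat_names()
  cloud <- matrix(rnorm(200 * 9, mean = 50, sd = 2), ncol = 9,
                  dimnames = list(NULL, nm))
  inside <- setNames(rep(50, 9), nm)
  outside <- setNames(rep(80, 9), nm)
  expect_gt(scenario_likelihood(cloud, inside),
            scenario_likelihood(cloud, outside))
  # identical accepted clouds give identical likelihoods (BF = 1)
  expect_equal(scenario_likelihood(cloud, inside),
               scenario_likelihood(cloud[, nm], inside))
  # degenerate dimension falls back to the floor bandwidth
  cloud2 <- cloud
  cloud2[, 1] <- 7
  obs2 <- inside; obs2[1] <- 7
  expect_warning(l <- scenario_likelihood(cloud2, obs2), "degenerate")
  expect_true(is.finite(l) && l > 0)
  expect_error(scenario_likelihood(cloud[1:10, ], inside), ">= 20")
})

test_that("posterior summaries report quantiles on the natural scale", {
  draws <- data.frame(T = seq(10, 30, length.out = 21),
                      m = rep(0.1, 21))
  ps <- posterior_summary(draws)
  expect_equal(ps$median[ps$parameter == "T"], 20)
  expect_true(is.na(ps$log10_median[ps$parameter == "T"]))
  expect_equal(ps$log10_median[ps$parameter == "m"], -1)
  expect_equal(ps$iqr[ps$parameter == "m"], 0)
  expect_equal(ps$ci_low[ps$parameter == "m"],
               ps$ci_high[ps$parameter == "m"])
})

test_that("the sixteen candidate scenarios are enumerated", {
  sc <- scenario_set(deme_graph())
  expect_equal(nrow(sc), 16)
  expect_equal(sum(sc$family == "static"), 1)
  expect_equal(sum(sc$family == "bottleneck"), 1)
  expect_equal(sum(sc$family == "expansion"), 7)
  expect_equal(sum(sc$family == "expansion_bottleneck"), 7)
  expect_false(anyDuplicated(sc$name) > 0)
})

test_that("a reduced ABC run is deterministic and well-formed", {
  graph <- deme_graph()
  d <- make_design(graph, n_modern = 16, n_ancient = 8, seed = 6)
  gg <- simulate_genealogy(graph, default_truth_scenario(), d, seed = 13)
  obs <- tmrca_summary(gg, graph)
  scen <- scenario_set(graph)[c(1, 2, 7, 14), ]  # static, bottleneck, 2 expansions
  r1 <- run_abc(obs, graph, d, scenarios = scen, n_sims = 400,
                acceptance = 0.10, seed = 99)
  r2 <- run_abc(obs, graph, d, scenarios = scen, n_sims = 400,
                acceptance = 0.10, seed = 99)
  expect_identical(r1$table, r2$table)
  expect_equal(nrow(r1$table), 4)
  expect_equal(max(r1$table$bayes_factor), 1)
  expect_equal(r1$table$bayes_factor[1], 1)
  expect_true(all(r1$table$n_accepted == 40))
  det <- r1$scenarios[[r1$best]]
  expect_equal(sum(det$accepted), 40)
  expect_equal(nrow(det$accepted_summaries), 40)
  expect_true(all(diff(sort(det$distances)[1:40]) >= 0))
  # posterior summaries exist for every free parameter of the best scenario
  expect_true(all(names(det$params) %in% det$posterior$parameter))
})
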