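# Approximate Bayesian Computation: priors, mass simulation of summary
# statistics, rejection, scenario likelihoods / Bayes factors and posterior
# parameter summaries.

#' Prior specification for the scenario parameters
#'
#' Defaults: `m` log-uniform on \[0.001, 20\] (events per ky); `K`, `K1`,
#' `K2`, `K3` log-uniform on \[0.01, 100\] (ky); `x` uniform on \[0, 1\];
#' `T` uniform on \[5, 40\] ky BP -- restricted to \[9, 16\] for expansions
#' out of North America or Arctic North America, where LGM ice sheets and
#' deglacial sea-level rise bracket the possible start of an expansion;
#' `dT` uniform on \[0.001, 1\] ky.
#'
#' @param m,K,x,T,dT Two-element ranges overriding the defaults.
#' @param T_american Range of `T` for American origins.
#' @return List of class `prior_spec`.
#' @export
prior_spec <- function(m = c(0.001, 20), K = c(0.01, 100), x = c(0, 1),
                       T = c(5, 40), dT = c(0.001, 1),
                       T_american = c(9, 16)) {
  chk <- function(r, nm) {
    if (length(r) != 2L || !is.numeric(r) || r[1] > r[2]) {
      stop("invalid range for ", nm)
    }
    as.numeric(r)
  }
  structure(list(m = chk(m, "m"), K = chk(K, "K"), x = chk(x, "x"),
                 T = chk(T, "T"), dT = chk(dT, "dT"),
                 T_american = chk(T_american, "T_american")),
            class = "prior_spec")
}

AMERICAN_ORIGINS <- c("NorthAmerica", "ArcticNorthAmerica")

#' Draw scenario parameters from the prior
#'
#' `m` and the `K` parameters are drawn log-uniformly (uniform on log10
#' scale); `x`, `T` and `dT` uniformly. For expansions out of North America
#' or Arctic North America the `T` draw respects the restricted range.
#'
#' @param family Scenario family (see [scenario()]).
#' @param origin Expansion origin deme (expansion families), else `NULL`.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @param prior A [prior_spec()].
#' @return data.frame with one row per draw; columns depend on the family
#'   (`m`, then `K` or `K1`/`K2`/`K3`, then `x`, `T`, `dT` if expansion).
#' @export
sample_prior <- function(family, origin = NULL, n, seed,
                         prior = prior_spec()) {
  family <- match.arg(family, SCENARIO_FAMILIES)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  runif_log10 <- function(n, r) 10^runif(n, log10(r[1]), log10(r[2]))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  out <- data.frame(m = runif_log10(n, prior$m))
  if (family %in% c("bottleneck", "expansion_bottleneck")) {
    out$K1 <- runif_log10(n, prior$K)
    out$K2 <- runif_log10(n, prior$K)
    out$K3 <- runif_log10(n, prior$K)
  } else {
    out$K <- runif_log10(n, prior$K)
  }
  if (family %in% c("expansion", "expansion_bottleneck")) {
    if (is.null(origin)) stop("expansion family needs an origin")
    Tr <- if (origin %in% AMERICAN_ORIGINS) prior$T_american else prior$T
    out$x <- runif(n, prior$x[1], prior$x[2])
    out$T <- runif(n, Tr[1], Tr[2])
    out$dT <- runif(n, prior$dT[1], prior$dT[2])
  }
  out
}

#' The sixteen candidate demographic scenarios
#'
#' One static scenario, one bottleneck scenario, and an expansion and a
#' combined expansion+bottleneck scenario for each of the seven possible
#' origin demes.
#'
#' @param graph A [deme_graph()].
#' @return data.frame with columns `name`, `family`, `origin`.
#' @export
scenario_set <- function(graph = deme_graph()) {
  origins <- graph$demes
  out <- rbind(
    data.frame(family = "static", origin = NA_character_),
    data.frame(family = "bottleneck", origin = NA_character_),
    data.frame(family = "expansion", origin = origins),
    data.frame(family = "expansion_bottleneck", origin = origins)
  )
  out$name <- ifelse(is.na(out$origin), out$family,
                     paste(out$family, out$origin, sep = "@"))
  out[, c("name", "family", "origin")]
}

#' Squared-Euclidean ABC distance
#'
#' Sum of squared differences between simulated and observed summary
#' statistics over the unmasked entries. With `standardize = TRUE` each
#' statistic is first divided by its standard deviation across the
#' simulation pool (off by default, matching the plain squared-Euclidean
#' definition).
#'
#' @param sim Numeric vector of simulated statistics, or a matrix with one
#'   simulation per row (named columns).
#' @param obs Named numeric vector of observed statistics.
#' @param mask Names of the statistics to use (default
#'   [summary_stat_names()], i.e. the nine-statistic set).
#' @param standardize Standardize by per-statistic scale of the pool.
#' @return Non-negative scalar, or a vector with one distance per row of
#'   `sim`. Simulations flagged as capped (attribute/column `capped`) get
#'   distance `Inf`.
#' @export
abc_distance <- function(sim, obs, mask = summary_stat_names(),
                         standardize = FALSE) {
  if (is.null(dim(sim))) sim <- matrix(sim, nrow = 1,
                                       dimnames = list(NULL, names(sim)))
  if (!all(mask %in% colnames(sim)) || !all(mask %in% names(obs))) {
    stop("mask entries absent from sim or obs")
  }
  capped <- if ("capped" %in% colnames(sim)) sim[, "capped"] > 0 else
    rep(FALSE, nrow(sim))
  s <- sim[, mask, drop = FALSE]
  o <- obs[mask]
  if (any(is.na(o))) {
    stop("observed statistic is missing and not masked: ",
         paste(mask[is.na(o)], collapse = ", "))
  }
  if (standardize) {
    sc <- apply(s, 2, sd, na.rm = TRUE)
    sc[!is.finite(sc) | sc == 0] <- 1
    s <- sweep(s, 2, sc, "/")
    o <- o / sc
  }
  d <- rowSums(sweep(s, 2, o, "-")^2)
  bad <- !capped & apply(is.na(s), 1, any)
  if (any(bad)) {
    stop("simulated statistic missing (no pairs in a group) and not masked")
  }
  d[capped] <- Inf
  unname(d)
}

#' Rejection step
#'
#' Accepts the `ceiling(fraction * n)` smallest distances; ties are broken
#' by draw index (first come, first accepted).
#'
#' @param distances Numeric vector of ABC distances.
#' @param fraction Acceptance fraction in (0, 1\]; default the lowest tenth
#'   percentile of distances.
#' @return Logical acceptance mask of the same length.
#' @export
abc_reject <- function(distances, fraction = 0.10) {
  n <- length(distances)
  if (n < 10) stop("need at least 10 simulations")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  k <- ceiling(fraction * n)
  ord <- order(distances, seq_len(n))
  acc <- rep(FALSE, n)
  acc[ord[seq_len(k)]] <- TRUE
  acc
}

#' Marginal likelihood of a scenario at the observed statistics
#'
#' Gaussian product-kernel density estimate of the accepted simulations'
#' summary statistics, evaluated at the observed vector. Bandwidths follow
#' Silverman's rule per dimension over the accepted draws; a degenerate
#' (zero-variance) dimension falls back to `bw_floor` with a warning.
#'
#' @param accepted Matrix of accepted summary vectors (rows = simulations,
#'   named columns).
#' @param obs Named numeric vector of observed statistics.
#' @param mask Statistics entering the density (default the nine-statistic
#'   set).
#' @param bw_floor Minimum bandwidth (ky).
#' @return Scalar density estimate (>= 0).
#' @export
scenario_likelihood <- function(accepted, obs, mask = summary_stat_names(),
                                bw_floor = 1e-6) {
  if (nrow(accepted) < 20) stop("need >= 20 accepted draws")
  s <- accepted[, mask, drop = FALSE]
  o <- obs[mask]
  h <- apply(s, 2, bw.nrd0)
  degen <- !is.finite(h) | h <= 0 | apply(s, 2, sd) == 0
  if (any(degen)) {
    warning("degenerate (zero-variance) summary dimension; using floor bandwidth")
    h[degen] <- bw_floor
  }
  h <- pmax(h, bw_floor)
  lg <- sweep(s, 2, o, "-")
  lg <- sweep(lg, 2, h, "/")
  logk <- -0.5 * rowSums(lg^2) - sum(log(h)) -
    ncol(s) / 2 * log(2 * pi)
  mx <- max(logk)
  exp(mx + log(mean(exp(logk - mx))))
}

#' Posterior summaries of accepted parameter draws
#'
#' @param draws data.frame of accepted parameter draws (one column per
#'   parameter).
#' @param log_params Parameters whose posterior is additionally reported on
#'   the log10 scale (the log-uniform ones by default).
#' @return data.frame with one row per parameter: `median`, `q25`, `q75`,
#'   `iqr`, `ci_low`/`ci_high` (95% interval), and `log10_median` where
#'   applicable. Quantiles are computed on the natural scale.
#' @export
posterior_summary <- function(draws,
                              log_params = c("m", "K", "K1", "K2", "K3")) {
  if (nrow(draws) < 20) stop("need >= 20 accepted draws")
  rows <- lapply(names(draws), function(p) {
    v <- draws[[p]]
    q <- quantile(v, c(0.5, 0.25, 0.75, 0.025, 0.975), names = FALSE,
                  type = 7)
    data.frame(parameter = p, median = q[1], q25 = q[2], q75 = q[3],
               iqr = q[3] - q[2], ci_low = q[4], ci_high = q[5],
               log10_median = if (p %in% log_params) log10(q[1]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Batch-simulate summary statistics for one scenario. Returns a matrix with
# the 10 statistic columns plus a `capped` indicator column.
simulate_summaries <- function(graph, family, origin, params, samples,
                               seed_base, time_cap = 1e4,
                               neighbours_at = c("T", "T_minus_dT"),
                               epoch_boundaries = c(15, 40)) {
  neighbours_at <- match.arg(neighbours_at)
  family <- match.arg(family, SCENARIO_FAMILIES)
  samples <- validate_samples(samples, graph)
  ea <- sim_engine_args(graph, samples)
  bottleneck <- family %in% c("bottleneck", "expansion_bottleneck")
  expansion <- family %in% c("expansion", "expansion_bottleneck")
  bounds <- if (bottleneck) epoch_boundaries else numeric(0)
  Kcols <- if (bottleneck) c("K1", "K2", "K3") else c("K", "K", "K")[1]
  need <- c("m", if (expansion) c("x", "T", "dT"), Kcols)
  if (!all(need %in% names(params))) {
    stop("params must have columns: ", paste(need, collapse = ", "))
  }
  nsim <- nrow(params)
  par <- cbind(
    params$m,
    if (expansion) params$x else rep(0, nsim),
    if (expansion) params$T else rep(0, nsim),
    if (expansion) params$dT else rep(1, nsim),
    as.matrix(params[, Kcols, drop = FALSE])
  )
  n_demes <- length(graph$demes)
  col_sources <- vector("list", n_demes)
  if (expansion) {
    hops <- hop_distances(graph, origin)
    hop <- as.integer(hops[graph$demes])
    for (i in seq_len(n_demes)) {
      d <- graph$demes[i]
      if (d != origin) {
        nb <- graph$adj[[d]]
        col_sources[[i]] <- match(nb[hops[nb] < hops[d]], graph$demes)
      }
    }
  } else {
    hop <- rep(NA_integer_, n_demes)
  }
  col_offset <- if (neighbours_at == "T") 0L else 1L
  res <- .sim_batch_cpp(ea$adj, ea$sample_deme, ea$sample_age,
                        ea$sample_group, bounds, par, hop, col_sources,
                        col_offset, time_cap, as.numeric(seed_base))
  colnames(res) <- c(STAT_NAMES_FULL, "capped")
  res
}

# per-scenario uint64 seed stream base, disjoint across scenarios and safe
# in double precision (< 2^53)
abc_seed_base <- function(seed, scenario_index) {
  ((seed %% 2^22) * 64 + (scenario_index %% 64)) * 2^24
}

#' Run the full ABC analysis
#'
#' For each candidate scenario: draw `n_sims` parameter combinations from
#' the prior, simulate the genealogy summary statistics for the sampling
#' design in `samples`, compute squared-Euclidean distances to `obs`, accept
#' the lowest `acceptance` fraction, estimate the scenario's marginal
#' likelihood by a Gaussian kernel density at the observed vector, and
#' summarize the accepted parameter draws. Bayes factors are reported
#' relative to the best scenario. The run is deterministic given `seed`;
#' simulations are keyed by (scenario, draw index), so results do not depend
#' on execution order.
#'
#' @param obs Named numeric vector of observed summary statistics (from
#'   [tmrca_summary()]).
#' @param graph A [deme_graph()].
#' @param samples Sample table: the demes and ages to simulate (normally the
#'   same design as the observed data).
#' @param scenarios data.frame as from [scenario_set()] (possibly a subset).
#' @param n_sims Simulations per scenario.
#' @param acceptance Acceptance fraction (lowest-distance quantile).
#' @param seed Master integer seed.
#' @param prior A [prior_spec()].
#' @param mask Statistics used for distances and likelihoods.
#' @param time_cap See [simulate_genealogy()]; capped simulations get
#'   infinite distance and are counted in `n_capped`.
#' @param keep_summaries Keep the full summary matrices in the result
#'   (memory!); accepted rows are always kept.
#' @return Object of class `abc_result`: list with `table` (per-scenario
#'   likelihoods, Bayes factors, acceptance counts), `scenarios` (per-
#'   scenario detail: parameter draws, distances, acceptance mask, accepted
#'   summaries, posterior summaries), `best` (name of the highest-likelihood
#'   scenario), and the call settings.
#' @export
run_abc <- function(obs, graph, samples, scenarios = scenario_set(graph),
                    n_sims = 20000, acceptance = 0.10, seed = 1,
                    prior = prior_spec(), mask = summary_stat_names(),
                    time_cap = 1e4, keep_summaries = FALSE) {
  stopifnot(nrow(scenarios) >= 1)
  detail <- vector("list", nrow(scenarios))
  names(detail) <- scenarios$name
  lik <- numeric(nrow(scenarios))
  ncap <- integer(nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    fam <- scenarios$family[i]
    org <- if (is.na(scenarios$origin[i])) NULL else scenarios$origin[i]
    params <- sample_prior(fam, org, n_sims,
                           seed = (seed + 7919 * i) %% .Machine$integer.max,
                           prior = prior)
    summ <- simulate_summaries(graph, fam, org, params, samples,
                               seed_base = abc_seed_base(seed, i),
                               time_cap = time_cap)
    d <- abc_distance(summ, obs, mask = mask)
    acc <- abc_reject(d, acceptance)
    accsum <- summ[acc, , drop = FALSE]
    lik[i] <- scenario_likelihood(accsum, obs, mask = mask)
    ncap[i] <- sum(summ[, "capped"] > 0)
    post <- posterior_summary(params[acc, , drop = FALSE])
    detail[[i]] <- list(
      name = scenarios$name[i], family = fam, origin = org,
      params = params, distances = d, accepted = acc,
      accepted_summaries = accsum,
      summaries = if (keep_summaries) summ else NULL,
      posterior = post, likelihood = lik[i], n_capped = ncap[i]
    )
  }
  bf <- lik / max(lik)
  tab <- data.frame(name = scenarios$name, family = scenarios$family,
                    origin = scenarios$origin, likelihood = lik,
                    bayes_factor = bf, n_accepted = ceiling(acceptance * n_sims),
                    n_capped = ncap, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$bayes_factor), ]
  rownames(tab) <- NULL
  structure(
    list(table = tab, scenarios = detail, best = tab$name[1],
         obs = obs, mask = mask, n_sims = n_sims, acceptance = acceptance,
         seed = seed),
    class = "abc_result"
  )
}

#' @export
print.abc_result <- function(x, ...) {
  cat("ABC scenario selection:", length(x$scenarios), "scenarios,",
      x$n_sims, "simulations each\n")
  cat("Best scenario:", x$best, "\n\n")
  tab <- x$table
  tab$likelihood <- signif(tab$likelihood, 3)
  tab$bayes_factor <- signif(tab$bayes_factor, 3)
  print(head(tab, 10), row.names = FALSE)
  invisible(x)
}

#' Scenario-recovery experiment
#'
#' Generates pseudo-observed data under a known truth scenario, runs the
#' full ABC selection, and reports whether the true origin ranks in the
#' top-2 Bayes factors, the Bayes factor of the static scenario, and the
#' 95% posterior interval for the expansion start `T` from the
#' best-supported expansion scenario.
#'
#' @param truth A [scenario()] with an expansion component (the generating
#'   model).
#' @param design Sample table for the pseudo-observed data (default: the
#'   full synthetic design of [make_design()]).
#' @param n_reps Number of independent repetitions.
#' @param n_sims Simulations per scenario per repetition.
#' @param seed Master seed.
#' @param graph A [deme_graph()].
#' @param ... Passed to [run_abc()].
#' @return data.frame with one row per repetition: `true_in_top2`,
#'   `bf_static`, `T_true`; `T_ci_low`/`T_ci_high`/`T_median`/`T_covered`
#'   from the best-supported expansion scenario (the interval an analyst
#'   would report); `T_true_ci_low`/`T_true_ci_high`/`T_true_covered` from
#'   the posterior under the true scenario (the classical coverage
#'   experiment); and `best` (scenario name).
#' @export
abc_recovery <- function(truth, design = NULL, n_reps = 20, n_sims = 20000,
                         seed = 1, graph = deme_graph(), ...) {
  if (is.null(truth$expansion)) stop("truth scenario must include an expansion")
  if (is.null(design)) design <- make_design(graph, seed = seed)
  scen <- scenario_set(graph)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- (seed + 104729 * r) %% .Machine$integer.max
    g <- simulate_genealogy(graph, truth, design, seed = rep_seed)
    obs <- tmrca_summary(g, graph)
    res <- run_abc(obs, graph, design, scenarios = scen, n_sims = n_sims,
                   seed = rep_seed, ...)
    tab <- res$table
    top2_orig <- tab$origin[1:2]
    true_org <- truth$expansion$origin
    bf_static <- tab$bayes_factor[tab$family == "static"]
    # reported T interval: best-supported scenario that estimates T
    exp_tab <- tab[tab$family %in% c("expansion", "expansion_bottleneck"), ]
    best_exp <- exp_tab$name[1]
    post <- res$scenarios[[best_exp]]$posterior
    Trow <- post[post$parameter == "T", ]
    # classical coverage: posterior of T under the generating scenario
    true_name <- paste(truth$family, true_org, sep = "@")
    post_true <- res$scenarios[[true_name]]$posterior
    Ttrue <- post_true[post_true$parameter == "T", ]
    Tstar <- truth$expansion$T
    out[[r]] <- data.frame(
      rep = r, true_in_top2 = true_org %in% top2_orig,
      bf_static = bf_static, T_true = Tstar,
      T_ci_low = Trow$ci_low, T_ci_high = Trow$ci_high,
      T_median = Trow$median,
      T_covered = Tstar >= Trow$ci_low && Tstar <= Trow$ci_high,
      T_true_ci_low = Ttrue$ci_low, T_true_ci_high = Ttrue$ci_high,
      T_true_covered = Tstar >= Ttrue$ci_low && Tstar <= Ttrue$ci_high,
      best = tab$name[1], stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
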