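# Independent oracles used across the suite. These deliberately re-derive
# expected values through different routes than the package code: a linear
# first-step-analysis solver for expected pairwise coalescence times in the
# static structured coalescent, and explicit-loop implementations of the
# Mantel statistic and the AMOVA sums of squares.

# Exact expected TMRCA of a pair of lineages under the static structured
# coalescent on an arbitrary deme graph: states are unordered deme pairs,
# within-deme coalescence at rate 1/K, per-lineage migration at rate m with
# uniform destination among neighbours. Solved as a linear system.
expected_pair_tmrca <- function(graph, K, m) {
  demes <- graph$demes
  nd <- length(demes)
  states <- list()
  for (i in seq_len(nd)) for (j in i:nd) states[[length(states) + 1]] <- c(i, j)
  key <- vapply(states, paste, collapse = "_", FUN.VALUE = "")
  ns <- length(states)
  A <- matrix(0, ns, ns)
  b <- rep(1, ns)
  for (s in seq_len(ns)) {
    i <- states[[s]][1]; j <- states[[s]][2]
    coal <- if (i == j) 1 / K else 0
    total <- coal
    trans <- list()
    for (lin in c(i, j)) {
      other <- if (lin == i) j else i
      nb <- graph$adj[[demes[lin]]]
      for (d in match(nb, demes)) {
        rate <- m / length(nb)
        to <- sort(c(d, other))
        trans[[length(trans) + 1]] <- list(key = paste(to, collapse = "_"),
                                           rate = rate)
        total <- total + rate
      }
    }
    A[s, s] <- total
    for (tr in trans) {
      t_idx <- match(tr$key, key)
      A[s, t_idx] <- A[s, t_idx] - tr$rate
    }
  }
  E <- solve(A, b)
  out <- matrix(NA_real_, nd, nd, dimnames = list(demes, demes))
  for (s in seq_len(ns)) {
    i <- states[[s]][1]; j <- states[[s]][2]
    out[i, j] <- out[j, i] <- E[s]
  }
  out
}

# Pearson correlation of the upper triangles computed with explicit sums
brute_cor_upper <- function(a, b) {
  n <- nrow(a)
  xa <- c(); xb <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xa <- c(xa, a[i, j]); xb <- c(xb, b[i, j])
  }
  sa <- sum((xa - mean(xa))^2); sb <- sum((xb - mean(xb))^2)
  sum((xa - mean(xa)) * (xb - mean(xb))) / sqrt(sa * sb)
}

# Exhaustive Mantel test by explicit enumeration (independent of the
# package's permutation machinery)
brute_mantel <- function(geo, gen) {
  n <- nrow(geo)
  perms <- NULL
  rec <- function(v, rest) {
    if (!length(rest)) { perms[[length(perms) + 1]] <<- v; return() }
    for (r in rest) rec(c(v, r), setdiff(rest, r))
  }
  perms <- list(); rec(integer(0), seq_len(n))
  obs <- brute_cor_upper(geo, gen)
  stats <- vapply(perms, function(p) brute_cor_upper(geo, gen[p, p]),
                  numeric(1))
  list(rho = obs, p = mean(stats >= obs - 1e-12), n_perm = length(perms))
}

# One-level AMOVA components by direct application of the sums-of-squares
# definitions (explicit loops over pairs, no matrix shortcuts)
brute_amova <- function(d, groups) {
  n <- nrow(d)
  glev <- unique(groups)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in glev) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    s <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) s <- s + d[idx[a], idx[b]]^2
    }
    ssw <- ssw + s / length(idx)
  }
  ssa <- sst - ssw
  G <- length(glev)
  msa <- ssa / (G - 1)
  msw <- ssw / (n - G)
  ngs <- as.numeric(table(groups)[glev])
  n0 <- (n - sum(ngs^2) / n) / (G - 1)
  s2a <- (msa - msw) / n0
  s2w <- msw
  list(ss_among = ssa, ss_within = ssw, sigma2_among = s2a,
       sigma2_within = s2w, phi_st = s2a / (s2a + s2w),
       pct_among = 100 * s2a / (s2a + s2w))
}

# shared small fixtures
toy_graph2 <- function() {
  deme_graph(demes = c("A", "B"), edges = rbind(c("A", "B")),
             stat_groups = c(A = "EUR", B = "ME"))
}

toy_graph3_line <- function() {
  deme_graph(demes = c("A", "B", "C"),
             edges = rbind(c("A", "B"), c("B", "C")),
             stat_groups = c(A = "EUR", B = "ME", C = "EAS"))
}

pair_samples <- function(demes, ages = c(0, 0)) {
  data.frame(id = c("s1", "s2"), deme = demes, age_ky = ages,
             stringsAsFactors = FALSE)
}

# mean pairwise TMRCA of a two-lineage configuration over many replicate
# genealogies, via the batch engine (one fixed parameter row per replicate)
mean_pair_tmrca <- function(graph, family, params, samples, n_rep, seed_base,
                            origin = NULL) {
  p <- params[rep(1, n_rep), , drop = FALSE]
  s <- wolfdemog:::simulate_summaries(graph, family, origin, p, samples,
                                      seed_base = seed_base)
  stopifnot(all(s[, "capped"] == 0))
  nm <- colnames(s)[colSums(!is.na(s[, 1:10, drop = FALSE])) == n_rep]
  s[, nm[1]]
}
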