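# Population-structure analyses on geolocated alignments: great-circle
# distances, pairwise genetic distances, Mantel isolation-by-distance test
# and one-level AMOVA.

#' Great-circle distance (Haversine)
#'
#' Distance in kilometres between points on a sphere of radius `r`,
#' `G = 2 r asin( sqrt( sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dlambda/2) ) )`.
#' Vectorized over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (latitudes in
#'   \[-90, 90\], longitudes in \[-180, 360)).
#' @param r Earth radius in km.
#' @return Distance(s) in km.
#' @examples
#' haversine_km(0, 0, 0, 90)  # quarter great circle, ~10007.5 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, r = 6371) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude out of [-90, 90]")
  if (any(c(lon1, lon2) < -180 | c(lon1, lon2) >= 360)) {
    stop("longitude out of [-180, 360)")
  }
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Pairwise geographic distance matrix
#'
#' @param samples data.frame with columns `id`, `lat`, `lon`.
#' @param r Earth radius, km.
#' @return Symmetric matrix of great-circle distances (km) over sample ids.
#' @export
geo_distance_matrix <- function(samples, r = 6371) {
  need <- c("id", "lat", "lon")
  if (!all(need %in% names(samples))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(samples)
  m <- matrix(0, n, n, dimnames = list(samples$id, samples$id))
  for (i in seq_len(n)) {
    m[i, ] <- haversine_km(samples$lat[i], samples$lon[i],
                           samples$lat, samples$lon, r = r)
  }
  m[abs(m) < 1e-12] <- 0
  (m + t(m)) / 2
}

#' Pairwise genetic distance matrix (proportion of differing sites)
#'
#' Raw p-distance with pairwise deletion: for each pair the denominator is
#' the number of sites where both sequences carry an unambiguous base
#' (missing data -- N, gaps, ? -- is excluded pair by pair). Computed with
#' `ape::dist.dna(model = "raw", pairwise.deletion = TRUE)`.
#'
#' @param aln A `DNAbin` alignment (matrix of equal-length sequences).
#' @return Symmetric matrix of proportions in \[0, 1\].
#' @export
genetic_distance_matrix <- function(aln) {
  if (!inherits(aln, "DNAbin")) aln <- ape::as.DNAbin(aln)
  aln <- as.matrix(aln)
  d <- ape::dist.dna(aln, model = "raw", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(d))) {
    stop("sequence pair with no comparable (non-missing) sites")
  }
  d
}

mantel_statistic <- function(geo, gen, method) {
  lt <- lower.tri(geo)
  if (method == "spearman") {
    cor(geo[lt], gen[lt], method = "spearman")
  } else {
    cor(geo[lt], gen[lt])
  }
}

#' Mantel test of isolation by distance
#'
#' Correlates the off-diagonal entries of a geographic and a genetic
#' distance matrix; significance by joint row/column permutation of one
#' matrix. One-sided p-value (permuted correlation >= observed) with the
#' `+1/(n_perm + 1)` correction; with `permutations = "exhaustive"` all
#' `n!` relabelings are enumerated and the p-value is exact.
#'
#' @param geo,gen Symmetric distance matrices over the same samples (same
#'   order).
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the permutation draw.
#' @param method Correlation flavour: Pearson (default) or Spearman.
#' @param permutations `"sampled"` or `"exhaustive"` (n <= 8).
#' @return List with `rho`, `p`, `n_perm`, `method`.
#' @export
mantel_ibd <- function(geo, gen, n_perm = 10000, seed = 1,
                       method = c("pearson", "spearman"),
                       permutations = c("sampled", "exhaustive")) {
  method <- match.arg(method)
  permutations <- match.arg(permutations)
  geo <- as.matrix(geo); gen <- as.matrix(gen)
  if (!all(dim(geo) == dim(gen))) stop("matrices must match")
  n <- nrow(geo)
  lt <- lower.tri(geo)
  if (sd(geo[lt]) == 0 || sd(gen[lt]) == 0) {
    stop("constant distance matrix: correlation undefined")
  }
  rho <- mantel_statistic(geo, gen, method)
  if (permutations == "exhaustive") {
    perms <- all_permutations(n)
    stat <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      mantel_statistic(geo, gen[p, p], method)
    }, numeric(1))
    p <- mean(stat >= rho - 1e-12)
    n_perm <- nrow(perms)
  } else {
    stat <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      mantel_statistic(geo, gen[p, p], method)
    }, numeric(1)))
    p <- (sum(stat >= rho - 1e-12) + 1) / (n_perm + 1)
  }
  list(rho = rho, p = p, n_perm = n_perm, method = method)
}

amova_components <- function(d2, groups) {
  # d2: squared distances; one-level AMOVA sums of squares
  N <- nrow(d2)
  glev <- unique(groups)
  G <- length(glev)
  ss_total <- sum(d2[lower.tri(d2)]) / N
  ss_within <- 0
  ng <- numeric(G)
  for (k in seq_len(G)) {
    i <- which(groups == glev[k])
    ng[k] <- length(i)
    if (length(i) > 1) {
      sub <- d2[i, i, drop = FALSE]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(i)
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1
  df_within <- N - G
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(ng^2) / N) / (G - 1)
  sigma2_w <- ms_within
  sigma2_a <- (ms_among - ms_within) / n0
  phi <- sigma2_a / (sigma2_a + sigma2_w)
  list(ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
       df_among = df_among, df_within = df_within,
       ms_among = ms_among, ms_within = ms_within, n0 = n0,
       sigma2_among = sigma2_a, sigma2_within = sigma2_w,
       phi_st = phi, pct_among = 100 * phi)
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared pairwise distances among and within groups following
#' the standard sums-of-squares decomposition with the unequal-sample-size
#' coefficient `n0`; reports the variance components, the percentage of
#' variance among groups, `Phi_ST`, and a permutation p-value obtained by
#' permuting group labels (one-sided: permuted `Phi_ST` >= observed).
#'
#' @param d Distance matrix (not squared; the function squares it).
#' @param groups Group label per sample (same order as `d`).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param permutations `"sampled"` or `"exhaustive"` (n <= 8).
#' @return List of class `amova_fit` with the components of
#'   the decomposition plus `p` and `n_perm`.
#' @export
amova_dist <- function(d, groups, n_perm = 10000, seed = 1,
                       permutations = c("sampled", "exhaustive")) {
  permutations <- match.arg(permutations)
  d <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("groups must match the matrix")
  if (length(unique(groups)) < 2) stop("need at least two groups")
  d2 <- d^2
  obs <- amova_components(d2, groups)
  if (permutations == "exhaustive") {
    perms <- all_permutations(nrow(d))
    stat <- vapply(seq_len(nrow(perms)), function(i) {
      amova_components(d2, groups[perms[i, ]])$phi_st
    }, numeric(1))
    p <- mean(stat >= obs$phi_st - 1e-12)
    n_perm <- nrow(perms)
  } else {
    stat <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      amova_components(d2, sample(groups))$phi_st
    }, numeric(1)))
    p <- (sum(stat >= obs$phi_st - 1e-12) + 1) / (n_perm + 1)
  }
  structure(c(obs, list(p = p, n_perm = n_perm, groups = table(groups))),
            class = "amova_fit")
}

#' @export
print.amova_fit <- function(x, ...) {
  cat("One-level AMOVA\n")
  cat(sprintf("  among groups : SS = %.4g, df = %d, sigma2 = %.4g\n",
              x$ss_among, x$df_among, x$sigma2_among))
  cat(sprintf("  within groups: SS = %.4g, df = %d, sigma2 = %.4g\n",
              x$ss_within, x$df_within, x$sigma2_within))
  cat(sprintf("  %% among = %.2f%%  (Phi_ST = %.4f),  p = %.4g (%d perms)\n",
              x$pct_among, x$phi_st, x$p, x$n_perm))
  invisible(x)
}
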