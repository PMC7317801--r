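#!/usr/bin/env Rscript
# Population-structure analyses of the synthetic alignment, paralleling the
# descriptive analyses run on the real data before demographic modelling:
# (a) isolation by distance across Eurasia (Mantel test of great-circle vs
# p-distance among modern samples), and (b) one-level AMOVA quantifying how
# much mitochondrial variance the seven demes capture. Reads results/data/,
# writes results/structure/.

library(wolfdemog)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

data_dir <- file.path("results", "data")
out_dir <- file.path("results", "structure")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

graph <- read_graph_config(file.path(data_dir, "deme_graph.yaml"))
md <- read_metadata(file.path(data_dir, "samples.tsv"), graph)
aln <- read_alignment(file.path(data_dir, "alignment.fasta"))

# modern Eurasian samples only, mirroring the IBD analysis of the real data
eurasia <- c("Europe", "MiddleEast", "CentralNorthEurasia", "EastEurasia",
             "Beringia")
mod <- md[md$is_modern & md$deme %in% eurasia, ]
gd_all <- genetic_distance_matrix(aln)
gd <- gd_all[mod$id, mod$id]
geo <- geo_distance_matrix(mod)
ibd <- mantel_ibd(geo, gd, n_perm = 10000, seed = seed)
cat(sprintf("IBD (modern Eurasia, n = %d): Mantel rho = %.3f, p = %.2g\n",
            nrow(mod), ibd$rho, ibd$p))

# AMOVA over all modern samples grouped by deme
mod_all <- md[md$is_modern, ]
am <- amova_dist(gd_all[mod_all$id, mod_all$id], mod_all$deme,
                 n_perm = 10000, seed = seed)
print(am)

write.csv(data.frame(
  analysis = c("ibd_mantel_rho", "ibd_mantel_p",
               "amova_pct_among", "amova_phi_st", "amova_p"),
  value = c(ibd$rho, ibd$p, am$pct_among, am$phi_st, am$p)
), file.path(out_dir, "structure_stats.csv"), row.names = FALSE)
write_run_manifest(list(step = "population_structure", seed = seed,
                        n_perm = 10000), out_dir)
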