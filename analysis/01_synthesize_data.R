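#!/usr/bin/env Rscript
# Generate the synthetic study data set: a sampling design emulating the
# 90-modern + 45-ancient wolf mitogenome panel, one pseudo-observed dated
# genealogy under the default truth scenario (expansion out of Beringia with
# an LGM bottleneck), and a mitogenome-like alignment with ~8% variable
# sites. Outputs go to results/data/.

library(wolfdemog)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

graph <- deme_graph()
design <- make_design(graph, seed = seed)
po <- make_pseudo_observed(design, default_truth_scenario(),
                           seed = seed + 1, graph = graph)
aln <- mutate_alignment(po$genealogy, seed = seed + 2)

write_metadata(design, file.path(out_dir, "samples.tsv"))
write_genealogy(po$genealogy, file.path(out_dir, "genealogy.nwk"))
write_truth(po$truth, file.path(out_dir, "truth.json"))
write_alignment(aln, file.path(out_dir, "alignment.fasta"))
write_graph_config(graph, file.path(out_dir, "deme_graph.yaml"))
write_run_manifest(list(step = "synthesize_data", seed = seed), out_dir)

v <- count_variable_sites(aln)
cat(sprintf("design: %d samples (%d ancient) across %d demes\n",
            nrow(design), sum(design$age_ky > 0), length(graph$demes)))
cat(sprintf("genealogy: root age %.1f ky BP\n", max(po$genealogy$node_age)))
cat(sprintf("alignment: %d bp, %d variable sites (%.1f%%)\n",
            ncol(as.matrix(aln)), v, 100 * v / ncol(as.matrix(aln))))
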