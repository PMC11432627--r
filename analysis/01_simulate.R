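#!/usr/bin/env Rscript

# Step 1: generate the synthetic six-cell-type study.
#
# Emulates the study design the downstream analyses assume: three
# progenitor (ESC, NSC, NPC) and three mature neuron (AD, Ngn2, Motor)
# cell types, 5000 enhancers of 500 bp per cell type of which 35% are
# cell-type-specific and 40% stage-shared, a 6000-gene universe, ABC
# scores straddling the 0.02 threshold and TPMs straddling the 1-TPM
# filter, FIMO-style TF binding with a planted stage bias, and a
# ~250,000-variant case/control space with a 3x case enrichment planted
# into C3 elements (written by step 06).

suppressMessages(library(epinets))

seed <- 42
out_dir <- "results/simulation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
genome <- generate_genome(cfg)
epi <- generate_epi_tables(cfg, genome)

for (ct in names(epi$networks)) {
  write_epi_table(epi$networks[[ct]],
                  file.path(out_dir, paste0(ct, "_epi.tsv")))
}
utils::write.table(genome, file.path(out_dir, "genome.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(epi$manifest$enhancers,
                   file.path(out_dir, "enhancer_manifest.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

tf <- generate_tfbs_table(cfg, epi)
write_fimo_tsv(tf$fimo, file.path(out_dir, "fimo.tsv"))
utils::write.table(tf$tf_truth, file.path(out_dir, "tf_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

ex <- generate_expression_and_genesets(cfg, epi, tf$tf_truth)
for (ct in names(ex$tpm_tables)) {
  write_tpm_table(ex$tpm_tables[[ct]],
                  file.path(out_dir, paste0(ct, "_tpm.tsv")))
}
utils::write.table(ex$de, file.path(out_dir, "de_table.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
writeLines(ex$disease_genes, file.path(out_dir, "disease_genes.txt"))

message("Simulated ", length(epi$networks), " cell-type networks of ",
        cfg$n_enhancers_per_celltype, " enhancers each (",
        nrow(epi$manifest$enhancers), " distinct elements), ",
        cfg$n_genes, " genes, ", cfg$n_tfs, " TFs.")
message("Tables written under ", out_dir)
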