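#!/usr/bin/env Rscript

# Step 3: collapsed network, subset network and C1-C4 sub-structures.
#
# Concatenates the six filtered networks into the collapsed network
# (duplicates kept, overlapping enhancers merged separately), builds the
# subset network (100-bp merge, nine stage-aware categories), and labels
# every EPI with its sub-structure: C1 one-to-one, C2 one enhancer to
# many promoters, C3 many enhancers to one promoter, C4 many-to-many.

suppressMessages(library(epinets))

net_dir <- "results/networks"
if (!file.exists(file.path(net_dir, "ESC_filtered.tsv"))) {
  stop("run analysis/02_score_and_filter.R first")
}
cts <- names(default_stages())
nets <- lapply(cts, function(ct)
  read_epi_table(file.path(net_dir, paste0(ct, "_filtered.tsv"))))
names(nets) <- cts

collapsed <- build_collapsed_network(nets)
write_bed(collapsed$merged_enhancers,
          file.path(net_dir, "merged_enhancers.bed"))
message(sprintf(
  "Collapsed network: %d EPIs across 6 cell types; %d distinct enhancer intervals, %d after overlap-merging",
  nrow(collapsed$records),
  nrow(unique(collapsed$records[, c("chrom", "start", "end")])),
  nrow(collapsed$merged_enhancers)))

subset_net <- build_subset_network(nets, gap = 100, agg = "max")
utils::write.table(subset_net, file.path(net_dir, "subset_network.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat_tab <- sort(table(subset_net$category), decreasing = TRUE)
message("Subset network categories (merged EPIs): ",
        paste(names(cat_tab), cat_tab, sep = "=", collapse = ", "))

sub_rows <- lapply(cts, function(ct) {
  lab <- classify_substructure(nets[[ct]])
  out <- nets[[ct]]
  out$substructure <- lab
  utils::write.table(out, file.path(net_dir, paste0(ct, "_labeled.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  c(cell_type = ct, round(substructure_distribution(lab), 4))
})
dist_tab <- as.data.frame(do.call(rbind, sub_rows))
utils::write.table(dist_tab, file.path(net_dir, "substructure_shares.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("Per-cell-type sub-structure shares written to ",
        file.path(net_dir, "substructure_shares.tsv"),
        " (C1..C4 columns sum to 1)")
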