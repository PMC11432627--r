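#!/usr/bin/env Rscript

# Step 4: cross-cell-type element comparison.
#
# Per-cell-type uniqueness fractions (an enhancer is unique when it shares
# no base pair with any other network's enhancers; a promoter when its
# gene symbol appears nowhere else) and the pairwise Jaccard matrices for
# enhancers (interval-level) and promoters (gene-symbol sets).

suppressMessages(library(epinets))

sim_dir <- "results/simulation"
out_dir <- "results/comparison"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cts <- names(default_stages())
nets <- lapply(cts, function(ct)
  read_epi_table(file.path(sim_dir, paste0(ct, "_epi.tsv"))))
names(nets) <- cts

u_enh <- unique_element_fraction(nets, kind = "enhancer")
u_pro <- unique_element_fraction(nets, kind = "promoter")
uniq <- data.frame(cell_type = cts, unique_enhancer_frac = round(u_enh, 4),
                   unique_promoter_frac = round(u_pro, 4))
utils::write.table(uniq, file.path(out_dir, "uniqueness.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf(
  "Mean uniqueness: enhancers %.1f%%, promoters %.1f%% (planted specific fraction: 35%%)",
  100 * mean(u_enh), 100 * mean(u_pro)))

long <- NULL
for (kind in c("enhancer", "promoter")) {
  J <- jaccard_matrix(nets, kind = kind)
  for (i in seq_along(cts)) for (j in seq_along(cts)) {
    long <- rbind(long, data.frame(cell_a = cts[i], cell_b = cts[j],
                                   kind = kind, jaccard = round(J[i, j], 4)))
  }
}
utils::write.table(long, file.path(out_dir, "jaccard_long.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

J <- jaccard_matrix(nets, kind = "enhancer")
st <- default_stages()
prog <- names(st)[st == "progenitor"]; mat <- names(st)[st == "mature"]
within <- mean(c(J[prog, prog][upper.tri(J[prog, prog])],
                 J[mat, mat][upper.tri(J[mat, mat])]))
cross <- mean(J[prog, mat])
message(sprintf(
  "Enhancer Jaccard: within-stage mean %.3f vs cross-stage mean %.3f (stage-sharing drives the block structure)",
  within, cross))
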