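#!/usr/bin/env Rscript
# Relate the metaTAD tree to the feature track: correlation over tree vs
# linear distance, correlation lengths at the 20% threshold, significance
# against random neighbour trees, compartments, co-compartment frequency
# along the tree, and boundary profiles.

suppressMessages(library(metatadr))
inp <- "results/synthetic"
out <- "results/features"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

m <- read_contact_matrix(file.path(inp, "contacts_A.tsv"), bin_size = 5e4)
tads <- read_bed(file.path(inp, "tads.bed"), as_tads = TRUE)
track <- read_bedgraph(file.path(inp, "feature.bedGraph"))
tree <- build_metatad_tree(tad_contact_matrix(m, tads), tads = tads)

vals <- aggregate_feature_per_tad(track, tads)
td <- tree_distances(tree)
p_tree <- correlation_vs_distance(vals, td, tads)
p_lin <- correlation_vs_distance(vals, "linear", tads)
write.table(p_tree, file.path(out, "corr_tree.tsv"), sep = "\t",
            row.names = FALSE)
write.table(p_lin, file.path(out, "corr_linear.tsv"), sep = "\t",
            row.names = FALSE)

cl_tree <- correlation_length(p_tree, 0.2)
cl_lin <- correlation_length(p_lin, 0.2)
message(sprintf(
  "correlation length at 20%%: %.1f Mb over the tree vs %.1f Mb linear (%s/%s)",
  cl_tree / 1e6, cl_lin / 1e6, attr(cl_tree, "flag"), attr(cl_lin, "flag")))

ens <- random_neighbour_trees(tads, 500, seed = 3)
pv <- correlation_pvalue(vals, tads, p_tree, ens)
write.table(pv, file.path(out, "corr_tree_pvalues.tsv"), sep = "\t",
            row.names = FALSE)
message(sprintf("tree correlation beats random neighbour trees (p < 0.05) at %d of %d distances",
                sum(pv$p < 0.05), nrow(pv)))

bal <- ice_balance(m)
comp <- compartments_pc1(bal)
tc <- tad_compartment(comp, tads, m$bin_size)
cc <- co_compartment_vs_tree(tree, tc$label)
write.table(cc, file.path(out, "co_compartment.tsv"), sep = "\t",
            row.names = FALSE)

bp <- boundary_profiles(track, tads, tree, flank = 9e5,
                        size_range = quantile(tree$d, c(0.5, 1)))
write.table(bp, file.path(out, "boundary_profiles.tsv"), sep = "\t",
            row.names = FALSE)

# LAD-like track: treat the B compartment as lamina-associated intervals
bbins <- which(comp$label == "B")
if (length(bbins)) {
  runs <- split(bbins, cumsum(c(1, diff(bbins) != 1)))
  lads <- do.call(rbind, lapply(runs, function(r) {
    data.frame(start = (min(r) - 1) * m$bin_size, end = max(r) * m$bin_size)
  }))
  lt <- lad_transition_coincidence(tads$start[-1], lads,
                                   chrom_length = max(tads$end),
                                   window = 1e5, n_perm = 1000, seed = 4)
  message(sprintf("TAD boundaries coinciding with LAD-like transitions: %.0f%% (p = %.3g)",
                  100 * lt$fraction, lt$p))
}
message("feature analyses written to ", out)
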