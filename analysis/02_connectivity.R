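# Build Fisher-z FC matrices for every subject x clip, threshold them at
# each sparsity, and export the long-format edge-vector tables the effects
# and classification stages consume.
#
# Run from the repository root:  Rscript analysis/02_connectivity.R

source(file.path("analysis", "00_parameters.R"))

ds <- study_dataset()
e_total <- n_edges(N_REGIONS)

utils::write.table(edge_index(N_REGIONS),
                   file.path(RESULTS_DIR, "edge_index.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

for (sp in SPARSITIES) {
  stack <- fc_stack(ds, sparsity = sp)
  path <- file.path(RESULTS_DIR, sprintf("fc_edges_sparsity%s.tsv", sp))
  moviefc:::write_stack_tsv(stack, path)
  kept <- floor(sp * e_total)
  cat(sprintf("sparsity %.2f: %d x %d edge vectors, %d of %d edges retained per matrix -> %s\n",
              sp, dim(stack$values)[1] * dim(stack$values)[2], e_total,
              kept, e_total, path))
}
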