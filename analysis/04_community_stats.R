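#!/usr/bin/env Rscript
# Stage 4 — community structure.
#
# Richness and Gini-based evenness per plant on the 1%-filtered order
# profiles, z-score hierarchical clustering of the metaprotein profiles
# (euclidean distance, average linkage, 1000-replicate permutation test
# of the four-group separation), and PCA at three profile levels.

suppressPackageStartupMessages(library(proteotypeR))

run <- "results/run"
seed <- 1L
fl_mp <- read_matrix(file.path(run, "abundance_metaprotein_filtered.tsv"))
fl_ord <- read_matrix(file.path(run, "abundance_order_filtered.tsv"))
fl_proc <- read_matrix(file.path(run, "abundance_process_filtered.tsv"))
counts <- read_matrix(file.path(run, "metaprotein_counts.tsv"))
gt <- jsonlite::read_json(file.path(run, "ground_truth.json"),
                          simplifyVector = TRUE)
groups <- unlist(gt$groups)

idx <- community_indices(fl_ord, n_spectra = colSums(counts))
write.table(idx, file.path(run, "community_indices.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("richness %d-%d orders (mean %.1f); evenness %.1f-%.1f%%\n",
            min(idx$richness), max(idx$richness), mean(idx$richness),
            min(idx$evenness_pct), max(idx$evenness_pct)))

z <- zscore_rows(fl_mp)
cl <- hierarchical_cluster(z, k = 4)
pt <- cluster_permutation_test(z, groups[colnames(z)], n_perm = 1000,
                               seed = seed)
cat(sprintf("four-group separation: T = %.3f, permutation p = %.4g\n",
            pt$statistic, pt$p_value))
write.table(data.frame(sample_id = names(cl$labels), cluster = cl$labels,
                       group = groups[names(cl$labels)]),
            file.path(run, "cluster_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (nm in c(order = "order", process = "process", metaprotein = "metaprotein")) {
  m <- switch(nm, order = fl_ord, process = fl_proc, metaprotein = fl_mp)
  pc <- pca(m, n_components = 2)
  cat(sprintf("PCA (%s): first two components explain %.1f%% of variance\n",
              nm, sum(pc$variance_explained_pct[1:2])))
  write_matrix(t(pc$scores), file.path(run, sprintf("pca_scores_%s.tsv", nm)))
  write_matrix(t(pc$loadings),
               file.path(run, sprintf("pca_loadings_%s.tsv", nm)))
}
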